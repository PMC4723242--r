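test_that("latent scores are orthogonal across factors and seeded deterministically", {
  tr <- generate_latent(n_facilities = 10000, waves = 1, seed = 1)
  expect_lt(abs(cor(tr[[1]][, "functional"], tr[[1]][, "structural"])), 0.03)
  tr2 <- generate_latent(n_facilities = 10000, waves = 1, seed = 1)
  expect_identical(tr, tr2)
})

test_that("the wave-2 change model has the closed-form cross-wave correlation", {
  # zero mean reversion: wave 2 identical to wave 1
  tr0 <- generate_latent(200, waves = 2, kappa = c(0, 0), seed = 2)
  expect_equal(tr0$wave2, tr0$wave1)
  # kappa = 0.5 implies corr = 1 - kappa = 0.5, unit marginal variance
  tr <- generate_latent(20000, waves = 2, kappa = c(0.5, 0.1), seed = 3)
  expect_equal(cor(tr$wave1[, 1], tr$wave2[, 1]), 0.5, tolerance = 0.02)
  expect_equal(cor(tr$wave1[, 2], tr$wave2[, 2]), 0.9, tolerance = 0.02)
  expect_equal(var(tr$wave2[, 1]), 1, tolerance = 0.03)
})

test_that("indicator generation follows the probit measurement model", {
  # zero loading: categories follow the threshold-implied margins exactly
  eta <- generate_latent(20000, waves = 1, seed = 4)[[1]]
  lds <- default_loadings(); lds[] <- 0; lds["unit_availability"] <- 0
  im <- generate_indicators(eta, lds,
                            thresholds = list(unit_availability = c(-0.5, 1)),
                            seed = 5)
  freq <- table(im$x[, "unit_availability"]) / nrow(eta)
  expect_equal(as.numeric(freq),
               diff(c(0, pnorm(-0.5), pnorm(1), 1)), tolerance = 0.02)

  # near-deterministic loading on a binary indicator: indicator ~ sign(eta)
  lds2 <- default_loadings(); lds2[] <- 0.99
  nc <- default_ncat(); nc[] <- 2L
  im2 <- generate_indicators(eta, lds2, n_cat = nc,
                             thresholds = stats::setNames(
                               rep(list(0), 8), names(lds2)), seed = 6)
  agree <- mean((im2$x[, "consult_integration"] == 1) ==
                (eta[, "functional"] > 0))
  expect_gt(agree, 0.95)

  expect_identical(generate_indicators(eta[1:50, ], seed = 7)$x,
                   generate_indicators(eta[1:50, ], seed = 7)$x)
  bad <- default_loadings(); bad[1] <- 1
  expect_error(generate_indicators(eta, bad), "< 1")
})

test_that("client-flow generation hits the attribute targets in expectation", {
  tg <- data.frame(facility_id = "F01", unit_availability = 0.6,
                   facility_availability = 0.75, room_range = 0.5,
                   provider_range = 0.4, temporal_range = 0.8,
                   consult_integration = 0.5, visit_integration = 0.7,
                   art_score_fraction = 0.6)
  g <- generate_flow(tg, clients_per_day = 400, n_days = 5, seed = 3)
  fl <- g$flow
  expect_equal(num(compute_consult_integration(fl)), 0.5, tolerance = 0.03)
  expect_equal(num(compute_visit_integration(fl)), 0.7, tolerance = 0.03)
  expect_equal(num(compute_art_score(fl)), g$targets$art_score_expected,
               tolerance = 0.1)
  expect_equal(num(compute_temporal_range(fl)), 0.8, tolerance = 0.2001)

  # infeasible combinations are rejected
  bad <- tg; bad$consult_integration <- 0.6; bad$visit_integration <- 0.4
  expect_error(generate_flow(bad), "consultation integration exceeds")
  bad2 <- tg; bad2$visit_integration <- 0.9; bad2$temporal_range <- 0.5
  expect_error(generate_flow(bad2), "exceeds the share of days")
})

test_that("the full study simulator is deterministic and internally consistent", {
  sim <- simulate_study(n_facilities = 12, waves = 2, flow = TRUE,
                        clients_per_day = 15, seed = 9)
  sim2 <- simulate_study(n_facilities = 12, waves = 2, flow = TRUE,
                         clients_per_day = 15, seed = 9)
  expect_identical(sim$indicators$baseline$x, sim2$indicators$baseline$x)
  expect_identical(as.data.frame(sim$flow$endline),
                   as.data.frame(sim2$flow$endline))
  expect_equal(names(sim$indicators), c("baseline", "endline"))
  expect_equal(nrow(sim$truth$wave1), 12L)
  # flow-layer attribute table covers all facilities in both waves
  tab <- suppressWarnings(
    build_attribute_table(sim$flow$baseline, sim$inventories$baseline,
                          wave = "baseline"))
  expect_equal(nrow(tab), 12L)
  # 40 facilities x 2 waves -> 80 attribute rows via the generator round trip
  sim40 <- simulate_study(n_facilities = 40, waves = 2, flow = TRUE,
                          clients_per_day = 8, seed = 10)
  tabs <- lapply(c("baseline", "endline"), function(w)
    suppressWarnings(build_attribute_table(sim40$flow[[w]],
                                           sim40$inventories[[w]], wave = w)))
  expect_equal(sum(vapply(tabs, nrow, integer(1))), 80L)
})

test_that("attributes computed from generated flow correlate with the latent truth", {
  sim <- simulate_study(n_facilities = 40, waves = 1, flow = TRUE,
                        clients_per_day = 40, seed = 12)
  tab <- suppressWarnings(
    build_attribute_table(sim$flow$baseline, sim$inventories$baseline,
                          wave = "baseline"))
  tab <- tab[match(sprintf("F%02d", 1:40), tab$facility_id), ]
  expect_gt(cor(tab$visit_integration, sim$truth$wave1[, "functional"]), 0.6)
  expect_gt(cor(tab$unit_availability, sim$truth$wave1[, "structural"]), 0.4)
  expect_true(all(tab$consult_integration <= tab$visit_integration + 1e-12))
})
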