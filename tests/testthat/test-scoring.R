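fake_scores <- function(score, wave = "baseline", factor = "functional",
                        ids = NULL) {
  out <- data.frame(facility_id = if (is.null(ids))
    sprintf("F%02d", seq_along(score)) else ids, wave = wave)
  out[[paste0(factor, "_score")]] <- score
  out[[paste0(factor, "_se")]] <- rep(0.3, length(score))
  attr(out, "factors") <- factor
  class(out) <- c("factor_scores", "data.frame")
  out
}

test_that("rescaling maps the practical score range onto the 1-7 scale exactly", {
  sc <- rank_and_rescale(fake_scores(c(-3, 0, 3)))
  expect_equal(sc$functional_rescaled, c(1, 4, 7))
  # order-preserving, ranks invariant under rescale
  expect_equal(order(sc$functional_rescaled), order(sc$functional_score))
  expect_warning(out <- rank_and_rescale(fake_scores(c(-5, 0, 1))),
                 "not clipped")
  expect_equal(out$functional_rescaled[1], -1)  # passes through unclipped
})

test_that("ranking is descending with average ties, within wave", {
  sc <- rank_and_rescale(fake_scores(c(2.1, -0.3, 0.8)))
  expect_equal(sc$functional_rank, c(1, 3, 2))
  tied <- rank_and_rescale(fake_scores(c(1.0, 1.0)))
  expect_equal(tied$functional_rank, c(1.5, 1.5))
  two <- rbind(fake_scores(c(1, 2)), fake_scores(c(5, -1), wave = "endline"))
  attr(two, "factors") <- "functional"
  class(two) <- c("factor_scores", "data.frame")
  two <- suppressWarnings(rank_and_rescale(two))
  expect_equal(two$functional_rank, c(2, 1, 1, 2))
})

test_that("change metrics match hand arithmetic and guard degenerate input", {
  b <- fake_scores(c(1, 2, 3))
  e <- fake_scores(c(2, 2, 2), wave = "endline")
  expect_warning(cm <- change_metrics(b, e), "degenerate")
  expect_equal(unname(cm$sad["functional"]), 2)
  expect_true(is.na(cm$cross_wave_r["functional"]))

  same <- change_metrics(b, fake_scores(c(1, 2, 3), wave = "endline"))
  expect_equal(unname(same$sad["functional"]), 0)
  expect_equal(unname(same$cross_wave_r["functional"]), 1)

  expect_error(change_metrics(b, fake_scores(c(1, 2, 3), ids = c("X", "Y", "Z"))),
               "unmatched")
  # facility order does not matter: matched by id
  e2 <- fake_scores(c(3, 2, 2), wave = "endline",
                    ids = c("F03", "F02", "F01"))
  cm2 <- suppressWarnings(change_metrics(b, e2))
  expect_equal(unname(cm2$sad["functional"]), sum(abs(c(2, 2, 3) - c(1, 2, 3))))
})

test_that("plausible values summarize scores with uncertainty and ranks", {
  sim <- simulate_study(n_facilities = 30, waves = 1, seed = 81)
  fit <- integration_cfa(sim$indicators[[1]], 2, chains = 2, iter = 3000,
                         seed = 81)
  pv <- plausible_values(fit)
  expect_s3_class(pv, "factor_scores")
  expect_equal(nrow(pv), 30L)
  expect_true(all(pv$functional_se > 0))
  expect_equal(sort(pv$functional_rank), seq_len(30))
  # recovery: scores track the generating latent variables
  expect_gt(cor(pv$functional_score, sim$truth[[1]][, "functional"]), 0.8)
  expect_gt(cor(pv$structural_score, sim$truth[[1]][, "structural"]), 0.8)
  # a facility at the top category on every indicator scores highest
  top <- which.max(rowSums(sim$indicators[[1]]$x))
  if (all(sim$indicators[[1]]$x[top, ] ==
          sim$indicators[[1]]$ncat[colnames(sim$indicators[[1]]$x)] - 1L)) {
    expect_equal(which.max(pv$functional_score + pv$structural_score), top)
  }
  # random-draw mode is seeded and reproducible
  d1 <- plausible_values(fit, summary = "random_draw", seed = 4)
  d2 <- plausible_values(fit, summary = "random_draw", seed = 4)
  expect_equal(d1$functional_score, d2$functional_score)
  expect_false(identical(d1$functional_score, pv$functional_score))
})

test_that("fixed-parameter scoring reproduces plausible values on the same data", {
  sim <- simulate_study(n_facilities = 30, waves = 1, seed = 91)
  fit <- integration_cfa(sim$indicators[[1]], 2, chains = 4, iter = 8000,
                         seed = 91)
  pv <- plausible_values(fit)
  sf <- score_fixed(fit, sim$indicators[[1]], iter = 8000, seed = 7)
  for (f in c("functional", "structural")) {
    expect_gt(cor(pv[[paste0(f, "_score")]], sf[[paste0(f, "_score")]]), 0.99)
    expect_lt(mean(abs(pv[[paste0(f, "_score")]] - sf[[paste0(f, "_score")]])),
              0.15)
  }
})

test_that("given fixed parameters facilities are scored independently", {
  sim <- simulate_study(n_facilities = 20, waves = 1, seed = 101)
  fit <- integration_cfa(sim$indicators[[1]], 2, chains = 2, iter = 4000,
                         seed = 101)
  batch <- score_fixed(fit, sim$indicators[[1]], iter = 20000, seed = 3)
  solo_im <- facint:::im_subset(sim$indicators[[1]], 7L)
  solo <- score_fixed(fit, solo_im, iter = 20000, seed = 3)
  expect_equal(solo$functional_score, batch$functional_score[7],
               tolerance = 0.05)
  expect_equal(solo$structural_score, batch$structural_score[7],
               tolerance = 0.05)
})

test_that("scoring new data with categories beyond the baseline coding fails", {
  sim <- simulate_study(n_facilities = 20, waves = 1, seed = 111)
  fit <- integration_cfa(sim$indicators[[1]], 2, chains = 2, iter = 1000,
                         seed = 111)
  new_im <- sim$indicators[[1]]
  new_im$x[1, 1] <- 9L
  expect_error(score_fixed(fit, new_im), "exceeds the baseline coding")
})
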