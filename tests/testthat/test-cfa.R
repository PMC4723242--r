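test_that("standardized loadings follow the theta-parameterization closed form", {
  sim <- simulate_study(n_facilities = 25, waves = 1, seed = 21)
  fit <- integration_cfa(sim$indicators[[1]], n_factors = 2, chains = 2,
                         iter = 1200, seed = 1)
  lam <- facint:::pooled_draws(fit, "lambda")
  sl <- standardized_loadings(fit)
  # identical to applying lambda/sqrt(lambda^2+1) per draw, then averaging
  expect_equal(sl$estimate, unname(colMeans(lam / sqrt(lam^2 + 1))))
  expect_true(all(sl$estimate > -1 & sl$estimate < 1))
  expect_true(all(sl$lower <= sl$estimate & sl$estimate <= sl$upper))
  # spot values of the transform itself
  f <- function(l) l / sqrt(l^2 + 1)
  expect_equal(f(1), 0.7071, tolerance = 1e-4)
  expect_equal(f(0), 0)
  expect_gt(f(1e8), 1 - 1e-8)
})

test_that("sign resolution orients every draw and restores cross-chain agreement", {
  spec <- facint:::model_spec(attribute_names(), 2)
  n <- 4
  set.seed(1)
  base_lam <- matrix(abs(rnorm(50 * 8, 1)), 50, 8,
                     dimnames = list(NULL, paste0("lambda_", attribute_names())))
  base_eta <- matrix(rnorm(50 * n * 2), 50, n * 2)
  ch1 <- list(lambda = base_lam, tau = matrix(0, 50, 1), eta = base_eta)
  # a chain stuck in the mirrored mode of the functional factor
  ch2 <- ch1
  fun_cols <- which(spec$free_cols == 1)
  ch2$lambda[, fun_cols] <- -ch2$lambda[, fun_cols]
  ch2$eta[, 1:n] <- -ch2$eta[, 1:n]
  r1 <- facint:::resolve_signs_chain(ch1, spec, n)
  r2 <- facint:::resolve_signs_chain(ch2, spec, n)
  expect_equal(r1$lambda, r2$lambda)
  expect_equal(r1$eta, r2$eta)
  # an already-positive draw is unchanged
  expect_equal(r1$lambda, base_lam)
  # PSR computed after resolution sees identical chains
  expect_equal(unname(facint:::psr.list(list(r1$lambda, r2$lambda))),
               rep(1, 8))
})

test_that("the augmented-data likelihood is invariant under factor reflection", {
  set.seed(2)
  n <- 15
  Lambda <- cbind(c(rnorm(4), 0, 0, 0, 0), c(0, 0, 0, 0, rnorm(4)))
  eta <- matrix(rnorm(n * 2), n, 2)
  ystar <- eta %*% t(Lambda) + matrix(rnorm(n * 8), n, 8)
  ll <- facint:::latent_loglik(ystar, eta, Lambda)
  Lambda2 <- Lambda; Lambda2[, 1] <- -Lambda2[, 1]
  eta2 <- eta; eta2[, 1] <- -eta2[, 1]
  expect_equal(facint:::latent_loglik(ystar, eta2, Lambda2), ll)
})

test_that("with loadings fixed at zero the model reproduces independent ordinal margins", {
  set.seed(3)
  n <- 400
  x <- cbind(a = sample(0:2, n, TRUE, prob = c(0.5, 0.3, 0.2)),
             b = sample(0:1, n, TRUE, prob = c(0.35, 0.65)))
  ncat <- c(3L, 2L)
  pattern <- matrix(1L, 2, 1)
  tau0 <- list(c(-0.1, 0.9), 0.1)
  ch <- facint:::gibbs_chain(x, ncat, pattern, 3000L, 1500L, 1L, 25, 25,
                             matrix(0, 2, 1), tau0,
                             FALSE, TRUE, FALSE)
  # implied category probabilities from posterior-mean thresholds
  tmean <- colMeans(ch$tau)
  pa <- diff(c(0, pnorm(tmean[1]), pnorm(tmean[2]), 1))
  pb <- diff(c(0, pnorm(tmean[3]), 1))
  expect_equal(pa, as.numeric(table(factor(x[, "a"], 0:2))) / n,
               tolerance = 0.05)
  expect_equal(pb, as.numeric(table(factor(x[, "b"], 0:1))) / n,
               tolerance = 0.05)
})

test_that("the two-factor fit recovers generating loadings on one synthetic study", {
  sim <- simulate_study(n_facilities = 40, waves = 1, seed = 31)
  fit <- integration_cfa(sim$indicators[[1]], n_factors = 2, chains = 4,
                         iter = 8000, seed = 31)
  sl <- standardized_loadings(fit)
  truth <- default_loadings()[sl$indicator]
  expect_gte(sum(truth >= sl$lower & truth <= sl$upper), 6L)
  expect_lt(mean(abs(sl$estimate - truth)), 0.15)
  # factor assignment respects the confirmatory pattern
  expect_setequal(sl$indicator[sl$factor == "functional"],
                  c("art_location_score", "temporal_range",
                    "consult_integration", "visit_integration"))
})

test_that("fits are reproducible given the master seed", {
  sim <- simulate_study(n_facilities = 15, waves = 1, seed = 41)
  f1 <- integration_cfa(sim$indicators[[1]], 2, chains = 2, iter = 800,
                        seed = 5)
  f2 <- integration_cfa(sim$indicators[[1]], 2, chains = 2, iter = 800,
                        seed = 5)
  expect_identical(f1$draws[[1]]$lambda, f2$draws[[1]]$lambda)
  expect_identical(f1$draws[[2]]$eta, f2$draws[[2]]$eta)
})

test_that("degenerate inputs are rejected with clear errors", {
  sim <- simulate_study(n_facilities = 15, waves = 1, seed = 51)
  im <- sim$indicators[[1]]
  im$x[, 3] <- 0L
  expect_error(integration_cfa(im, 2), "fewer than 2 observed categories")
  expect_error(integration_cfa(sim$indicators[[1]], 2, chains = 1),
               "2 chains")
  small <- facint:::im_subset(sim$indicators[[1]], 1:5)
  expect_error(integration_cfa(small, 2), "fewer facilities")
  expect_error(integration_cfa(sim$indicators[[1]], 3), "1 or 2")
})

test_that("threshold draws are strictly increasing in every retained draw", {
  sim <- simulate_study(n_facilities = 30, waves = 1, seed = 61)
  fit <- integration_cfa(sim$indicators[[1]], 2, chains = 2, iter = 1500,
                         seed = 2)
  tau <- facint:::pooled_draws(fit, "tau")
  ncat <- fit$indicators$ncat
  p <- 0L
  for (j in seq_along(ncat)) {
    k <- ncat[j] - 1L
    if (k > 1L) {
      block <- tau[, p + seq_len(k), drop = FALSE]
      expect_true(all(apply(block, 1, function(v) all(diff(v) > 0))))
    }
    p <- p + k
  }
})

test_that("posterior-predictive simulate() returns matched indicator matrices", {
  sim <- simulate_study(n_facilities = 20, waves = 1, seed = 71)
  fit <- integration_cfa(sim$indicators[[1]], 2, chains = 2, iter = 1000,
                         seed = 3)
  reps <- simulate(fit, nsim = 3, seed = 4)
  expect_length(reps, 3L)
  for (r in reps) {
    expect_s3_class(r, "indicator_matrix")
    expect_equal(dim(r$x), dim(fit$indicators$x))
    expect_equal(r$ncat, fit$indicators$ncat)
  }
  expect_identical(simulate(fit, nsim = 2, seed = 9)[[1]]$x,
                   simulate(fit, nsim = 2, seed = 9)[[1]]$x)
})
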