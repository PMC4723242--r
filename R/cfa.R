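#' Bayesian ordinal-probit confirmatory factor analysis
#'
#' Fits a one- or two-factor confirmatory factor model to the ordinal
#' indicator matrix, using a 2-parameter probit link: for indicator \eqn{j}
#' of facility \eqn{i} the latent response is
#' \eqn{y^*_{ij} = \lambda_j' \eta_i + \epsilon_{ij}},
#' \eqn{\epsilon_{ij} \sim N(0,1)}, and the observed category is determined
#' by strictly increasing thresholds \eqn{\tau_j}.  Factor variances and
#' residual variances are fixed at 1 (theta parameterization); all loadings
#' and thresholds are free with diffuse normal priors.  Estimation is by a
#' data-augmentation Gibbs sampler (truncated-normal latent responses,
#' conjugate normal updates for loadings and scores, truncated-normal
#' conditional threshold updates); missing indicator cells are integrated
#' out by the augmentation step under an ignorable-missingness assumption.
#'
#' In the two-factor specification the four functional indicators
#' (HIV-treatment-location score, day-level co-delivery, consultation- and
#' visit-level co-receipt) load only on the functional factor and the four
#' structural indicators (unit and facility availability, provider and room
#' range) only on the structural factor; the factors are orthogonal by
#' construction (identity factor covariance).  The one-factor specification
#' loads all indicators on a single factor.
#'
#' Reflection invariance (flipping the signs of one factor's loadings and
#' scores leaves the likelihood unchanged) is resolved after sampling:
#' within every retained draw, each factor is oriented so that the sum of
#' its loadings is positive.
#'
#' @param indicators an `indicator_matrix` from [ordinalize()],
#'   [indicator_matrix()] or the synthetic generator.
#' @param n_factors 1 or 2.
#' @param prior_var_loading,prior_var_threshold prior variances of the
#'   normal(0, v) priors.  The defaults (25) are weakly informative on the
#'   probit scale: they are flat over the entire plausible range
#'   (standardized loadings up to 0.98 correspond to raw loadings of about
#'   5) while regularizing the weakly identified scale ridge that arises
#'   when a small sample is separated almost perfectly by an indicator.
#'   Set them very large (e.g. 1e6) for fully diffuse priors.
#' @param chains number of MCMC chains (>= 2, needed for convergence
#'   diagnostics).
#' @param iter total iterations per chain (including burn-in).
#' @param burnin fraction of iterations discarded (default 0.5).
#' @param thin retain every `thin`-th post-burn-in draw.
#' @param seed master seed; per-chain seeds are derived deterministically.
#' @param store_eta keep factor-score draws (needed for scoring; default
#'   `TRUE`).
#' @return An object of class `integration_cfa` with per-chain draw matrices
#'   (`lambda`, `tau`, `eta`), the model specification, and metadata.
#'   Methods: [print()], [summary()], [coef()], [plot()], [simulate()],
#'   [predict()] (fixed-parameter scoring of new data).
#' @examples
#' sim <- simulate_study(n_facilities = 20, waves = 1, seed = 1)
#' fit <- integration_cfa(sim$indicators[[1]], n_factors = 2,
#'                        chains = 2, iter = 600, seed = 1)
#' coef(fit)
#' @export
integration_cfa <- function(indicators, n_factors = 2,
                            prior_var_loading = 25,
                            prior_var_threshold = 25,
                            chains = 4, iter = 50000, burnin = 0.5,
                            thin = 1, seed = 1, store_eta = TRUE) {
  stopifnot(inherits(indicators, "indicator_matrix"))
  if (!n_factors %in% c(1, 2)) stop("n_factors must be 1 or 2", call. = FALSE)
  if (chains < 2) stop("at least 2 chains are required", call. = FALSE)
  if (burnin <= 0 || burnin >= 1) stop("burnin must be in (0,1)", call. = FALSE)
  x <- indicators$x
  J <- ncol(x); n <- nrow(x)
  for (j in seq_len(J)) {
    v <- x[, j][!is.na(x[, j])]
    if (length(unique(v)) < 2L)
      stop("indicator ", colnames(x)[j],
           " has fewer than 2 observed categories", call. = FALSE)
  }

  spec <- model_spec(colnames(x), n_factors)
  if (n < sum(spec$pattern))
    stop("fewer facilities (", n, ") than free loadings (",
         sum(spec$pattern), ")", call. = FALSE)

  n_burn <- floor(iter * burnin)
  if (iter - n_burn < thin) stop("no retained draws; increase iter", call. = FALSE)

  set.seed(seed)
  chain_seeds <- sample.int(.Machine$integer.max - 1L, chains)

  ncat <- as.integer(indicators$ncat[colnames(x)])
  run_chain <- function(cs) {
    set.seed(cs)
    lam0 <- matrix(0, J, spec$n_factors)
    lam0[spec$pattern == 1L] <- stats::rnorm(sum(spec$pattern), 0, 1)
    tau0 <- lapply(seq_len(J), function(j) {
      v <- x[, j][!is.na(x[, j])]
      fr <- tabulate(v + 1L, nbins = ncat[j])
      p <- cumsum(fr)[-ncat[j]] / sum(fr)
      p <- pmin(pmax(p, 0.02), 0.98)
      tt <- stats::qnorm(p) + stats::rnorm(ncat[j] - 1L, 0, 0.1)
      sort(tt) + seq(0, 1e-6, length.out = ncat[j] - 1L)
    })
    gibbs_chain(x, ncat, spec$pattern, as.integer(iter), as.integer(n_burn),
                as.integer(thin), prior_var_loading, prior_var_threshold,
                lam0, tau0, TRUE, TRUE, store_eta)
  }
  raw <- lapply(chain_seeds, run_chain)

  lam_names <- paste0("lambda_", colnames(x)[spec$free_rows])
  tau_names <- unlist(lapply(seq_len(J), function(j)
    paste0("tau_", colnames(x)[j], "_", seq_len(ncat[j] - 1L))))
  eta_names <- if (store_eta)
    as.vector(outer(indicators$facility_id, spec$factors,
                    function(a, b) paste0("eta_", a, "_", b))) else character(0)

  draws <- lapply(raw, function(ch) {
    colnames(ch$lambda) <- lam_names
    colnames(ch$tau) <- tau_names
    if (store_eta) colnames(ch$eta) <- eta_names
    resolve_signs_chain(ch, spec, n)
  })

  structure(list(draws = draws, spec = spec, indicators = indicators,
                 n = n, chains = chains, iter = iter, burnin = burnin,
                 thin = thin, seed = seed,
                 prior_var_loading = prior_var_loading,
                 prior_var_threshold = prior_var_threshold,
                 store_eta = store_eta),
            class = "integration_cfa")
}

# loading pattern for the confirmatory one- and two-factor specifications
model_spec <- function(indicator_names, n_factors) {
  J <- length(indicator_names)
  if (n_factors == 1) {
    pattern <- matrix(1L, J, 1, dimnames = list(indicator_names, "integration"))
    factors <- "integration"
  } else {
    fun <- functional_attributes()
    str <- structural_attributes()
    if (!all(indicator_names %in% c(fun, str)))
      stop("two-factor specification requires the eight standard attribute ",
           "indicators; got: ", paste(indicator_names, collapse = ", "),
           call. = FALSE)
    pattern <- matrix(0L, J, 2,
                      dimnames = list(indicator_names,
                                      c("functional", "structural")))
    pattern[indicator_names %in% fun, 1] <- 1L
    pattern[indicator_names %in% str, 2] <- 1L
    factors <- c("functional", "structural")
  }
  # free loadings in row-major order (indicator-by-indicator), matching the
  # storage order of the sampler
  rows_cm <- row(pattern)[pattern == 1L]
  cols_cm <- col(pattern)[pattern == 1L]
  o <- order(rows_cm, cols_cm)
  list(n_factors = n_factors, pattern = pattern, factors = factors,
       indicators = indicator_names,
       free_rows = rows_cm[o], free_cols = cols_cm[o])
}

# orient each factor so the sum of its loadings is positive, per draw;
# factor-score columns are negated accordingly
resolve_signs_chain <- function(ch, spec, n) {
  for (f in seq_len(spec$n_factors)) {
    cols <- which(spec$free_cols == f)
    flip <- rowSums(ch$lambda[, cols, drop = FALSE]) < 0
    if (any(flip)) {
      ch$lambda[flip, cols] <- -ch$lambda[flip, cols, drop = FALSE]
      if (length(ch$eta) > 0) {
        ecols <- ((f - 1L) * n + 1L):(f * n)
        ch$eta[flip, ecols] <- -ch$eta[flip, ecols, drop = FALSE]
      }
    }
  }
  ch
}

# all retained draws of one block ("lambda", "tau", "eta"), chains stacked
pooled_draws <- function(fit, block = "lambda") {
  do.call(rbind, lapply(fit$draws, `[[`, block))
}

#' Standardized factor loadings
#'
#' Under the theta parameterization (unit factor and residual variances) the
#' standardized loading of indicator \eqn{j} is
#' \eqn{\lambda_j / \sqrt{\lambda_j^2 + 1}}, applied per posterior draw and
#' then summarized.  Values lie in (-1, 1).
#'
#' @param fit an [integration_cfa()] fit.
#' @param prob credible-interval mass (default 0.95).
#' @return Data frame with indicator, factor, posterior mean, sd and
#'   credible bounds of the standardized loading.
#' @export
standardized_loadings <- function(fit, prob = 0.95) {
  lam <- pooled_draws(fit, "lambda")
  std <- lam / sqrt(lam^2 + 1)
  a <- (1 - prob) / 2
  data.frame(
    indicator = sub("^lambda_", "", colnames(lam)),
    factor = fit$spec$factors[fit$spec$free_cols],
    estimate = colMeans(std),
    sd = apply(std, 2, stats::sd),
    lower = apply(std, 2, stats::quantile, probs = a),
    upper = apply(std, 2, stats::quantile, probs = 1 - a),
    row.names = NULL)
}

#' @export
coef.integration_cfa <- function(object, type = c("standardized", "raw"), ...) {
  type <- match.arg(type)
  if (type == "standardized") {
    sl <- standardized_loadings(object)
    stats::setNames(sl$estimate, sl$indicator)
  } else {
    lam <- pooled_draws(object, "lambda")
    stats::setNames(colMeans(lam), sub("^lambda_", "", colnames(lam)))
  }
}

#' @export
print.integration_cfa <- function(x, ...) {
  cat("Bayesian ordinal-probit factor model (", x$spec$n_factors,
      "-factor", if (x$spec$n_factors == 2) ", orthogonal" else "",
      ")\n", sep = "")
  cat(sprintf("%d facilities, %d indicators; %d chains x %d iterations (burn-in %g%%, thin %d)\n",
              x$n, length(x$spec$indicators), x$chains, x$iter,
              x$burnin * 100, x$thin))
  cat("\nStandardized loadings (posterior means):\n")
  sl <- standardized_loadings(x)
  for (f in x$spec$factors) {
    cat("  ", f, ":\n", sep = "")
    sub <- sl[sl$factor == f, ]
    for (i in seq_len(nrow(sub)))
      cat(sprintf("    %-22s %6.3f\n", sub$indicator[i], sub$estimate[i]))
  }
  invisible(x)
}

#' @export
summary.integration_cfa <- function(object, ...) {
  sl <- standardized_loadings(object)
  conv <- psr(object)
  out <- list(loadings = sl, psr = conv, max_psr = max(conv),
              spec = object$spec, n = object$n,
              retained = nrow(pooled_draws(object, "lambda")))
  class(out) <- "summary.integration_cfa"
  out
}

#' @export
print.summary.integration_cfa <- function(x, ...) {
  cat("Standardized factor loadings:\n")
  print(x$loadings, digits = 3)
  cat(sprintf("\nConvergence: max PSR = %.3f over %d parameters (%d draws)\n",
              x$max_psr, length(x$psr), x$retained))
  invisible(x)
}

#' @export
plot.integration_cfa <- function(x, type = c("loadings", "scores"), ...) {
  type <- match.arg(type)
  if (type == "loadings") {
    sl <- standardized_loadings(x)
    ord <- order(sl$factor, sl$estimate)
    sl <- sl[ord, ]
    graphics::dotchart(sl$estimate, labels = sl$indicator,
                       groups = factor(sl$factor), xlim = c(-1, 1),
                       xlab = "standardized loading", ...)
    graphics::segments(sl$lower, seq_len(nrow(sl)), sl$upper)
    graphics::abline(v = 0, lty = 3)
  } else {
    sc <- plausible_values(x)
    f1 <- x$spec$factors[1]
    y <- sc[[paste0(f1, "_score")]]
    if (x$spec$n_factors == 2) {
      xx <- sc[[paste0(x$spec$factors[2], "_score")]]
      graphics::plot(xx, y, xlab = paste(x$spec$factors[2], "score"),
                     ylab = paste(f1, "score"), ...)
      graphics::text(xx, y, sc$facility_id, pos = 3, cex = 0.6)
    } else {
      ord <- order(y, decreasing = TRUE)
      graphics::barplot(y[ord], names.arg = sc$facility_id[ord],
                        las = 2, ylab = paste(f1, "score"), ...)
    }
  }
  invisible(x)
}

#' Posterior-predictive replicate datasets
#'
#' Draws replicate indicator matrices from randomly selected retained
#' posterior draws: new factor scores from the standard-normal prior, new
#' latent responses, categorized by the draw's thresholds.
#'
#' @param object an [integration_cfa()] fit.
#' @param nsim number of replicate datasets.
#' @param seed seed for the replicate simulation.
#' @param ... unused.
#' @return A list of `indicator_matrix` objects.
#' @export
simulate.integration_cfa <- function(object, nsim = 1, seed = 1, ...) {
  set.seed(seed)
  lam <- pooled_draws(object, "lambda")
  tau <- pooled_draws(object, "tau")
  pick <- sample.int(nrow(lam), nsim, replace = nsim > nrow(lam))
  spec <- object$spec
  n <- object$n
  ncat <- object$indicators$ncat
  lapply(pick, function(d) {
    Lambda <- matrix(0, nrow(spec$pattern), spec$n_factors)
    Lambda[cbind(spec$free_rows, spec$free_cols)] <- lam[d, ]
    eta <- matrix(stats::rnorm(n * spec$n_factors), n, spec$n_factors)
    ystar <- eta %*% t(Lambda) +
      matrix(stats::rnorm(n * nrow(spec$pattern)), n)
    x <- matrix(NA_integer_, n, nrow(spec$pattern),
                dimnames = list(NULL, spec$indicators))
    p <- 0L
    for (j in seq_along(spec$indicators)) {
      K <- ncat[spec$indicators[j]]
      tj <- tau[d, p + seq_len(K - 1L)]
      p <- p + K - 1L
      x[, j] <- as.integer(rowSums(outer(ystar[, j], tj, ">")))
    }
    x[is.na(object$indicators$x)] <- NA_integer_
    indicator_matrix(x, facility_id = object$indicators$facility_id,
                     wave = object$indicators$wave, ncat = ncat)
  })
}

#' @export
predict.integration_cfa <- function(object, newdata = NULL, ...,
                                    iter = 4000, burnin = 0.5, seed = 1) {
  if (is.null(newdata)) return(plausible_values(object))
  score_fixed(object, newdata, iter = iter, burnin = burnin, seed = seed)
}

# augmented-data log likelihood (used to verify reflection invariance)
latent_loglik <- function(ystar, eta, Lambda) {
  mu <- eta %*% t(Lambda)
  sum(stats::dnorm(ystar, mu, 1, log = TRUE)) +
    sum(stats::dnorm(eta, 0, 1, log = TRUE))
}
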