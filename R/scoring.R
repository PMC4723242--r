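#' Plausible-value facility scores
#'
#' Assigns each facility a model-based latent score per factor.  The default
#' summary is the posterior mean of the facility's factor score with the
#' posterior SD as its standard error; `"random_draw"` returns a single
#' seeded posterior draw (classical plausible-value semantics).  Scores are
#' ranked (1 = highest) and rescaled by +4 for graphing, mapping the
#' practical -3..3 range onto 1..7.
#'
#' @param fit an [integration_cfa()] fit with stored factor-score draws.
#' @param summary `"mean"` (default) or `"random_draw"`.
#' @param seed seed for the `"random_draw"` mode.
#' @return A data frame of class `factor_scores`: `facility_id`, `wave`, and
#'   per factor `<factor>_score`, `<factor>_se`, `<factor>_rank`,
#'   `<factor>_rescaled`.
#' @export
plausible_values <- function(fit, summary = c("mean", "random_draw"),
                             seed = 1) {
  summary <- match.arg(summary)
  if (!fit$store_eta)
    stop("fit was run with store_eta = FALSE; no score draws available",
         call. = FALSE)
  eta <- pooled_draws(fit, "eta")
  n <- fit$n
  factors <- fit$spec$factors
  out <- data.frame(facility_id = fit$indicators$facility_id,
                    wave = fit$indicators$wave,
                    stringsAsFactors = FALSE)
  if (summary == "random_draw") {
    set.seed(seed)
    d <- sample.int(nrow(eta), 1L)
  }
  for (f in seq_along(factors)) {
    cols <- ((f - 1L) * n + 1L):(f * n)
    sc <- if (summary == "mean") colMeans(eta[, cols, drop = FALSE])
          else eta[d, cols]
    se <- apply(eta[, cols, drop = FALSE], 2, stats::sd)
    out[[paste0(factors[f], "_score")]] <- unname(sc)
    out[[paste0(factors[f], "_se")]] <- unname(se)
  }
  attr(out, "factors") <- factors
  class(out) <- c("factor_scores", "data.frame")
  rank_and_rescale(out)
}

#' Rank and rescale factor scores
#'
#' Ranks facilities per factor in descending score order (rank 1 = most
#' integrated, ties averaged) and adds the graphing rescale
#' `score + 4` (an affine map sending -3 to 1, 0 to 4 and 3 to 7).  Values
#' outside the practical -3..3 range pass through with a warning, not
#' clipped.  Ranking is computed within wave when several waves are present.
#'
#' @param scores a `factor_scores` data frame.
#' @return The input with `<factor>_rank` and `<factor>_rescaled` columns
#'   added or refreshed.
#' @export
rank_and_rescale <- function(scores) {
  factors <- attr(scores, "factors")
  if (is.null(factors))
    stop("scores lack a 'factors' attribute", call. = FALSE)
  for (f in factors) {
    sc <- scores[[paste0(f, "_score")]]
    rk <- rep(NA_real_, length(sc))
    for (w in unique(scores$wave)) {
      i <- scores$wave == w
      rk[i] <- rank(-sc[i], ties.method = "average")
    }
    scores[[paste0(f, "_rank")]] <- rk
    resc <- sc + 4
    if (any(!is.na(resc) & (resc < 1 | resc > 7)))
      warning("factor ", f, ": rescaled score(s) outside the 1-7 graphing ",
              "range (scores beyond the practical -3..3 band); not clipped",
              call. = FALSE)
    scores[[paste0(f, "_rescaled")]] <- resc
  }
  scores
}

#' Score facilities with fixed measurement parameters
#'
#' Samples factor scores for (possibly new) indicator data conditional on
#' the measurement parameters of a previously fitted model, fixed at their
#' posterior means.  Scoring multiple waves with one baseline measurement
#' model makes scores comparable across waves: differences then reflect
#' latent change, not drift in the measurement model.  Given fixed
#' parameters, facilities are scored independently, so a facility's score
#' does not depend on which other facilities are in the batch.
#'
#' @param fit an [integration_cfa()] fit (the baseline measurement model).
#' @param new_indicators an `indicator_matrix` coded with the same scheme
#'   and category counts as the fit's data.
#' @param iter,burnin conditional-sampler iterations and burn-in fraction.
#' @param seed seed.
#' @return A `factor_scores` data frame (see [plausible_values()]).
#' @export
score_fixed <- function(fit, new_indicators, iter = 4000, burnin = 0.5,
                        seed = 1) {
  stopifnot(inherits(new_indicators, "indicator_matrix"))
  x <- new_indicators$x
  if (!identical(colnames(x), fit$spec$indicators))
    stop("new indicators do not match the fitted model's indicators",
         call. = FALSE)
  ncat <- as.integer(fit$indicators$ncat[fit$spec$indicators])
  for (j in seq_len(ncol(x))) {
    v <- x[, j][!is.na(x[, j])]
    if (length(v) > 0L && max(v) >= ncat[j])
      stop("indicator ", colnames(x)[j], ": category ", max(v),
           " exceeds the baseline coding (max ", ncat[j] - 1L, ")",
           call. = FALSE)
  }
  spec <- fit$spec
  lam_mean <- colMeans(pooled_draws(fit, "lambda"))
  tau_mean <- colMeans(pooled_draws(fit, "tau"))
  Lambda <- matrix(0, nrow(spec$pattern), spec$n_factors)
  Lambda[cbind(spec$free_rows, spec$free_cols)] <- lam_mean
  tau0 <- vector("list", ncol(x))
  p <- 0L
  for (j in seq_len(ncol(x))) {
    tau0[[j]] <- as.numeric(tau_mean[p + seq_len(ncat[j] - 1L)])
    p <- p + ncat[j] - 1L
  }
  n_burn <- floor(iter * burnin)
  set.seed(seed)
  ch <- gibbs_chain(x, ncat, spec$pattern, as.integer(iter),
                    as.integer(n_burn), 1L,
                    fit$prior_var_loading, fit$prior_var_threshold,
                    Lambda, tau0, FALSE, FALSE, TRUE)
  n <- nrow(x)
  factors <- spec$factors
  out <- data.frame(facility_id = new_indicators$facility_id,
                    wave = new_indicators$wave, stringsAsFactors = FALSE)
  for (f in seq_along(factors)) {
    cols <- ((f - 1L) * n + 1L):(f * n)
    out[[paste0(factors[f], "_score")]] <- colMeans(ch$eta[, cols, drop = FALSE])
    out[[paste0(factors[f], "_se")]] <- apply(ch$eta[, cols, drop = FALSE], 2,
                                              stats::sd)
  }
  attr(out, "factors") <- factors
  class(out) <- c("factor_scores", "data.frame")
  rank_and_rescale(out)
}

#' Baseline-vs-endline change metrics
#'
#' For matched facility score tables from two waves, computes per factor the
#' sum of absolute score differences (SAD) and the Pearson correlation
#' between waves, plus the cross-factor correlation within each wave (for
#' two-factor scores).  A degenerate (zero-variance) score vector yields a
#' missing correlation with a warning.
#'
#' @param baseline,endline `factor_scores` data frames with identical
#'   facility sets.
#' @return A list of class `change_report` with elements `sad`,
#'   `cross_wave_r` (named by factor) and `cross_factor_r` (named by wave).
#' @export
change_metrics <- function(baseline, endline) {
  factors <- attr(baseline, "factors")
  if (!setequal(baseline$facility_id, endline$facility_id)) {
    only_b <- setdiff(baseline$facility_id, endline$facility_id)
    only_e <- setdiff(endline$facility_id, baseline$facility_id)
    stop("unmatched facilities: ",
         paste(c(only_b, only_e), collapse = ", "), call. = FALSE)
  }
  endline <- endline[match(baseline$facility_id, endline$facility_id), ]
  safe_cor <- function(a, b, what) {
    if (stats::sd(a) == 0 || stats::sd(b) == 0) {
      warning("degenerate (constant) scores: correlation undefined for ",
              what, call. = FALSE)
      return(NA_real_)
    }
    stats::cor(a, b)
  }
  sad <- cross_wave_r <- stats::setNames(numeric(length(factors)), factors)
  for (f in factors) {
    b <- baseline[[paste0(f, "_score")]]
    e <- endline[[paste0(f, "_score")]]
    sad[f] <- sum(abs(e - b))
    cross_wave_r[f] <- safe_cor(b, e, f)
  }
  cross_factor_r <- NULL
  if (length(factors) == 2L) {
    cross_factor_r <- c(
      baseline = safe_cor(baseline[[paste0(factors[1], "_score")]],
                          baseline[[paste0(factors[2], "_score")]],
                          "baseline cross-factor"),
      endline = safe_cor(endline[[paste0(factors[1], "_score")]],
                         endline[[paste0(factors[2], "_score")]],
                         "endline cross-factor"))
  }
  structure(list(sad = sad, cross_wave_r = cross_wave_r,
                 cross_factor_r = cross_factor_r, n = nrow(baseline)),
            class = "change_report")
}

#' @export
print.change_report <- function(x, ...) {
  cat("Baseline-vs-endline change metrics (", x$n, " facilities)\n", sep = "")
  for (f in names(x$sad))
    cat(sprintf("  %-12s sum |diff| = %6.2f   cross-wave r = %s\n", f,
                x$sad[f], formatC(x$cross_wave_r[f], digits = 3,
                                  format = "f")))
  if (!is.null(x$cross_factor_r))
    cat(sprintf("  cross-factor r: baseline %.3f, endline %.3f\n",
                x$cross_factor_r["baseline"], x$cross_factor_r["endline"]))
  invisible(x)
}

#' Write / read a facility score table CSV
#'
#' Wide CSV with `facility_id`, `wave`, optional `country`, and per factor
#' `<factor>_score`, `<factor>_se`, `<factor>_rank`, `<factor>_rescaled`.
#'
#' @param x a `factor_scores` data frame.
#' @param path CSV path.
#' @param factors factor names expected when reading; default auto-detected
#'   from `<name>_score` columns.
#' @return `read_scores()` returns a `factor_scores` data frame.
#' @export
write_scores <- function(x, path) {
  utils::write.csv(as.data.frame(x), path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_scores
#' @export
read_scores <- function(path, factors = NULL) {
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("facility_id", "wave") %in% names(x)))
    stop(path, ": needs facility_id and wave columns", call. = FALSE)
  if (is.null(factors))
    factors <- sub("_score$", "", grep("_score$", names(x), value = TRUE))
  if (length(factors) == 0L)
    stop(path, ": no <factor>_score columns found", call. = FALSE)
  x$facility_id <- as.character(x$facility_id)
  attr(x, "factors") <- factors
  class(x) <- c("factor_scores", "data.frame")
  x
}
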