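#' Default generating loadings for the synthetic study
#'
#' Standardized loadings used by the synthetic generator: a strongly
#' measured two-factor structure in which four functional indicators load on
#' one factor and four structural indicators on the other, calibrated to the
#' magnitudes observed for baseline facility-integration indexes of this
#' kind.
#'
#' @return Named numeric vector (by attribute) of standardized loadings.
#' @export
default_loadings <- function() {
  c(unit_availability = 0.952, facility_availability = 0.617,
    room_range = 0.795, art_location_score = 0.489,
    temporal_range = 0.774, provider_range = 0.836,
    consult_integration = 0.979, visit_integration = 0.984)
}

default_ncat <- function() {
  c(unit_availability = 3L, facility_availability = 3L, room_range = 3L,
    art_location_score = 4L, temporal_range = 3L, provider_range = 3L,
    consult_integration = 3L, visit_integration = 3L)
}

#' Generate true latent factor scores
#'
#' Facility scores are drawn independently standard-normal per factor
#' (orthogonal dimensions).  For a two-wave study, wave-2 scores follow a
#' mean-reverting change model
#' \eqn{\eta_2 = (1-\kappa)\eta_1 + \epsilon} with
#' \eqn{\epsilon \sim N(0, 1-(1-\kappa)^2)}, which keeps the marginal
#' variance at 1 and gives cross-wave correlation \eqn{1-\kappa}.  Defaults
#' \eqn{\kappa = 0.5} for the functional factor and \eqn{\kappa = 0.1} for
#' the structural factor emulate the common pattern that client-level
#' service delivery regresses to the mean faster than infrastructure.
#'
#' @param n_facilities number of facilities (default 40).
#' @param n_factors 1 or 2.
#' @param waves 1 or 2.
#' @param kappa per-factor mean-reversion coefficient(s) in `[0, 1]`.
#' @param seed seed.
#' @return A list of `waves` matrices (`n_facilities` x `n_factors`) of true
#'   scores, with factor column names.
#' @export
generate_latent <- function(n_facilities = 40, n_factors = 2, waves = 2,
                            kappa = c(functional = 0.5, structural = 0.1),
                            seed = 1) {
  factors <- if (n_factors == 2) c("functional", "structural") else "integration"
  kappa <- rep_len(as.numeric(kappa), n_factors)
  if (any(kappa < 0 | kappa > 1)) stop("kappa must be in [0, 1]", call. = FALSE)
  set.seed(seed)
  eta1 <- matrix(stats::rnorm(n_facilities * n_factors), n_facilities,
                 dimnames = list(NULL, factors))
  out <- list(eta1)
  if (waves == 2) {
    rho <- 1 - kappa
    noise <- matrix(stats::rnorm(n_facilities * n_factors), n_facilities)
    eta2 <- sweep(eta1, 2, rho, `*`) +
      sweep(noise, 2, sqrt(1 - rho^2), `*`)
    colnames(eta2) <- factors
    out <- list(eta1, eta2)
  }
  names(out) <- paste0("wave", seq_along(out))
  out
}

#' Generate ordinal indicators from true latent scores
#'
#' Runs the probit measurement model generatively: raw loadings are obtained
#' from standardized ones via \eqn{\lambda = s/\sqrt{1-s^2}}, the latent
#' response is \eqn{\lambda \eta + N(0,1)}, and categories are cut at
#' thresholds.  Default thresholds give equal-probability categories on the
#' marginal scale of the latent response.
#'
#' @param eta matrix of true scores (facilities x factors) from
#'   [generate_latent()].
#' @param loadings_std named standardized loadings in `(-1, 1)`; default
#'   [default_loadings()] (for one-factor `eta`, the same magnitudes all on
#'   the single factor).
#' @param n_cat named per-indicator category counts; default
#'   3 categories everywhere except the 4-level treatment-location score.
#' @param thresholds optional named list of threshold vectors on the raw
#'   latent-response scale; overrides the equal-probability default.
#' @param wave wave label for the resulting matrix.
#' @param seed seed (regeneration with the same inputs is deterministic).
#' @return An `indicator_matrix`.
#' @export
generate_indicators <- function(eta, loadings_std = default_loadings(),
                                n_cat = default_ncat(), thresholds = NULL,
                                wave = "baseline", seed = 1) {
  if (any(abs(loadings_std) >= 1))
    stop("standardized loadings must have |s| < 1", call. = FALSE)
  nms <- names(loadings_std)
  n <- nrow(eta)
  lam_raw <- loadings_std / sqrt(1 - loadings_std^2)
  factor_of <- if (ncol(eta) == 1) stats::setNames(rep(1L, length(nms)), nms)
  else stats::setNames(ifelse(nms %in% functional_attributes(), 1L, 2L), nms)

  set.seed(seed)
  x <- matrix(NA_integer_, n, length(nms), dimnames = list(NULL, nms))
  for (j in seq_along(nms)) {
    nm <- nms[j]
    lam <- lam_raw[nm]
    ystar <- lam * eta[, factor_of[nm]] + stats::rnorm(n)
    K <- n_cat[[nm]]
    tj <- if (!is.null(thresholds) && !is.null(thresholds[[nm]]))
      thresholds[[nm]]
    else sqrt(lam^2 + 1) * stats::qnorm(seq_len(K - 1) / K)
    x[, j] <- as.integer(rowSums(outer(ystar, tj, ">")))
  }
  indicator_matrix(x, facility_id = sprintf("F%02d", seq_len(n)),
                   wave = wave, ncat = vapply(nms, function(nm) n_cat[[nm]],
                                              integer(1)))
}

# map latent scores to per-facility attribute targets (probit squash with
# spread chosen to occupy most of the unit interval across eta ~ N(0,1))
targets_from_latent <- function(eta) {
  pr <- function(z, a, b) stats::pnorm(a + b * z)
  f <- eta[, "functional"]; s <- eta[, "structural"]
  visit <- pr(f, 0.1, 0.9)
  consult <- visit * pr(f, 0.6, 0.5)
  temporal <- pmax(visit + 0.05, pr(f, 0.8, 0.8))
  temporal <- pmin(temporal, 1)
  art_frac <- pr(f, -0.2, 0.7)
  data.frame(
    facility_id = sprintf("F%02d", seq_len(nrow(eta))),
    unit_availability = pr(s, 0.3, 1.0),
    facility_availability = pr(s, 0.8, 0.7),
    room_range = pr(s, 0.0, 0.9),
    provider_range = pr(s, 0.1, 0.9),
    temporal_range = temporal,
    consult_integration = consult,
    visit_integration = visit,
    art_score_fraction = art_frac,
    stringsAsFactors = FALSE)
}

#' Generate client-flow records and inventories matching attribute targets
#'
#' Builds a per-facility client-flow dataset and facility inventory whose
#' *expected* computed attributes equal the given targets.  The flow layer is
#' a fixture with a simple conditional-independence service model, not a
#' behavioural simulation:
#'
#' * a share `consult_integration` of clients receives an RH and an
#'   HIV-related service in one contact;
#' * a further share receives the two classes from different providers on
#'   the same day (raising visit-level but not consultation-level
#'   integration to `visit_integration`);
#' * HIV-related delivery is confined to a random subset of days of the
#'   window (Bernoulli per day with the `temporal_range` target);
#' * the HIV service of integrated clients is antiretroviral therapy for a
#'   calibrated fraction of clients, realising the expected
#'   treatment-location score; some non-integrated clients are referred for
#'   treatment;
#' * inventories list each service independently with probability equal to
#'   the availability targets, and room/staff logs carry each HIV-related
#'   service with probability equal to the range targets.
#'
#' Feasibility requires `consult <= visit <= temporal` targets; infeasible
#' combinations are rejected.
#'
#' @param targets data frame from `targets_from_latent()` or with the same
#'   columns (`facility_id`, the seven proportion targets, and
#'   `art_score_fraction`, the fraction of the maximum attainable
#'   treatment-location score to realise).
#' @param clients_per_day expected clients per facility-day (default 20).
#' @param n_days observation window (default 5).
#' @param n_rooms,n_staff rooms and staff logged per facility.
#' @param seed seed.
#' @return A list with `flow` (a [client_flow()]) and `inventories` (named
#'   list of [facility_inventory()]), plus the realised `targets`.
#' @export
generate_flow <- function(targets, clients_per_day = 20, n_days = 5,
                          n_rooms = 2, n_staff = 3, seed = 1) {
  bad <- targets$consult_integration > targets$visit_integration + 1e-12
  if (any(bad))
    stop("infeasible targets for facility ",
         paste(targets$facility_id[bad], collapse = ", "),
         ": consultation integration exceeds visit integration",
         call. = FALSE)
  bad <- targets$visit_integration > targets$temporal_range + 1e-12
  if (any(bad))
    stop("infeasible targets for facility ",
         paste(targets$facility_id[bad], collapse = ", "),
         ": visit integration exceeds the share of days with HIV delivery",
         call. = FALSE)
  targets$art_score_expected <- targets$art_score_fraction *
    (3 * targets$consult_integration +
       2 * (targets$visit_integration - targets$consult_integration) +
       1 * (1 - targets$visit_integration))
  set.seed(seed)
  rows <- list()
  inventories <- list()
  for (i in seq_len(nrow(targets))) {
    tg <- targets[i, ]
    fid <- tg$facility_id
    # HIV-active days
    hiv_day <- stats::runif(n_days) < tg$temporal_range
    q <- tg$temporal_range
    # per-client probabilities conditional on being seen on an HIV day
    p_c <- min(tg$consult_integration / max(q, 1e-9), 1)
    p_v <- min(tg$visit_integration / max(q, 1e-9), 1)
    # treatment-location overlay: max attainable mean score given the split
    max_art <- 3 * tg$consult_integration + 2 *
      (tg$visit_integration - tg$consult_integration) +
      1 * (1 - tg$visit_integration)
    s_art <- tg$art_score_fraction
    cl <- 0L
    for (d in seq_len(n_days)) {
      ncl <- stats::rpois(1, clients_per_day)
      if (ncl == 0L) next
      for (k in seq_len(ncl)) {
        cl <- cl + 1L
        cid <- sprintf("%s_c%04d", fid, cl)
        u <- stats::runif(1)
        use_art <- stats::runif(1) < s_art
        refer <- stats::runif(1) < s_art
        if (hiv_day[d] && u < p_c) {
          # both classes in a single contact
          hiv_sv <- if (use_art) "ART" else "HIV_TEST"
          rows[[length(rows) + 1L]] <- list(fid, d, cid, "p1",
                                            paste("FP", hiv_sv, sep = ";"), "")
        } else if (hiv_day[d] && u < p_v) {
          # both classes, different providers
          hiv_sv <- if (use_art) "ART" else "HIV_TEST"
          rows[[length(rows) + 1L]] <- list(fid, d, cid, "p1", "ANC", "")
          rows[[length(rows) + 1L]] <- list(fid, d, cid, "p2", hiv_sv, "")
        } else {
          # RH only, possibly referred for treatment
          rows[[length(rows) + 1L]] <- list(fid, d, cid, "p1", "FP",
                                            if (refer) "ART" else "")
        }
      }
      # guarantee the day's HIV-active status is realised
      if (hiv_day[d]) {
        cl <- cl + 1L
        rows[[length(rows) + 1L]] <- list(fid, d,
                                          sprintf("%s_c%04d", fid, cl),
                                          "p2", "HIV_TEST", "")
      }
    }
    # inventories: independent Bernoulli per service at the target rate
    hs <- hiv_services()
    unit <- hs[stats::runif(5) < tg$unit_availability]
    fac <- integration_services()[stats::runif(8) < tg$facility_availability]
    room_logs <- lapply(seq_len(n_rooms), function(r)
      hs[stats::runif(5) < tg$room_range])
    names(room_logs) <- paste0("r", seq_len(n_rooms))
    staff_logs <- lapply(seq_len(n_staff), function(s)
      hs[stats::runif(5) < tg$provider_range])
    names(staff_logs) <- paste0("s", seq_len(n_staff))
    inventories[[fid]] <- suppressWarnings(
      facility_inventory(fid, unit, fac, room_logs, staff_logs))
  }
  df <- do.call(rbind, lapply(rows, function(r)
    data.frame(facility_id = r[[1]], day = r[[2]], client_id = r[[3]],
               provider_id = r[[4]], services = r[[5]], referrals = r[[6]],
               stringsAsFactors = FALSE)))
  list(flow = client_flow(df), inventories = inventories, targets = targets)
}

#' Simulate a complete synthetic facility study
#'
#' Generates true latent scores, per-wave ordinal indicator matrices and
#' (optionally) client-flow/inventory records for a two-wave, 40-facility
#' study with two orthogonal latent factors driving four functional and four
#' structural indicators, so that every stage of the pipeline can be tested
#' against known truth.
#'
#' @param n_facilities facilities (default 40).
#' @param n_factors 1 or 2 (default 2).
#' @param waves 1 or 2 (default 2).
#' @param loadings_std,n_cat,kappa see [generate_indicators()] and
#'   [generate_latent()].
#' @param flow also generate the client-flow/inventory layer (slower;
#'   default `FALSE`).
#' @param clients_per_day passed to [generate_flow()].
#' @param seed master seed; layer seeds are derived deterministically.
#' @return A list of class `synthetic_study`: `truth` (latent scores per
#'   wave), `indicators` (list per wave), optionally `flow` and
#'   `inventories` per wave, and the generating parameters.
#' @export
simulate_study <- function(n_facilities = 40, n_factors = 2, waves = 2,
                           loadings_std = default_loadings(),
                           n_cat = default_ncat(),
                           kappa = c(functional = 0.5, structural = 0.1),
                           flow = FALSE, clients_per_day = 20, seed = 1) {
  set.seed(seed)
  layer_seeds <- sample.int(.Machine$integer.max - 1L, 1L + 2L * waves)
  truth <- generate_latent(n_facilities, n_factors, waves, kappa,
                           seed = layer_seeds[1])
  wave_names <- c("baseline", "endline")[seq_len(waves)]
  indicators <- lapply(seq_len(waves), function(w)
    generate_indicators(truth[[w]], loadings_std, n_cat,
                        wave = wave_names[w], seed = layer_seeds[1 + w]))
  names(indicators) <- wave_names
  out <- list(truth = truth, indicators = indicators,
              loadings_std = loadings_std, n_cat = n_cat, kappa = kappa,
              seed = seed)
  if (flow) {
    if (n_factors != 2)
      stop("the flow layer requires the two-factor structure", call. = FALSE)
    fl <- lapply(seq_len(waves), function(w)
      generate_flow(targets_from_latent(truth[[w]]),
                    clients_per_day = clients_per_day,
                    seed = layer_seeds[1 + waves + w]))
    out$flow <- lapply(fl, `[[`, "flow")
    out$inventories <- lapply(fl, `[[`, "inventories")
    out$targets <- lapply(fl, `[[`, "targets")
    names(out$flow) <- names(out$inventories) <- names(out$targets) <- wave_names
  }
  class(out) <- "synthetic_study"
  out
}

#' @export
print.synthetic_study <- function(x, ...) {
  cat("Synthetic facility study:", nrow(x$truth[[1]]), "facilities,",
      length(x$truth), "wave(s),", ncol(x$truth[[1]]), "factor(s)\n")
  cat("indicators per wave:", paste(names(x$indicators), collapse = ", "),
      if (!is.null(x$flow)) "(with client-flow layer)" else "", "\n")
  invisible(x)
}
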