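#' Ordinalization schemes
#'
#' The measurement model consumes ordinal categories, so each continuous
#' attribute must be coded.  A scheme assigns one rule per attribute:
#'
#' * `rule_quantile(k)`: `k` categories cut at the pooled empirical
#'   `1/k, ..., (k-1)/k` quantiles.  Values equal to a cutpoint go to the
#'   lower category (deterministic tie-break).
#' * `rule_cutpoints(cuts)`: fixed ascending cutpoints.
#' * `rule_as_is(fallback_k)`: values already categorical; distinct values
#'   are compressed to contiguous integers starting at 0.  If the values are
#'   not integral (e.g. a facility mean of client-level scores), the rule
#'   falls back to `rule_quantile(fallback_k)`.
#'
#' `default_scheme()` codes every attribute with `rule_quantile(3)` except
#' the HIV-treatment-location score, which keeps its native 0-3 scale via
#' `rule_as_is(4)`.
#'
#' @param k number of categories (>= 2).
#' @param cuts strictly ascending numeric cutpoints.
#' @param fallback_k categories used when `rule_as_is` meets non-integral
#'   values.
#' @param ... named per-attribute rule overrides.
#' @return A named list of rules covering all eight attributes
#'   (`default_scheme`/`ordinal_scheme`) or a single rule (`rule_*`).
#' @export
rule_quantile <- function(k = 3) {
  stopifnot(k >= 2)
  structure(list(type = "quantile", k = as.integer(k)), class = "ordinal_rule")
}

#' @rdname rule_quantile
#' @export
rule_cutpoints <- function(cuts) {
  cuts <- as.numeric(cuts)
  if (length(cuts) < 1L || is.unsorted(cuts, strictly = TRUE))
    stop("cutpoints must be strictly ascending", call. = FALSE)
  structure(list(type = "cutpoints", cuts = cuts), class = "ordinal_rule")
}

#' @rdname rule_quantile
#' @export
rule_as_is <- function(fallback_k = 4) {
  structure(list(type = "as_is", fallback_k = as.integer(fallback_k)),
            class = "ordinal_rule")
}

#' @rdname rule_quantile
#' @export
default_scheme <- function() {
  rules <- stats::setNames(rep(list(rule_quantile(3)), 8), attribute_names())
  rules$art_location_score <- rule_as_is(4)
  rules
}

#' @rdname rule_quantile
#' @export
ordinal_scheme <- function(...) {
  rules <- default_scheme()
  over <- list(...)
  bad <- setdiff(names(over), attribute_names())
  if (length(bad) > 0L)
    stop("unknown attribute(s) in scheme: ", paste(bad, collapse = ", "),
         call. = FALSE)
  for (nm in names(over)) {
    if (!inherits(over[[nm]], "ordinal_rule"))
      stop("scheme entry for ", nm, " is not an ordinal rule", call. = FALSE)
    rules[[nm]] <- over[[nm]]
  }
  rules
}

# apply one rule to a numeric vector; returns list(cat, cuts, ncat)
apply_rule <- function(values, rule, name) {
  obs <- values[!is.na(values)]
  if (length(obs) == 0L)
    stop("attribute ", name, " has no observed values", call. = FALSE)
  if (rule$type == "as_is") {
    if (all(abs(obs - round(obs)) < 1e-8)) {
      lev <- sort(unique(round(obs)))
      cat <- match(round(values), lev) - 1L
      return(list(cat = cat, cuts = utils::head(lev, -1) + 0.5,
                  ncat = length(lev)))
    }
    rule <- rule_quantile(rule$fallback_k)
  }
  cuts <- if (rule$type == "quantile") {
    unique(as.numeric(stats::quantile(obs, probs = seq_len(rule$k - 1) / rule$k,
                                      names = FALSE)))
  } else {
    rule$cuts
  }
  # strictly-greater comparison sends boundary ties to the lower category
  cat <- rowSums(outer(values, cuts, ">"))
  cat[is.na(values)] <- NA
  list(cat = as.integer(cat), cuts = cuts, ncat = length(cuts) + 1L)
}

#' Code an attribute table as an ordinal indicator matrix
#'
#' Applies an ordinalization scheme to each of the eight attributes, pooling
#' all rows (so both study waves, when present, share identical cutpoints —
#' a requirement for cross-wave score comparability).  The mapping is
#' monotone: larger attribute values never receive smaller categories.
#'
#' @param table an `attribute_table` (any number of waves).
#' @param scheme a scheme from [ordinal_scheme()]; default [default_scheme()].
#' @return An object of class `indicator_matrix`: integer matrix `x`
#'   (facility-wave rows by 8 indicators, categories `0..ncat-1`, `NA`
#'   allowed), with `facility_id`, `wave`, per-indicator `ncat`, the realized
#'   `cutpoints`, and the `scheme`.
#' @examples
#' tab <- data.frame(facility_id = c("a", "b", "c", "d"), wave = "baseline",
#'                   matrix(runif(32), 4, 8,
#'                          dimnames = list(NULL, attribute_names())))
#' class(tab) <- c("attribute_table", "data.frame")
#' im <- ordinalize(tab, ordinal_scheme(
#'   art_location_score = rule_cutpoints(c(0.25, 0.5, 0.75))))
#' im$ncat
#' @export
ordinalize <- function(table, scheme = default_scheme()) {
  an <- attribute_names()
  miss <- setdiff(an, names(scheme))
  if (length(miss) > 0L)
    stop("scheme does not cover attribute(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  x <- matrix(NA_integer_, nrow(table), length(an),
              dimnames = list(NULL, an))
  ncat <- stats::setNames(integer(length(an)), an)
  cutpoints <- stats::setNames(vector("list", length(an)), an)
  for (nm in an) {
    res <- apply_rule(table[[nm]], scheme[[nm]], nm)
    nobs <- length(unique(res$cat[!is.na(res$cat)]))
    if (nobs < 2L)
      stop("indicator ", nm, " collapses to a single observed category; ",
           "refine its ordinalization rule", call. = FALSE)
    x[, nm] <- res$cat
    ncat[nm] <- res$ncat
    cutpoints[[nm]] <- res$cuts
  }
  structure(list(x = x, facility_id = as.character(table$facility_id),
                 wave = as.character(table$wave), ncat = ncat,
                 cutpoints = cutpoints, scheme = scheme),
            class = "indicator_matrix")
}

#' Construct an indicator matrix directly
#'
#' Used when categories come from a source other than [ordinalize()] (e.g.
#' the synthetic generator).
#'
#' @param x integer matrix of categories (`0`-based), columns named by
#'   [attribute_names()] (or any indicator names).
#' @param facility_id,wave row identifiers (recycled if length 1).
#' @param ncat per-indicator category counts; default inferred as
#'   `max(x) + 1` per column.
#' @return An `indicator_matrix`.
#' @export
indicator_matrix <- function(x, facility_id = NULL, wave = "baseline",
                             ncat = NULL) {
  x <- as.matrix(x)
  storage.mode(x) <- "integer"
  if (is.null(colnames(x))) colnames(x) <- attribute_names()[seq_len(ncol(x))]
  if (is.null(facility_id)) facility_id <- sprintf("F%02d", seq_len(nrow(x)))
  if (length(wave) == 1L) wave <- rep(wave, nrow(x))
  if (is.null(ncat))
    ncat <- apply(x, 2, function(v) max(v, na.rm = TRUE) + 1L)
  ncat <- stats::setNames(as.integer(ncat), colnames(x))
  for (j in seq_len(ncol(x))) {
    v <- x[, j]
    if (any(v[!is.na(v)] < 0L) || any(v[!is.na(v)] >= ncat[j]))
      stop("indicator ", colnames(x)[j], ": categories outside 0..",
           ncat[j] - 1L, call. = FALSE)
  }
  structure(list(x = x, facility_id = as.character(facility_id),
                 wave = as.character(wave), ncat = ncat,
                 cutpoints = NULL, scheme = NULL),
            class = "indicator_matrix")
}

#' @export
print.indicator_matrix <- function(x, ...) {
  cat("Ordinal indicator matrix:", nrow(x$x), "facility-waves x",
      ncol(x$x), "indicators\n")
  cat("categories per indicator:\n")
  print(x$ncat)
  invisible(x)
}

# subset rows of an indicator matrix
im_subset <- function(im, rows) {
  structure(list(x = im$x[rows, , drop = FALSE],
                 facility_id = im$facility_id[rows], wave = im$wave[rows],
                 ncat = im$ncat, cutpoints = im$cutpoints,
                 scheme = im$scheme),
            class = "indicator_matrix")
}
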