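#' Client-flow datasets
#'
#' A client-flow dataset holds one row per provider contact: a client seen by
#' one provider on one day, with the set of services received and the set of
#' services the client was referred for in that contact.  It is the raw
#' material for the functional integration attributes (co-receipt of RH and
#' HIV-related services within a consultation or a one-day visit, the
#' HIV-treatment-location score, and day-level co-delivery).
#'
#' @param x a data frame with columns `facility_id`, `day`, `client_id`,
#'   `provider_id`, `services`, `referrals`.  `services`/`referrals` may be
#'   semicolon-delimited strings or list columns of character vectors.
#' @param allow_overlap if `FALSE` (default) a service appearing in both the
#'   received and the referred set of one contact is an error.
#' @return An object of class `client_flow`: the validated data frame with
#'   list columns `services` and `referrals`.
#' @examples
#' cf <- client_flow(data.frame(
#'   facility_id = "F1", day = 1, client_id = "c1", provider_id = "p1",
#'   services = "FP;HIV_TEST", referrals = ""))
#' nrow(cf)
#' @export
client_flow <- function(x, allow_overlap = FALSE) {
  req <- c("facility_id", "day", "client_id", "provider_id",
           "services", "referrals")
  miss <- setdiff(req, names(x))
  if (length(miss) > 0L)
    stop("client flow data lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  x <- as.data.frame(x)[req]
  x$facility_id <- as.character(x$facility_id)
  x$client_id <- as.character(x$client_id)
  x$provider_id <- as.character(x$provider_id)
  x$day <- as.integer(x$day)
  if (anyNA(x$day)) stop("non-integer day values in client flow", call. = FALSE)
  if (!is.list(x$services)) x$services <- split_codes(as.character(x$services))
  if (!is.list(x$referrals)) x$referrals <- split_codes(as.character(x$referrals))

  all_sv <- unlist(x$services, use.names = FALSE)
  all_rf <- unlist(x$referrals, use.names = FALSE)
  validate_service_codes(all_sv, "service")
  validate_service_codes(all_rf, "referral")

  if (!allow_overlap) {
    ov <- mapply(function(s, r) length(intersect(s, r)) > 0L,
                 x$services, x$referrals)
    if (any(ov))
      stop("row(s) ", paste(which(ov), collapse = ", "),
           ": service present in both received and referred sets ",
           "(set allow_overlap = TRUE to permit)", call. = FALSE)
  }

  class(x) <- c("client_flow", "data.frame")
  x
}

#' Read a client-flow CSV file
#'
#' Expected columns: `facility_id`, `day`, `client_id`, `provider_id`,
#' `services`, `referrals`; the two set-valued columns are
#' semicolon-delimited code lists (may be empty).  Unknown service codes are
#' rejected with the offending rows named; exact duplicate contact rows are
#' dropped with a warning.
#'
#' @param path path to a CSV file (UTF-8, header row required).
#' @param allow_overlap passed to [client_flow()].
#' @return A [client_flow()] object.
#' @export
read_client_flow <- function(path, allow_overlap = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  x <- utils::read.csv(path, stringsAsFactors = FALSE,
                       colClasses = "character")
  req <- c("facility_id", "day", "client_id", "provider_id",
           "services", "referrals")
  miss <- setdiff(req, names(x))
  if (length(miss) > 0L)
    stop(path, ": missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)

  # row-wise code validation so errors carry line numbers
  sv <- split_codes(x$services)
  rf <- split_codes(x$referrals)
  known <- integration_services()
  bad_rows <- which(vapply(sv, function(v) any(!v %in% known), logical(1)) |
                    vapply(rf, function(v) any(!v %in% known), logical(1)))
  if (length(bad_rows) > 0L) {
    codes <- unique(setdiff(unlist(c(sv[bad_rows], rf[bad_rows])), known))
    stop(path, ": unknown service code(s) ", paste(codes, collapse = ", "),
         " in data row(s) ", paste(bad_rows, collapse = ", "), call. = FALSE)
  }

  key <- do.call(paste, c(x[req], sep = "\r"))
  dup <- duplicated(key)
  if (any(dup)) {
    warning(path, ": dropped ", sum(dup), " duplicated contact row(s)",
            call. = FALSE)
    x <- x[!dup, , drop = FALSE]
  }
  client_flow(x, allow_overlap = allow_overlap)
}

# split a client_flow into per-facility groups
split_by_facility <- function(flow) {
  split(seq_len(nrow(flow)), flow$facility_id)
}

# visit key: one client on one day at one facility
visit_key <- function(flow) paste(flow$facility_id, flow$day, flow$client_id,
                                  sep = "\r")
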