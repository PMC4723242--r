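#' Names of the eight integration attributes
#'
#' Canonical order used throughout the package: four structural attributes
#' (availability and provision capacity) and four functional attributes
#' (actual co-delivery and co-receipt).
#'
#' @return Character vector of length 8.
#' @export
attribute_names <- function() {
  c("unit_availability", "facility_availability", "room_range",
    "art_location_score", "temporal_range", "provider_range",
    "consult_integration", "visit_integration")
}

# attribute -> latent factor in the two-factor structure
functional_attributes <- function() {
  c("art_location_score", "temporal_range", "consult_integration",
    "visit_integration")
}
structural_attributes <- function() {
  c("unit_availability", "facility_availability", "provider_range",
    "room_range")
}

na_with_warning <- function(msg) {
  warning(msg, call. = FALSE)
  structure(NA_real_, denominator = NA_integer_)
}

with_denom <- function(value, n) structure(value, denominator = as.integer(n))

#' Structural availability attributes
#'
#' `compute_unit_availability()` is the share of the five HIV-related
#' services available in the MCH/FP unit; `compute_facility_availability()`
#' is the share of all eight RH and HIV-related services available anywhere
#' in the facility.
#'
#' @param inv a [facility_inventory()].
#' @return A number in `[0, 1]` with attribute `denominator`, or `NA` with a
#'   warning when the underlying record is missing.
#' @examples
#' inv <- facility_inventory("F1",
#'   unit_services = c("HIV_TEST", "STI_TREAT"),
#'   facility_services = c("FP", "ANC", "PNC", "HIV_TEST"))
#' compute_unit_availability(inv)      # 2/5
#' compute_facility_availability(inv)  # 4/8
#' @export
compute_unit_availability <- function(inv) {
  if (is.null(inv$unit_services))
    return(na_with_warning(paste0("facility ", inv$facility_id,
                                  ": no MCH/FP unit service record")))
  with_denom(length(intersect(inv$unit_services, hiv_services())) / 5, 5)
}

#' @rdname compute_unit_availability
#' @export
compute_facility_availability <- function(inv) {
  if (is.null(inv$facility_services))
    return(na_with_warning(paste0("facility ", inv$facility_id,
                                  ": no facility-wide service record")))
  with_denom(length(intersect(inv$facility_services,
                              integration_services())) / 8, 8)
}

#' Room- and provider-level provision range
#'
#' `compute_room_range()` averages, over MCH/FP consultation rooms, the share
#' of the five HIV-related services provided in each room.
#' `compute_provider_range()` does the same over MCH/FP clinical staff
#' members (services provided per staff member in a day).  Both use an
#' unweighted mean across rooms/staff.
#'
#' @param inv a [facility_inventory()].
#' @return A number in `[0, 1]` with attribute `denominator` (the number of
#'   rooms/staff averaged over), or `NA` with a warning when no logs exist.
#' @export
compute_room_range <- function(inv) {
  if (length(inv$room_logs) == 0L)
    return(na_with_warning(paste0("facility ", inv$facility_id,
                                  ": no consultation room logs")))
  shares <- vapply(inv$room_logs,
                   function(v) length(intersect(v, hiv_services())) / 5,
                   numeric(1))
  with_denom(mean(shares), length(shares))
}

#' @rdname compute_room_range
#' @export
compute_provider_range <- function(inv) {
  if (length(inv$staff_logs) == 0L)
    return(na_with_warning(paste0("facility ", inv$facility_id,
                                  ": no staff service logs")))
  shares <- vapply(inv$staff_logs,
                   function(v) length(intersect(v, hiv_services())) / 5,
                   numeric(1))
  with_denom(mean(shares), length(shares))
}

#' Day-level co-delivery of RH and HIV-related services
#'
#' The share of days in the observation window on which at least one RH
#' service and at least one HIV-related service were received by any client.
#'
#' @param flow a [client_flow()] restricted to one facility.
#' @param n_days length of the observation window (default 5, the standard
#'   five-day client-flow assessment).
#' @return A number in `[0, 1]` with attribute `denominator` = `n_days`.
#' @export
compute_temporal_range <- function(flow, n_days = 5) {
  if (n_days < 1) stop("n_days must be >= 1", call. = FALSE)
  days <- unique(flow$day)
  if (length(days) > n_days)
    stop("observed ", length(days), " distinct days but n_days = ", n_days,
         " (inconsistent observation window)", call. = FALSE)
  if (nrow(flow) == 0L)
    return(na_with_warning("empty client flow: temporal range undefined"))
  both <- vapply(days, function(d) {
    sv <- unlist(flow$services[flow$day == d], use.names = FALSE)
    has_any(sv, rh_services()) && has_any(sv, hiv_services())
  }, logical(1))
  with_denom(sum(both) / n_days, n_days)
}

# per-visit client summaries used by the three client-level attributes
visit_summaries <- function(flow) {
  if (nrow(flow) == 0L) return(NULL)
  keys <- visit_key(flow)
  idx <- split(seq_len(nrow(flow)), keys)
  t(vapply(idx, function(ii) {
    sv <- flow$services[ii]
    rf <- unlist(flow$referrals[ii], use.names = FALSE)
    all_sv <- unlist(sv, use.names = FALSE)
    consult <- any(vapply(sv, function(v)
      has_any(v, rh_services()) && has_any(v, hiv_services()), logical(1)))
    visit <- has_any(all_sv, rh_services()) && has_any(all_sv, hiv_services())
    art_same <- any(vapply(sv, function(v)
      "ART" %in% v && has_any(v, srh_services()), logical(1)))
    art_any <- "ART" %in% all_sv
    art_ref <- "ART" %in% rf
    any_srh <- has_any(all_sv, srh_services())
    any_service <- length(all_sv) > 0L
    c(consult = consult, visit = visit, art_same = art_same,
      art_any = art_any, art_ref = art_ref, any_srh = any_srh,
      any_service = any_service)
  }, logical(7)))
}

#' Client-level co-receipt of RH and HIV-related services
#'
#' `compute_consult_integration()` is the share of clients with at least one
#' single provider contact in which both an RH and an HIV-related service
#' were received.  `compute_visit_integration()` is the share of clients
#' whose union of services over all contacts of the one-day visit contains
#' both classes.  Consultation-level integration implies visit-level
#' integration, so the former never exceeds the latter.
#'
#' @param flow a [client_flow()] restricted to one facility.
#' @param eligible denominator population: `"all"` (default) counts every
#'   tracked client; `"any_service"` restricts to clients who received at
#'   least one service.
#' @return A number in `[0, 1]` with attribute `denominator` (number of
#'   clients), or `NA` with a warning for an empty dataset.
#' @examples
#' cf <- client_flow(data.frame(
#'   facility_id = "F1", day = 1, client_id = c("a", "a", "b"),
#'   provider_id = c("p1", "p2", "p1"),
#'   services = c("FP", "HIV_TEST", "ANC"), referrals = ""))
#' compute_consult_integration(cf)  # client a never in one contact: 0
#' compute_visit_integration(cf)    # client a across the day: 1/2
#' @export
compute_consult_integration <- function(flow, eligible = c("all", "any_service")) {
  eligible <- match.arg(eligible)
  vs <- visit_summaries(flow)
  if (is.null(vs))
    return(na_with_warning("empty client flow: consultation integration undefined"))
  if (eligible == "any_service") vs <- vs[vs[, "any_service"], , drop = FALSE]
  if (nrow(vs) == 0L)
    return(na_with_warning("no eligible clients for consultation integration"))
  with_denom(mean(vs[, "consult"]), nrow(vs))
}

#' @rdname compute_consult_integration
#' @export
compute_visit_integration <- function(flow, eligible = c("all", "any_service")) {
  eligible <- match.arg(eligible)
  vs <- visit_summaries(flow)
  if (is.null(vs))
    return(na_with_warning("empty client flow: visit integration undefined"))
  if (eligible == "any_service") vs <- vs[vs[, "any_service"], , drop = FALSE]
  if (nrow(vs) == 0L)
    return(na_with_warning("no eligible clients for visit integration"))
  with_denom(mean(vs[, "visit"]), nrow(vs))
}

#' HIV treatment location and referral score
#'
#' Each client visit is scored on a 0-3 scale describing where antiretroviral
#' therapy (ART) sits relative to the client's other care:
#' 0 = no ART received and no ART referral; 1 = referred for ART but not
#' received during the visit; 2 = ART received, either alone or alongside
#' other services from a different provider; 3 = ART received together with
#' an SRH service (FP/ANC/PNC/STI treatment) from the same provider.
#' The facility value is the mean client score.
#'
#' @param flow a [client_flow()] restricted to one facility.
#' @param population clients entering the mean: `"all"` (default) or `"srh"`
#'   (clients who received at least one SRH service).
#' @return A number in `[0, 3]` with attribute `denominator` (number of
#'   clients scored).
#' @export
compute_art_score <- function(flow, population = c("all", "srh")) {
  population <- match.arg(population)
  vs <- visit_summaries(flow)
  if (is.null(vs))
    return(na_with_warning("empty client flow: ART location score undefined"))
  if (population == "srh") vs <- vs[vs[, "any_srh"], , drop = FALSE]
  if (nrow(vs) == 0L)
    return(na_with_warning("no eligible clients for ART location score"))
  score <- ifelse(vs[, "art_same"], 3,
                  ifelse(vs[, "art_any"], 2,
                         ifelse(vs[, "art_ref"], 1, 0)))
  with_denom(mean(score), nrow(vs))
}

#' Build the facility-by-attribute table for one study wave
#'
#' Computes all eight integration attributes for every facility appearing in
#' the client-flow data or the inventory set.  Facilities present in only
#' one source get rows with the unavailable attributes missing (flagged by a
#' warning, never silently zero-filled).
#'
#' @param flow a [client_flow()] covering all facilities of the wave (may be
#'   `NULL` if only structural attributes are wanted).
#' @param inventories a named list of [facility_inventory()] objects (may be
#'   `NULL`).
#' @param wave wave label, e.g. `"baseline"` or `"endline"`.
#' @param n_days observation window for the temporal attribute.
#' @param eligible,population passed to the client-level attribute functions.
#' @return A data frame of class `attribute_table`: `facility_id`, `wave`,
#'   the eight attribute columns, and companion denominator columns
#'   `n_<attribute>`.
#' @export
build_attribute_table <- function(flow = NULL, inventories = NULL,
                                  wave = "baseline", n_days = 5,
                                  eligible = "all", population = "all") {
  flow_ids <- if (!is.null(flow)) unique(flow$facility_id) else character(0)
  inv_ids <- names(inventories)
  ids <- sort(unique(c(flow_ids, inv_ids)))
  if (length(ids) == 0L) stop("no facilities in input data", call. = FALSE)
  only_flow <- setdiff(flow_ids, inv_ids)
  only_inv <- setdiff(inv_ids, flow_ids)
  if (length(only_flow) > 0L && !is.null(inventories))
    warning("facilities in client flow but not in inventory: ",
            paste(only_flow, collapse = ", "), call. = FALSE)
  if (length(only_inv) > 0L && !is.null(flow))
    warning("facilities in inventory but not in client flow: ",
            paste(only_inv, collapse = ", "), call. = FALSE)

  an <- attribute_names()
  rows <- lapply(ids, function(id) {
    vals <- stats::setNames(rep(NA_real_, 8), an)
    dens <- stats::setNames(rep(NA_integer_, 8), an)
    grab <- function(x) list(v = as.numeric(x), n = attr(x, "denominator"))
    if (id %in% inv_ids) {
      inv <- inventories[[id]]
      for (nm in c("unit_availability", "facility_availability",
                   "room_range", "provider_range")) {
        fn <- switch(nm,
                     unit_availability = compute_unit_availability,
                     facility_availability = compute_facility_availability,
                     room_range = compute_room_range,
                     provider_range = compute_provider_range)
        g <- grab(suppressWarnings(fn(inv)))
        vals[nm] <- g$v; dens[nm] <- g$n
      }
    }
    if (id %in% flow_ids) {
      fl <- flow[flow$facility_id == id, , drop = FALSE]
      class(fl) <- class(flow)
      g <- grab(compute_temporal_range(fl, n_days))
      vals["temporal_range"] <- g$v; dens["temporal_range"] <- g$n
      g <- grab(compute_consult_integration(fl, eligible))
      vals["consult_integration"] <- g$v; dens["consult_integration"] <- g$n
      g <- grab(compute_visit_integration(fl, eligible))
      vals["visit_integration"] <- g$v; dens["visit_integration"] <- g$n
      g <- grab(compute_art_score(fl, population))
      vals["art_location_score"] <- g$v; dens["art_location_score"] <- g$n
    }
    c(list(facility_id = id, wave = wave), as.list(vals),
      stats::setNames(as.list(dens), paste0("n_", an)))
  })
  out <- do.call(rbind, lapply(rows, function(r) as.data.frame(r)))
  na_counts <- colSums(is.na(out[an]))
  if (any(na_counts > 0L)) {
    msg <- paste0(names(na_counts)[na_counts > 0L], " (",
                  na_counts[na_counts > 0L], ")", collapse = ", ")
    warning("attribute values missing: ", msg, call. = FALSE)
  }
  class(out) <- c("attribute_table", "data.frame")
  out
}

#' Write / read an attribute table CSV
#'
#' Plain CSV with `facility_id`, `wave`, the eight attribute columns and the
#' `n_<attribute>` denominator columns.
#'
#' @param x an `attribute_table`.
#' @param path output/input CSV path.
#' @return `read_attribute_table()` returns an `attribute_table`.
#' @export
write_attribute_table <- function(x, path) {
  utils::write.csv(as.data.frame(x), path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_attribute_table
#' @export
read_attribute_table <- function(path) {
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("facility_id", "wave", attribute_names())
  miss <- setdiff(need, names(x))
  if (length(miss) > 0L)
    stop(path, ": missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  x$facility_id <- as.character(x$facility_id)
  for (nm in attribute_names()) x[[nm]] <- as.numeric(x[[nm]])
  class(x) <- c("attribute_table", "data.frame")
  x
}
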