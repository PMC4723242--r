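#' Facility inventory
#'
#' Structural integration attributes are computed from an inventory of what a
#' facility can and does provide: the services available in its MCH/FP unit,
#' the services available anywhere in the facility, and per-room and
#' per-staff logs of HIV-related services actually provided.
#'
#' Room and staff logs are filtered to the HIV-related vocabulary; RH codes
#' appearing there are ignored.  A unit offering a service the facility-wide
#' list lacks is flagged with a warning (registers can disagree) but is not
#' an error.
#'
#' @param facility_id facility identifier.
#' @param unit_services character vector of services available in the MCH/FP
#'   unit, or `NULL` if no unit record exists.
#' @param facility_services character vector of services available anywhere
#'   in the facility, or `NULL`.
#' @param room_logs named list, one element per MCH/FP consultation room,
#'   each a character vector of HIV-related services provided there.
#' @param staff_logs named list, one element per MCH/FP clinical staff
#'   member, each a character vector of HIV-related services provided by that
#'   person in a day.
#' @return An object of class `facility_inventory`.
#' @export
facility_inventory <- function(facility_id, unit_services = NULL,
                               facility_services = NULL,
                               room_logs = list(), staff_logs = list()) {
  if (!is.null(unit_services)) validate_service_codes(unit_services, "unit service")
  if (!is.null(facility_services))
    validate_service_codes(facility_services, "facility service")
  if (!is.null(unit_services) && !is.null(facility_services)) {
    extra <- setdiff(unit_services, facility_services)
    if (length(extra) > 0L)
      warning("facility ", facility_id, ": unit offers ",
              paste(extra, collapse = ", "),
              " not in the facility-wide service list", call. = FALSE)
  }
  clean_log <- function(lst, what) {
    lapply(lst, function(v) {
      validate_service_codes(v, what)
      intersect(unique(v), hiv_services())
    })
  }
  structure(list(facility_id = as.character(facility_id),
                 unit_services = unique(unit_services),
                 facility_services = unique(facility_services),
                 room_logs = clean_log(room_logs, "room log"),
                 staff_logs = clean_log(staff_logs, "staff log")),
            class = "facility_inventory")
}

#' @export
print.facility_inventory <- function(x, ...) {
  cat("Facility inventory:", x$facility_id, "\n")
  cat("  unit services:    ",
      if (is.null(x$unit_services)) "<missing>"
      else paste(x$unit_services, collapse = ", "), "\n")
  cat("  facility services:",
      if (is.null(x$facility_services)) "<missing>"
      else paste(x$facility_services, collapse = ", "), "\n")
  cat("  rooms logged:", length(x$room_logs),
      " staff logged:", length(x$staff_logs), "\n")
  invisible(x)
}

#' Read a set of facility inventories from CSV files
#'
#' Four files describe the structural side of a study wave:
#' * `unit_services.csv`: columns `facility_id`, `service`;
#' * `facility_services.csv`: columns `facility_id`, `service`;
#' * `room_logs.csv`: columns `facility_id`, `room_id`, `service`;
#' * `staff_logs.csv`: columns `facility_id`, `staff_id`, `service`.
#'
#' One row per (entity, service).  Facilities absent from a file simply have
#' that component missing.  Files may be absent (`NULL` path), in which case
#' the corresponding attribute will be missing for every facility.
#'
#' @param unit_path,facility_path,room_path,staff_path CSV paths (or `NULL`).
#' @return A named list of [facility_inventory()] objects.
#' @export
read_facility_inventory <- function(unit_path = NULL, facility_path = NULL,
                                    room_path = NULL, staff_path = NULL) {
  read_one <- function(path, cols) {
    if (is.null(path)) return(NULL)
    if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
    x <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character")
    miss <- setdiff(cols, names(x))
    if (length(miss) > 0L)
      stop(path, ": missing column(s): ", paste(miss, collapse = ", "),
           call. = FALSE)
    validate_service_codes(x$service, "service")
    x
  }
  unit <- read_one(unit_path, c("facility_id", "service"))
  fac <- read_one(facility_path, c("facility_id", "service"))
  room <- read_one(room_path, c("facility_id", "room_id", "service"))
  staff <- read_one(staff_path, c("facility_id", "staff_id", "service"))

  ids <- sort(unique(c(unit$facility_id, fac$facility_id,
                       room$facility_id, staff$facility_id)))
  out <- lapply(ids, function(id) {
    us <- if (!is.null(unit) && id %in% unit$facility_id)
      unit$service[unit$facility_id == id] else NULL
    fs <- if (!is.null(fac) && id %in% fac$facility_id)
      fac$service[fac$facility_id == id] else NULL
    rl <- list()
    if (!is.null(room) && id %in% room$facility_id) {
      sub <- room[room$facility_id == id, ]
      rl <- split(sub$service, sub$room_id)
    }
    sl <- list()
    if (!is.null(staff) && id %in% staff$facility_id) {
      sub <- staff[staff$facility_id == id, ]
      sl <- split(sub$service, sub$staff_id)
    }
    facility_inventory(id, us, fs, rl, sl)
  })
  names(out) <- ids
  out
}
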