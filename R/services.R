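#' Service code vocabulary
#'
#' The integration attributes are defined over a fixed vocabulary of eight
#' service codes: three reproductive-health (RH) services and five
#' HIV-related services.
#'
#' * RH: `FP` (family planning), `ANC` (antenatal care), `PNC` (post-natal
#'   care).
#' * HIV-related: `ART` (antiretroviral therapy), `CACX_SCREEN` (cervical
#'   cancer screening), `CD4` (CD4 count services), `HIV_TEST` (HIV testing
#'   and counselling), `STI_TREAT` (STI treatment).
#'
#' @return A character vector of service codes.
#' @examples
#' rh_services()
#' hiv_services()
#' @export
rh_services <- function() c("FP", "ANC", "PNC")

#' @rdname rh_services
#' @export
hiv_services <- function() c("ART", "CACX_SCREEN", "CD4", "HIV_TEST", "STI_TREAT")

#' @rdname rh_services
#' @export
integration_services <- function() c(rh_services(), hiv_services())

# SRH services for the HIV-treatment-location score: FP/ANC/PNC/STI.
# STI treatment counts as SRH here even though it is in the HIV-related set
# for the co-receipt attributes.
srh_services <- function() c("FP", "ANC", "PNC", "STI_TREAT")

#' Validate a vector of service codes
#'
#' @param codes character vector of candidate codes.
#' @param what label used in error messages.
#' @return `codes`, invisibly, if all are known.
#' @keywords internal
validate_service_codes <- function(codes, what = "services") {
  bad <- setdiff(codes, integration_services())
  if (length(bad) > 0L) {
    stop("unknown ", what, " code(s): ", paste(unique(bad), collapse = ", "),
         " (known codes: ", paste(integration_services(), collapse = ", "), ")",
         call. = FALSE)
  }
  invisible(codes)
}

# split a semicolon-delimited cell into a code vector
split_codes <- function(x) {
  out <- strsplit(ifelse(is.na(x), "", x), ";", fixed = TRUE)
  lapply(out, function(v) {
    v <- trimws(v)
    v[nzchar(v)]
  })
}

has_any <- function(codes, set) any(codes %in% set)
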