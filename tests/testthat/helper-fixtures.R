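# Small in-code fixtures shared across test files.

# build a client_flow from compact row specs:
# list(c(facility, day, client, provider, services, referrals), ...)
make_flow <- function(rows) {
  df <- do.call(rbind, lapply(rows, function(r)
    data.frame(facility_id = r[[1]], day = as.integer(r[[2]]),
               client_id = r[[3]], provider_id = r[[4]],
               services = r[[5]], referrals = r[[6]],
               stringsAsFactors = FALSE)))
  client_flow(df)
}

# a complete small inventory
tiny_inventory <- function(id = "F1") {
  facility_inventory(id,
                     unit_services = c("HIV_TEST", "STI_TREAT", "CD4"),
                     facility_services = c("FP", "ANC", "PNC", "HIV_TEST",
                                           "ART", "CD4", "STI_TREAT"),
                     room_logs = list(r1 = c("ART", "CD4"),
                                      r2 = c("HIV_TEST")),
                     staff_logs = list(s1 = c("HIV_TEST"),
                                       s2 = c("HIV_TEST", "STI_TREAT")))
}

# random client flow for property tests: n_clients clients over n_days,
# random subsets of services per contact
random_flow <- function(n_clients, n_days = 5, facility = "FX", seed = 1) {
  set.seed(seed)
  rows <- list()
  all_sv <- integration_services()
  for (k in seq_len(n_clients)) {
    d <- sample.int(n_days, 1)
    n_contacts <- sample.int(3, 1)
    for (ct in seq_len(n_contacts)) {
      sv <- all_sv[stats::runif(8) < 0.25]
      rows[[length(rows) + 1L]] <-
        list(facility, d, paste0("c", k), paste0("p", ct),
             paste(sv, collapse = ";"), "")
    }
  }
  make_flow(rows)
}

# strip the denominator attribute for plain numeric comparison
num <- function(x) as.numeric(x)
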