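test_that("availability attributes are intersection shares of the service sets", {
  inv_full <- facility_inventory("F1", unit_services = hiv_services(),
                                 facility_services = integration_services())
  expect_equal(num(compute_unit_availability(inv_full)), 1.0)
  expect_equal(num(compute_facility_availability(inv_full)), 1.0)

  inv <- suppressWarnings(
    facility_inventory("F2", unit_services = c("HIV_TEST", "STI_TREAT"),
                       facility_services = c("FP", "ANC", "PNC",
                                             "HIV_TEST")))
  expect_equal(num(compute_unit_availability(inv)), 0.4)     # 2/5
  expect_equal(num(compute_facility_availability(inv)), 0.5) # 4/8
  expect_equal(attr(compute_unit_availability(inv), "denominator"), 5L)

  inv_empty <- suppressWarnings(
    facility_inventory("F3", unit_services = character(0),
                       facility_services = character(0)))
  expect_equal(num(compute_unit_availability(inv_empty)), 0.0)
  expect_equal(num(compute_facility_availability(inv_empty)), 0.0)

  inv_miss <- facility_inventory("F4")
  expect_warning(v <- compute_unit_availability(inv_miss), "no MCH/FP unit")
  expect_true(is.na(v))
})

test_that("room and provider range average HIV-service shares across units", {
  inv1 <- facility_inventory("F1", room_logs = list(r1 = hiv_services()))
  expect_equal(num(compute_room_range(inv1)), 1.0)

  inv2 <- facility_inventory("F2",
                             room_logs = list(r1 = c("ART", "CD4"),
                                              r2 = character(0)))
  expect_equal(num(compute_room_range(inv2)), 0.2)  # mean of 2/5 and 0

  inv3 <- facility_inventory("F3",
                             room_logs = list(r1 = "ART", r2 = "CD4",
                                              r3 = "HIV_TEST"))
  expect_equal(num(compute_room_range(inv3)), 0.2)  # mean of 1/5 thrice

  inv4 <- facility_inventory("F4", staff_logs = list(s1 = hiv_services()))
  expect_equal(num(compute_provider_range(inv4)), 1.0)
  inv5 <- facility_inventory("F5",
                             staff_logs = list(A = "HIV_TEST",
                                               B = c("HIV_TEST", "STI_TREAT")))
  expect_equal(num(compute_provider_range(inv5)), 0.3)  # mean of .2 and .4
  inv6 <- facility_inventory("F6", staff_logs = list(A = character(0),
                                                     B = character(0)))
  expect_equal(num(compute_provider_range(inv6)), 0.0)
  expect_warning(v <- compute_room_range(facility_inventory("F7")),
                 "no consultation room")
  expect_true(is.na(v))
  # RH codes in a room log are filtered out, not counted as HIV
  inv7 <- facility_inventory("F8", room_logs = list(r1 = c("FP", "ART")))
  expect_equal(num(compute_room_range(inv7)), 0.2)
})

test_that("temporal range counts days with co-delivery of both classes", {
  both_daily <- make_flow(lapply(1:5, function(d)
    list("F1", d, paste0("c", d), "p1", "FP;HIV_TEST", "")))
  expect_equal(num(compute_temporal_range(both_daily)), 1.0)

  rows <- c(lapply(1:5, function(d)
    list("F1", d, paste0("a", d), "p1", "ANC", "")),
    list(list("F1", 1, "h1", "p2", "CD4", ""),
         list("F1", 3, "h3", "p2", "HIV_TEST", "")))
  expect_equal(num(compute_temporal_range(make_flow(rows))), 0.4) # days 1 and 3

  no_hiv <- make_flow(lapply(1:5, function(d)
    list("F1", d, paste0("c", d), "p1", "FP;ANC", "")))
  expect_equal(num(compute_temporal_range(no_hiv)), 0.0)

  expect_error(compute_temporal_range(both_daily, n_days = 3),
               "inconsistent")
})

test_that("consultation-level co-receipt requires both classes from one provider", {
  fl <- make_flow(list(
    list("F1", 1, "c1", "p1", "FP;HIV_TEST", ""),   # integrated contact
    list("F1", 1, "c2", "p1", "FP", ""),
    list("F1", 1, "c2", "p2", "HIV_TEST", ""),      # split across providers
    list("F1", 1, "c3", "p1", "ANC;CD4", ""),       # integrated contact
    list("F1", 1, "c4", "p1", "PNC", "")))
  expect_equal(num(compute_consult_integration(fl)), 0.5)  # c1, c3 of 4
  expect_equal(num(compute_visit_integration(fl)), 0.75)   # c2 also counts

  all_int <- make_flow(list(list("F1", 1, "c1", "p1", "ANC;HIV_TEST", ""),
                            list("F1", 2, "c2", "p1", "ANC;HIV_TEST", "")))
  expect_equal(num(compute_consult_integration(all_int)), 1.0)

  # denominator restriction to clients receiving any service
  with_empty <- make_flow(list(list("F1", 1, "c1", "p1", "FP;HIV_TEST", ""),
                               list("F1", 1, "c2", "p1", "", "")))
  expect_equal(num(compute_consult_integration(with_empty)), 0.5)
  expect_equal(num(compute_consult_integration(with_empty,
                                               eligible = "any_service")), 1.0)
})

test_that("visit-level co-receipt pools a client's contacts within the day", {
  fl <- make_flow(list(list("F1", 1, "c1", "p1", "FP", ""),
                       list("F1", 1, "c1", "p2", "HIV_TEST", "")))
  expect_equal(num(compute_visit_integration(fl)), 1.0)
  expect_equal(num(compute_consult_integration(fl)), 0.0)

  # 10 clients, 3 with both classes across the day
  rows <- c(lapply(1:3, function(k) list("F1", 1, paste0("b", k), "p1",
                                         "FP;CD4", "")),
            lapply(4:10, function(k) list("F1", 1, paste0("b", k), "p1",
                                          "FP", "")))
  expect_equal(num(compute_visit_integration(make_flow(rows))), 0.3)
})

test_that("HIV treatment location score follows the 0-3 grading", {
  fl <- make_flow(list(
    list("F1", 1, "c1", "p1", "ART;FP", ""),      # same provider with SRH: 3
    list("F1", 1, "c2", "p1", "FP", "ART"),       # referred only: 1
    list("F1", 1, "c3", "p1", "ART", ""),         # ART alone: 2
    list("F1", 1, "c4", "p1", "FP", ""),          # nothing ART-related: 0
    list("F1", 1, "c5", "p1", "ART;STI_TREAT", ""), # STI counts as SRH: 3
    list("F1", 1, "c6", "p1", "ANC", ""),
    list("F1", 1, "c6", "p2", "ART", "")))        # different provider: 2
  expect_equal(num(compute_art_score(fl)), mean(c(3, 1, 2, 0, 3, 2)))

  two <- make_flow(list(list("F1", 1, "c1", "p1", "ART;FP", ""),
                        list("F1", 1, "c2", "p1", "FP", "ART")))
  expect_equal(num(compute_art_score(two)), 2.0)  # mean of 3 and 1
  # srh population restriction drops clients without any SRH service
  mix <- make_flow(list(list("F1", 1, "c1", "p1", "ART;FP", ""),
                        list("F1", 1, "c2", "p1", "HIV_TEST", "")))
  expect_equal(num(compute_art_score(mix, population = "srh")), 3.0)
})

test_that("attribute table assembles per-facility rows and flags missing sources", {
  fl <- make_flow(list(list("F1", 1, "c1", "p1", "FP;HIV_TEST", ""),
                       list("F2", 1, "c1", "p1", "ANC", "")))
  invs <- list(F1 = tiny_inventory("F1"),
               F2 = suppressWarnings(
                 facility_inventory("F2", unit_services = "HIV_TEST",
                                    facility_services = c("FP", "ANC"))))
  expect_warning(tab <- build_attribute_table(fl, invs, wave = "baseline"),
                 "missing")
  expect_s3_class(tab, "attribute_table")
  expect_equal(dim(tab), c(2L, 2L + 16L))
  expect_equal(tab$facility_id, c("F1", "F2"))
  # F2 has no room/staff logs: those attributes are missing, never zero
  expect_true(is.na(tab$provider_range[tab$facility_id == "F2"]))
  expect_true(is.na(tab$room_range[tab$facility_id == "F2"]))
  expect_false(is.na(tab$unit_availability[tab$facility_id == "F2"]))
  # facility only in one source triggers a mismatch warning
  fl1 <- make_flow(list(list("F3", 1, "c1", "p1", "FP", "")))
  w <- capture_warnings(build_attribute_table(fl1, invs, wave = "baseline"))
  expect_true(any(grepl("not in", w)))
})

test_that("attribute invariants hold on random client flows", {
  for (s in 1:8) {
    fl <- random_flow(n_clients = 30, seed = s)
    ci <- num(compute_consult_integration(fl))
    vi <- num(compute_visit_integration(fl))
    tr <- num(compute_temporal_range(fl))
    as_ <- num(compute_art_score(fl))
    expect_lte(ci, vi)
    expect_true(ci >= 0 && vi <= 1)
    expect_true(tr >= 0 && tr <= 1)
    expect_true(as_ >= 0 && as_ <= 3)

    # invariance to record order and id relabeling
    perm <- sample.int(nrow(fl))
    fl2 <- fl[perm, ]
    class(fl2) <- class(fl)
    fl2$client_id <- paste0("zz_", fl2$client_id)
    expect_equal(num(compute_consult_integration(fl2)), ci)
    expect_equal(num(compute_visit_integration(fl2)), vi)
    expect_equal(num(compute_art_score(fl2)), as_)

    # adding a service-free client changes only the denominator
    extra <- rbind(as.data.frame(fl),
                   data.frame(facility_id = "FX", day = 1,
                              client_id = "null_client", provider_id = "p9",
                              services = I(list(character(0))),
                              referrals = I(list(character(0)))))
    fl3 <- client_flow(extra)
    n0 <- attr(compute_consult_integration(fl), "denominator")
    r3 <- compute_consult_integration(fl3)
    expect_equal(attr(r3, "denominator"), n0 + 1L)
    expect_equal(num(r3) * (n0 + 1L), ci * n0)
  }
})
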