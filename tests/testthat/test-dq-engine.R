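term <- paper_like_terminology()
tracers <- derive_tracers(term)

test_that("case classification distinguishes Orpha, tracer and RD cases", {
  # tracer diagnosis without Orphacode: tracer case, RD case, not Orpha case
  ds <- make_ds(diag_row(icd_code = "E84.0"))
  cls <- classify_cases(ds, tracers)
  expect_equal(cls$flags$tracer_case, TRUE)
  expect_equal(cls$flags$orpha_case, FALSE)
  expect_equal(cls$flags$rd_case, TRUE)
  expect_equal(c(cls$rdCase, cls$orphaCase, cls$tracerCase), c(1, 0, 1))

  # no diagnoses at all
  empty <- case_dataset()
  cls0 <- classify_cases(empty, tracers)
  expect_equal(c(cls0$rdCase, cls0$orphaCase, cls0$tracerCase), c(0, 0, 0))

  # Orphacode on a non-tracer code: Orpha case only
  ds2 <- make_ds(diag_row(icd_code = "G12.9", orphacode = 70))
  cls2 <- classify_cases(ds2, tracers)
  expect_equal(c(cls2$rdCase, cls2$orphaCase, cls2$tracerCase), c(1, 1, 0))

  # a case counts once however many qualifying diagnoses it has
  ds3 <- make_ds(rbind(diag_row("D1", icd_code = "E84.0", orphacode = 586),
                       diag_row("D2", icd_code = "Q87.5", orphacode = 2097)))
  expect_equal(classify_cases(ds3, tracers)$rdCase, 1)
})

test_that("relative frequencies normalize to 100,000 with half-up rounding", {
  expect_equal(relative_frequencies(5, 20000), 25)
  expect_equal(relative_frequencies(7, 7), 100000)
  expect_equal(relative_frequencies(1, 200000), 1)    # 0.5 rounds up
  expect_equal(relative_frequencies(1, 300000), 0)    # 0.33 rounds down
  expect_warning(out <- relative_frequencies(c(1, 2), NULL), "unknown")
  expect_equal(out, c(NA_real_, NA_real_))
})

test_that("item completeness flags items valueless across the whole dataset", {
  ds <- make_ds(diag_row(icd_code = "E84.0", orphacode = 586))
  ds$patients$address_city <- NA_character_
  ds$patients$address_postal_code <- NA_character_
  mi <- detect_missing_items(ds)
  expect_equal(mi$count, 2)
  expect_setequal(mi$issues$group_key, c("address_city", "address_postal_code"))
  expect_equal(mi$n_items, 15)

  full <- make_ds(diag_row(icd_code = "E84.0", orphacode = 586))
  expect_equal(detect_missing_items(full)$count, 0)
})

test_that("value completeness counts per-slot gaps, excluding missing items", {
  diag <- rbind(diag_row("D1", "C1", "P1", icd_code = "E84.0", orphacode = 586),
                diag_row("D2", "C2", "P2", icd_code = "Q87.5", orphacode = 2097))
  ds <- make_ds(diag)
  ds$patients$sex[2] <- NA_character_        # 1 missing value (item present via P1)
  ds$patients$address_city <- NA_character_  # whole item missing -> excluded
  mv <- detect_missing_values(ds)
  expect_equal(mv$count, 1)
  expect_equal(mv$issues$group_key, "sex")
  expect_equal(mv$issues$record_id, "P2")
  # 14 present items x 2 records each type
  expect_equal(mv$n_value_slots, 28)

  full <- make_ds(diag)
  expect_equal(detect_missing_values(full)$count, 0)
})

test_that("outlier rules catch impossible ages, date inversions and bad codes", {
  ds <- make_ds(diag_row(icd_code = "E84.0", orphacode = 586))
  ds$patients$birth_date <- "1889-01-01"   # 132 years at 2021 admission
  ol <- detect_outliers(ds)
  expect_equal(ol$count, 1)
  expect_match(ol$issues$detail, "age at admission")

  inv <- make_ds(diag_row(icd_code = "E84.0", orphacode = 586))
  inv$encounters$discharge_date <- "2021-02-20"  # before 2021-03-01 admission
  expect_equal(detect_outliers(inv)$count, 1)

  weird <- make_ds(diag_row(icd_code = "E84.0", orphacode = 586))
  weird$diagnoses$icd_code <- "E84.0§"
  expect_equal(detect_outliers(weird)$count, 1)

  expect_equal(detect_outliers(case_dataset())$count, 0)
  expect_equal(detect_outliers(case_dataset())$n_checked_values, 0)

  bad_rule <- list(list(id = "r", record_type = "diagnosis",
                        fields = "no_such_field", fun = function(ds) NULL))
  expect_error(detect_outliers(ds, bad_rule), "unknown field")
})

test_that("absent values are not checked by outlier rules", {
  ds <- make_ds(diag_row(icd_code = "E84.0", orphacode = 586))
  base <- detect_outliers(ds)$n_checked_values
  ds$encounters$discharge_date <- NA_character_
  expect_equal(detect_outliers(ds)$n_checked_values, base - 1)
})

test_that("tracer diagnoses without Orphacode are completeness issues", {
  ds <- make_ds(diag_row(icd_code = "E84.0"))
  mo <- detect_missing_orphacodes(ds, tracers)
  expect_equal(mo$count, 1)
  expect_equal(mo$n_tracer_diagnoses, 1)

  coded <- make_ds(diag_row(icd_code = "E84.0", orphacode = 586))
  expect_equal(detect_missing_orphacodes(coded, tracers)$count, 0)

  # non-tracer codes are outside the denominator
  non <- make_ds(diag_row(icd_code = "G12.9"))
  res <- detect_missing_orphacodes(non, tracers)
  expect_equal(c(res$count, res$n_tracer_diagnoses), c(0, 0))
})

test_that("implausible links are pairs absent from the terminology", {
  ds <- make_ds(diag_row(icd_code = "G71.2", orphacode = 777))
  il <- detect_implausible_links(ds, term)
  expect_equal(il$count, 1)
  expect_equal(il$n_linked_diagnoses, 1)

  ok <- make_ds(diag_row(icd_code = "Q87.5", orphacode = 2097))
  expect_equal(detect_implausible_links(ok, term)$count, 0)

  uncoded <- make_ds(diag_row(icd_code = "E84.0"))
  res <- detect_implausible_links(uncoded, term)
  expect_equal(c(res$count, res$n_linked_diagnoses), c(0, 0))
})

test_that("duplicates count surplus records per identical 4-tuple group", {
  two <- rbind(diag_row("D1", icd_code = "E84.0", orphacode = 586),
               diag_row("D2", icd_code = "E84.0", orphacode = 586))
  expect_equal(detect_duplicates(make_ds(two))$count, 1)

  expect_equal(detect_duplicates(make_ds(diag_row()))$count, 0)

  # groups of sizes {3, 2} -> (3-1) + (2-1) = 3
  grp <- rbind(diag_row("D1"), diag_row("D2"), diag_row("D3"),
               diag_row("D4", icd_code = "Q87.5", orphacode = 2097),
               diag_row("D5", icd_code = "Q87.5", orphacode = 2097))
  expect_equal(detect_duplicates(make_ds(grp))$count, 3)

  # differing Orphacode-or-absent breaks the group
  mix <- rbind(diag_row("D1", orphacode = 586), diag_row("D2"))
  expect_equal(detect_duplicates(make_ds(mix))$count, 0)
})

test_that("ambiguity requires a multi-candidate tracer the coding cannot resolve", {
  # F84.2 without Orphacode: two candidate disorders -> ambiguous
  amb <- make_ds(diag_row(icd_code = "F84.2"))
  expect_equal(detect_ambiguous(amb, term, tracers)$count, 1)

  # a plausible pair resolves the multi-candidate code -> unambiguous
  ok <- make_ds(diag_row(icd_code = "Q87.5", orphacode = 2097))
  expect_equal(detect_ambiguous(ok, term, tracers)$count, 0)

  # single-candidate tracer without Orphacode -> unambiguous
  single <- make_ds(diag_row(icd_code = "E84.0"))
  expect_equal(detect_ambiguous(single, term, tracers)$count, 0)

  # interpretation rule (b): implausible pair on a multi-candidate tracer
  implausible <- make_ds(diag_row(icd_code = "F84.2", orphacode = 999999))
  expect_equal(detect_ambiguous(implausible, term, tracers)$count, 1)
  expect_equal(detect_ambiguous(implausible, term, tracers, rule_b = FALSE)$count, 0)

  # a case counts once even with several ambiguous diagnoses
  multi <- make_ds(rbind(diag_row("D1", icd_code = "F84.2"),
                         diag_row("D2", icd_code = "Q87.5")))
  expect_equal(detect_ambiguous(multi, term, tracers)$count, 1)
})

test_that("indicator formulas reproduce published-scale rates and edge limits", {
  p <- dq_parameter_set(rdCase = 163, orphaCase = 0, tracerCase = 163,
                        rdCase_amb = 9, n_items = 15, n_value_slots = 10,
                        n_checked_values = 10, n_tracer_diagnoses = 163,
                        n_linked_diagnoses = 0, n_case_records = 163)
  ind <- compute_indicators(p)
  cur <- ind$value[ind$indicator == "dqi_un_cur"]
  expect_equal(cur, 100 * (1 - 9 / 163), tolerance = 1e-12)
  expect_gt(cur, 94)

  p2 <- dq_parameter_set(rdCase = 783, orphaCase = 729, tracerCase = 165,
                         link_ip = 21, n_items = 15, n_value_slots = 10,
                         n_checked_values = 10, n_tracer_diagnoses = 165,
                         n_linked_diagnoses = 729, n_case_records = 783)
  opr <- compute_indicators(p2)
  expect_equal(opr$value[opr$indicator == "dqi_pl_opr"],
               100 * (1 - 21 / 729), tolerance = 1e-12)
  expect_gt(opr$value[opr$indicator == "dqi_pl_opr"], 97)

  # no-issue limit: all 100
  clean <- dq_parameter_set(rdCase = 5, orphaCase = 5, tracerCase = 5,
                            n_items = 15, n_value_slots = 50,
                            n_checked_values = 20, n_tracer_diagnoses = 5,
                            n_linked_diagnoses = 5, n_case_records = 5)
  expect_true(all(compute_indicators(clean)$value == 100))

  # all-issue limit: all 0
  allbad <- dq_parameter_set(rdCase = 5, orphaCase = 5, tracerCase = 5,
                             im_misg = 15, vm_misg = 50, vo = 20, oc_misg = 5,
                             link_ip = 5, rdCase_dup = 5, rdCase_amb = 5,
                             n_items = 15, n_value_slots = 50,
                             n_checked_values = 20, n_tracer_diagnoses = 5,
                             n_linked_diagnoses = 5, n_case_records = 5)
  expect_true(all(compute_indicators(allbad)$value == 0))
})

test_that("vacuous denominators report 0 with the flag set", {
  p <- dq_parameter_set(n_items = 15, n_value_slots = 10,
                        n_checked_values = 10)
  ind <- compute_indicators(p)
  vac <- ind[ind$indicator %in% c("dqi_co_ocr", "dqi_pl_opr", "dqi_un_cur",
                                  "dqi_un_cdr"), ]
  expect_true(all(vac$vacuous))
  expect_true(all(vac$value == 0))
  expect_false(any(ind$vacuous[ind$indicator %in% c("dqi_co_icr",
                                                    "dqi_co_vcr",
                                                    "dqi_pl_rpr")]))
})

test_that("parameter-set invariants reject impossible count combinations", {
  expect_error(dq_parameter_set(rdCase = 1, orphaCase = 2, tracerCase = 0),
               "invariant")
  expect_error(dq_parameter_set(rdCase = 5, orphaCase = 2, tracerCase = 2),
               "invariant")
  expect_error(dq_parameter_set(rdCase = -1), "non-negative")
})

test_that("a full assessment keeps the issue ledger consistent with P7-P13", {
  set.seed(3)
  for (s in c(2, 5, 9)) {
    pair <- gen_dataset_pair(random_fixture_spec(s))
    a <- dq_assess(pair$reference, pair$terminology, tracers = pair$tracers)
    p <- a$params
    expect_equal(nrow(a$issues),
                 p$im_misg + p$vm_misg + p$vo + p$oc_misg + p$link_ip +
                   p$rdCase_dup + p$rdCase_amb)
    expect_true(all(a$indicators$value >= 0 & a$indicators$value <= 100))
  }
})
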