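ref_params <- function() {
  dq_parameter_set(rdCase = 783, orphaCase = 729, tracerCase = 165,
                   im_misg = 2, vm_misg = 0, oc_misg = 65, link_ip = 21,
                   rdCase_dup = 90, rdCase_amb = 14, n_items = 15,
                   n_value_slots = 100, n_checked_values = 100,
                   n_tracer_diagnoses = 165, n_linked_diagnoses = 729,
                   n_case_records = 873)
}

fhir_params <- function() {
  dq_parameter_set(rdCase = 163, orphaCase = 0, tracerCase = 163,
                   im_misg = 3, vm_misg = 1356, oc_misg = 163,
                   rdCase_amb = 9, n_items = 15, n_value_slots = 2445,
                   n_checked_values = 100, n_tracer_diagnoses = 163,
                   n_linked_diagnoses = 0, n_case_records = 163)
}

test_that("the loss statistic applies the piecewise sign rule", {
  v <- lost_parameters(ref_params(), fhir_params())
  expect_equal(v$lost[v$i == 1], 783 - 163)          # observation units
  expect_equal(v$lost[v$i == 7], 3 - 2)              # inverted: issue counts
  expect_equal(v$lost[v$i == 8], 1356 - 0)
  expect_equal(v$sign_rule[v$i == 8], "transformed-minus-reference")
  expect_equal(v$sign_rule[v$i == 1], "reference-minus-transformed")
  # negative losses are reported, never clamped
  expect_equal(v$lost[v$i == 10], 65 - 163)
})

test_that("self-comparison yields the zero vector", {
  v <- lost_parameters(ref_params(), ref_params())
  expect_true(all(v$lost[!is.na(v$lost)] == 0))
  expect_true(all(v$classification[!is.na(v$lost)] == "neutral"))
})

test_that("the loss vector is antisymmetric in its arguments", {
  for (s in c(4, 8)) {
    pair <- gen_dataset_pair(random_fixture_spec(s))
    a <- dq_assess(pair$reference, pair$terminology, tracers = pair$tracers)
    b <- dq_assess(pair$degraded, pair$terminology, tracers = pair$tracers)
    ab <- lost_parameters(a$params, b$params)$lost
    ba <- lost_parameters(b$params, a$params)$lost
    keep <- !is.na(ab)
    expect_equal(ab[keep], -ba[keep])
  }
})

test_that("outlier and duplicate reductions are not auto-classified as issues", {
  a <- dq_parameter_set(vo = 0, rdCase_dup = 0, n_case_records = 10)
  b <- dq_parameter_set(vo = 5, rdCase_dup = 0, n_case_records = 10)
  v <- lost_parameters(a, b)   # P9_lost = 5 - 0 = 5 > 0
  expect_equal(v$classification[v$i == 9], "possibly-intentional")
  c <- dq_parameter_set(rdCase_dup = 7, n_case_records = 10)
  v2 <- lost_parameters(c, a)  # P12_lost = 7 > 0
  expect_equal(v2$classification[v2$i == 12], "possibly-intentional")
  # but an introduced missing-value load is an issue
  v3 <- lost_parameters(dq_parameter_set(), dq_parameter_set(vm_misg = 3))
  expect_equal(v3$classification[v3$i == 8], "issue")
})

test_that("the summary reproduces the completeness and grand totals", {
  cmp <- summarize_lost(lost_parameters(ref_params(), fhir_params()))
  expect_equal(cmp$completeness_loss_total, 620 + 1 + 1356)
  expect_equal(cmp$grand_total, 1977 + 9 + 2)
  zero <- summarize_lost(lost_parameters(dq_parameter_set(), dq_parameter_set()))
  expect_equal(zero$completeness_loss_total, 0)
  expect_equal(zero$grand_total, 0)
})

test_that("summary totals match the ledger on a synthetic pair", {
  pair <- gen_dataset_pair(fixture_spec(
    seed = 21, degradation = list(drop_all_orphacodes = TRUE,
                                  drop_case_fraction = 0.2)))
  a <- dq_assess(pair$reference, pair$terminology, tracers = pair$tracers)
  b <- dq_assess(pair$degraded, pair$terminology, tracers = pair$tracers)
  v <- lost_parameters(a$params, b$params)
  el <- pair$ledger$expected_lost
  keep <- !is.na(v$lost)
  expect_equal(v$lost[keep], el$lost[keep])
  s <- summarize_lost(v)
  exp_comp <- sum(pmax(0, el$lost[el$i %in% c(1, 7, 8, 10)]), na.rm = TRUE)
  expect_equal(s$completeness_loss_total, exp_comp)
})

test_that("differing configurations are a comparability error", {
  a <- dq_parameter_set(fingerprint = "catalogA")
  b <- dq_parameter_set(fingerprint = "catalogB")
  expect_error(lost_parameters(a, b), "comparability")
})

test_that("relative parameters compare only under equal inpatient totals", {
  a <- dq_parameter_set(rdCase = 10, orphaCase = 10,
                        total_inpatient_cases = 1000)
  b <- dq_parameter_set(rdCase = 5, orphaCase = 5,
                        total_inpatient_cases = 1000)
  v <- lost_parameters(a, b)
  expect_equal(v$lost[v$i == 4], relative_frequencies(10, 1000) -
                 relative_frequencies(5, 1000))
  b2 <- dq_parameter_set(rdCase = 5, orphaCase = 5,
                         total_inpatient_cases = 2000)
  expect_warning(v2 <- lost_parameters(a, b2), "differing inpatient totals")
  expect_true(all(is.na(v2$lost[v2$i %in% 4:6])))
})
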