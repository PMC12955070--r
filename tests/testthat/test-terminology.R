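test_that("parsing builds entries, strips prefixes and collects malformed lines", {
  term <- parse_alpha_id_se("1|I128560|Q87.5|||2097|Grant syndrome")
  expect_equal(nrow(term$entries), 1)
  expect_equal(term$entries$alpha_id, "I128560")
  expect_equal(term$entries$icd_primary, "Q87.5")
  expect_equal(term$entries$orphacode, 2097L)
  expect_true(term$entries$valid)

  # the configurable dialect absorbs a layout without the extra columns
  short <- parse_alpha_id_se("1|I128560|Q87.5||2097|Grant syndrome",
                             dialect = alpha_dialect(icd_star = 3L,
                                                     orphacode = 4L,
                                                     label = 5L))
  expect_equal(short$entries$orphacode, 2097L)

  empty <- parse_alpha_id_se(character(0))
  expect_equal(nrow(empty$entries), 0)
  expect_equal(nrow(empty$parse_errors), 0)

  mixed <- parse_alpha_id_se(c("1|I000001|E84.0|||586|CF",
                               "not a terminology line",
                               "1|I000002|Q87.5|||2097|Grant syndrome"))
  expect_equal(nrow(mixed$entries), 2)
  expect_equal(nrow(mixed$parse_errors), 1)
  expect_equal(mixed$parse_errors$line, 2L)
})

test_that("mostly-malformed input is a format error naming the first bad line", {
  expect_error(parse_alpha_id_se(c("garbage", "more garbage",
                                   "1|I000001|E84.0|||586|CF")),
               "line 1")
})

test_that("an unreadable path is an I/O error", {
  # a directory path exists but cannot be read line-wise
  expect_error(parse_alpha_id_se(file.path(tempdir())), "cannot read")
})

test_that("ICD normalization uppercases, keeps the dot and strips usage markers", {
  expect_equal(icd_normalize(c("e84.0", " g71.2+ ", "M90.4*", "q87.5!")),
               c("E84.0", "G71.2", "M90.4", "Q87.5"))
  expect_equal(icd_marker("G71.2+"), "+")
  expect_true(all(icd_is_valid(c("Q87.5", "E84.0", "A01"))))
  expect_false(any(icd_is_valid(c("XX", "1234", NA, "E84.012"))))
})

test_that("tracer derivation requires every valid term of a code to carry an Orphacode", {
  term <- paper_like_terminology()
  tr <- derive_tracers(term)
  expect_s3_class(tr, "tracer_set")
  expect_equal(tr$provenance, "alpha_derived")
  expect_true("Q87.5" %in% tr$codes)      # all terms Orphacoded
  expect_true("E84.0" %in% tr$codes)
  expect_false("G12.9" %in% tr$codes)     # one term lacks an Orphacode
  expect_false("Z99.9" %in% tr$codes)     # only a retired entry: not a tracer
})

test_that("tracer derivation matches a brute-force scan on a random terminology", {
  set.seed(11)
  codes <- sprintf("%s%02d.%d", sample(LETTERS, 20, replace = TRUE),
                   sample(0:99, 20), sample(0:9, 20, replace = TRUE))
  codes <- unique(codes)
  lines <- unlist(lapply(seq_along(codes), function(i) {
    n_terms <- sample(1:3, 1)
    sapply(seq_len(n_terms), function(j) {
      orpha <- if (stats::runif(1) < 0.7) sample(1000:2000, 1) else ""
      sprintf("1|I%02d%04d|%s|||%s|Term %d", i, j, codes[i], orpha, j)
    })
  }))
  term <- parse_alpha_id_se(lines)
  # oracle: group all entries by code, keep codes where every term has a code
  expected <- character(0)
  for (c in unique(term$entries$icd_primary)) {
    e <- term$entries[term$entries$icd_primary == c, ]
    if (all(!is.na(e$orphacode))) expected <- c(expected, c)
  }
  expect_setequal(derive_tracers(term)$codes, expected)
  # invariance under entry reordering
  shuffled <- parse_alpha_id_se(sample(lines))
  expect_equal(derive_tracers(shuffled)$codes, derive_tracers(term)$codes)
})

test_that("curated tracer lists are normalized, deduplicated and filtered", {
  expect_equal(load_curated_tracers(c("e84.0", "E84.0"))$codes, "E84.0")
  expect_equal(load_curated_tracers(character(0))$codes, character(0))
  expect_warning(
    ts <- load_curated_tracers(c("E84.0", "q87.5", "# comment", "notacode",
                                 "G71.2", "M34.1")),
    "excluded")
  expect_equal(length(ts$codes), 4)
  expect_equal(attr(ts, "n_invalid"), 1L)
  expect_equal(ts$provenance, "curated")
})

test_that("link plausibility is exact pair membership over valid entries", {
  term <- paper_like_terminology()
  expect_equal(check_link(term, "G71.2", 777), "implausible")
  expect_equal(check_link(term, "Q87.5", 2097), "plausible")
  expect_equal(check_link(term, "Z99.9", 999), "implausible")  # retired entry
  empty <- parse_alpha_id_se(character(0))
  expect_equal(check_link(empty, "Q87.5", 2097), "implausible")
  expect_equal(check_link(term, character(0), integer(0)), character(0))
})

test_that("Orphacode candidates enumerate all distinct codes of an ICD code", {
  term <- paper_like_terminology()
  expect_equal(orpha_candidates(term, "F84.2"), c(778L, 3095L))
  expect_equal(orpha_candidates(term, "A00.0"), integer(0))
  # oracle on the paper-like fixture
  for (c in unique(term$entries$icd_primary)) {
    e <- term$entries[term$entries$valid & term$entries$icd_primary == c, ]
    expect_equal(orpha_candidates(term, c),
                 sort(unique(e$orphacode[!is.na(e$orphacode)])))
  }
})

test_that("tracer, candidate and plausibility queries are mutually consistent", {
  term <- paper_like_terminology()
  tr <- derive_tracers(term)
  for (c in tr$codes)
    expect_gt(length(orpha_candidates(term, c)), 0)
  for (c in unique(term$entries$icd_primary))
    for (o in orpha_candidates(term, c))
      expect_equal(check_link(term, c, o), "plausible")
})

test_that("a parsed terminology round-trips through its dialect", {
  term <- paper_like_terminology()
  again <- parse_alpha_id_se(write_alpha_id_se(term))
  expect_equal(again$entries, term$entries)
  expect_setequal(again$link_set, term$link_set)
})
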