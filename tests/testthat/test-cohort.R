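day <- function(n) as.POSIXct("2019-06-01 00:00:00", tz = "UTC") + n * 86400

test_that("the day window is inclusive at its boundary", {
  t0 <- day(0)
  expect_true(within_window(t0, t0, 15))
  expect_true(within_window(t0, day(15), 15))
  expect_true(within_window(day(15), t0, 15))
  expect_false(within_window(t0, day(16), 15))
  expect_false(within_window(t0, t0 + 3600, 0))  # zero window: same instant only
  expect_true(within_window(t0, t0, 0))
  expect_false(within_window(t0, t0 + 25 * 3600, 1))
})

test_that("criteria combine diagnosis and confirming imaging as A and (B or C)", {
  cfg <- default_search_config()
  ischemic <- cfg$criteria[[1]]
  thrombectomy <- cfg$criteria[[2]]

  r1 <- case_record("c1", list(coded_event("I63.9", "icd10", day(0)),
                               coded_event("803.900", "procedure", day(3))))
  expect_true(matches_criterion(r1, ischemic))

  r2 <- case_record("c2", list(coded_event("I63.9", "icd10", day(0))))
  expect_false(matches_criterion(r2, ischemic))  # missing imaging leg

  r3 <- case_record("c3", list(coded_event("I63.9", "icd10", day(0)),
                               coded_event("804.220", "procedure", day(20))))
  expect_false(matches_criterion(r3, ischemic))  # outside +/-15 days
  r3b <- case_record("c3", list(coded_event("I63.9", "icd10", day(0)),
                                coded_event("804.220", "procedure", day(15))))
  expect_true(matches_criterion(r3b, ischemic))

  # a confirming procedure alone must never select (the (A and B) or C
  # reading would)
  r4 <- case_record("c4", list(coded_event("804.220", "procedure", day(0)),
                               coded_event("803.900", "procedure", day(1))))
  expect_false(matches_criterion(r4, ischemic))
  expect_false(matches_criterion(r4, thrombectomy))

  r5 <- case_record("c5", list(coded_event("802.891", "procedure", day(0)),
                               coded_event("803.910", "procedure", day(-4))))
  expect_true(matches_criterion(r5, thrombectomy))
  # an icd10-kinded event with a procedure code must not anchor
  r6 <- case_record("c6", list(coded_event("802.891", "icd10", day(0)),
                               coded_event("803.910", "procedure", day(1))))
  expect_false(matches_criterion(r6, thrombectomy))
})

test_that("keyword matching is case-insensitive normalized substring search", {
  phrases <- default_search_config()$phrases
  expect_true(keyword_query("Follow-up: normal head ct today.", phrases))
  expect_true(keyword_query("  head   CT examination  within normal limits ", phrases))
  expect_true(keyword_query("no acute cranial CT finding was detected", phrases))
  expect_false(keyword_query("", phrases))
  expect_false(keyword_query("Large MCA infarct with midline shift.", phrases))
})

test_that("select_cases recovers the planted composition and is order-stable", {
  expect_equal(lengths(select_cases(list())$selected), c(
    icd10_and_head_ct_or_diffusion_mri = 0L,
    thrombectomy_and_head_ct_or_diffusion_mri = 0L,
    aneurysm_treatment_and_head_ct = 0L))

  reg <- gen_registry(200, criterion_counts = c(12L, 7L, 4L),
                      keyword_count = 9L, seed = 77)
  sel <- select_cases(reg)
  expect_equal(unname(lengths(sel$selected)), c(12L, 7L, 4L))
  expect_length(sel$keyword_hits, 9L)

  # input order does not matter
  sel_rev <- select_cases(rev(reg))
  expect_equal(sel_rev, sel)

  # monotone: adding a record never removes previously selected ids
  extra <- case_record("case99999",
                       list(coded_event("I60.9", "icd10", day(0)),
                            coded_event("803.900", "procedure", day(1))))
  sel2 <- select_cases(c(reg, list(extra)))
  for (nm in names(sel$selected))
    expect_true(all(sel$selected[[nm]] %in% sel2$selected[[nm]]))

  # shrinking the window never grows a selected set
  cfg <- default_search_config()
  tight <- lapply(cfg$criteria, function(cr) { cr$window_days <- 2; cr })
  sel_tight <- select_cases(reg, tight, cfg$phrases)
  for (i in seq_along(tight))
    expect_true(all(sel_tight$selected[[i]] %in% sel$selected[[i]]))

  # a record can hit both a criterion and a phrase
  both <- case_record("caseboth",
                      list(coded_event("I63.9", "icd10", day(0)),
                           coded_event("803.900", "procedure", day(1))),
                      "Normal head CT")
  sboth <- select_cases(list(both))
  expect_equal(sboth$selected[[1]], "caseboth")
  expect_equal(sboth$keyword_hits, "caseboth")

  expect_error(select_cases(list(both, both)), "duplicate case ids")
})

test_that("registry CSV round-trip preserves events, timestamps and reports", {
  reg <- gen_registry(30, criterion_counts = c(3L, 2L, 1L), keyword_count = 2L,
                      seed = 5)
  ev <- withr::local_tempfile(fileext = ".csv")
  rp <- withr::local_tempfile(fileext = ".csv")
  write_registry_csv(reg, ev, rp)
  reg2 <- read_registry_csv(ev, rp)
  expect_equal(select_cases(reg2), select_cases(reg))
  expect_equal(vapply(reg2, `[[`, "", "case_id"),
               vapply(reg, `[[`, "", "case_id"))
})
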