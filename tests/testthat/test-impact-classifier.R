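test_that("classify_t uses the ties-up boundary convention", {
  th <- threshold_set(c(50, 60, 70))
  lv <- classify_t(c(49, 50, 59.9, 60, 69.9, 70, 83.8), th)
  expect_identical(as.character(lv),
                   c("none", "mild", "mild", "moderate", "moderate",
                     "high", "high"))
  expect_identical(attr(lv, "index"), c(0L, 1L, 1L, 2L, 2L, 3L, 3L))
  # nondecreasing in t
  t_grid <- seq(30, 90, by = 0.25)
  expect_true(all(diff(attr(classify_t(t_grid, th), "index")) >= 0))
  expect_error(classify_t(NaN, th), "finite")
})

test_that("classify_sample conserves n and matches a direct tally", {
  th <- threshold_set(c(50, 60, 70))
  expect_error(classify_sample(numeric(0), th), "non-empty")
  all_low <- classify_sample(rep(40, 7), th)
  expect_equal(all_low$count, c(7, 0, 0, 0))
  expect_equal(all_low$proportion, c(1, 0, 0, 0))
  grid <- classify_sample(seq(40, 80, by = 1), th)
  expect_true(all(grid$count > 0))

  set.seed(31)
  scores <- rnorm(10000, 62.5, 7.5)
  cs <- classify_sample(scores, th)
  expect_equal(sum(cs$count), 10000)
  expect_equal(sum(cs$proportion), 1)
  # brute-force tally oracle
  expect_equal(cs$count,
               c(sum(scores < 50),
                 sum(scores >= 50 & scores < 60),
                 sum(scores >= 60 & scores < 70),
                 sum(scores >= 70)))
})

test_that("peg_score sums the three 0-10 items", {
  r <- gcpsr_responses(freq_pain = c(2, 0, 3), freq_limit = c(2, 0, 3),
                       peg_intensity = c(4, 0, 10),
                       peg_enjoyment = c(4, 0, 10),
                       peg_activity = c(3, 0, 10))
  expect_identical(peg_score(r), c(11L, 0L, 30L))
  expect_error(gcpsr_responses(1, 1, 11, 0, 0), "0..10")
  expect_error(gcpsr_responses(5, 1, 1, 1, 1), "0..3")
  expect_error(gcpsr_responses("sometimes", 1, 1, 1, 1), "unrecognized")
})

test_that("gcpsr_classify implements the rubric with both gates", {
  r <- gcpsr_responses(
    freq_pain  = c("most days", "every day", "some days", "most days",
                   "never", "some days"),
    freq_limit = c("every day", "some days", "never", "most days",
                   "never", "some days"),
    peg_intensity = c(2, 4, 7, 1, 0, 4),
    peg_enjoyment = c(2, 4, 7, 1, 0, 4),
    peg_activity  = c(1, 4, 6, 1, 0, 3))
  lv <- gcpsr_classify(r)
  # both items most/every day -> HICP regardless of PEG
  expect_identical(as.character(lv[1]), "high impact")
  expect_identical(as.character(lv[4]), "high impact")
  # PEG = 12 boundary -> bothersome; chronic-pain gate passes (every day)
  expect_identical(as.character(lv[2]), "bothersome")
  # default gate: pain on some days only -> no impact, whatever the PEG
  expect_identical(as.character(lv[3]), "no impact")
  expect_identical(as.character(lv[5]), "no impact")
  expect_identical(as.character(lv[6]), "no impact")
  # never_only gate reclassifies the some-days records by PEG
  lv2 <- gcpsr_classify(r, gate = "never_only")
  expect_identical(as.character(lv2[3]), "bothersome")  # PEG 20 >= 12
  expect_identical(as.character(lv2[6]), "mild")        # PEG 11 < 12
  expect_identical(as.character(lv2[5]), "no impact")
  # HICP unchanged by the gate
  expect_identical(as.character(lv2[c(1, 4)]), rep("high impact", 2))
})

test_that("gcpsr_classify refuses incomplete records with a reason", {
  r <- gcpsr_responses(freq_pain = c("most days", NA, "every day"),
                       freq_limit = c("most days", "never", "some days"),
                       peg_intensity = c(1, 1, NA),
                       peg_enjoyment = c(1, 1, 2),
                       peg_activity = c(1, 1, 2))
  lv <- gcpsr_classify(r)
  expect_identical(as.character(lv[1]), "high impact")
  expect_true(is.na(lv[2]))
  expect_true(is.na(lv[3]))
  refused <- attr(lv, "refused")
  expect_identical(refused[2], "missing_frequency_item")
  expect_identical(refused[3], "missing_peg_item")
})

test_that("rubric is exhaustive and monotone in the PEG items", {
  # every complete response maps to exactly one of the 4 levels
  grid <- expand.grid(fp = 0:3, fl = 0:3, peg = c(0, 11, 12, 30))
  r <- gcpsr_responses(grid$fp, grid$fl,
                       pmin(grid$peg, 10),
                       pmin(pmax(grid$peg - 10, 0), 10),
                       pmin(pmax(grid$peg - 20, 0), 10))
  for (gate in c("chronic_pain", "never_only")) {
    lv <- gcpsr_classify(r, gate = gate)
    expect_false(anyNA(lv))
    expect_true(all(as.character(lv) %in%
                      c("no impact", "mild", "bothersome", "high impact")))
  }
  # raising a PEG item never lowers the level at fixed frequencies,
  # and HICP status ignores PEG entirely
  set.seed(41)
  for (i in 1:50) {
    fp <- sample(0:3, 1); fl <- sample(0:3, 1)
    p <- sample(0:9, 3, replace = TRUE)
    r1 <- gcpsr_responses(fp, fl, p[1], p[2], p[3])
    r2 <- gcpsr_responses(fp, fl, p[1] + 1, p[2], p[3])
    expect_gte(as.integer(gcpsr_classify(r2)), as.integer(gcpsr_classify(r1)))
    if (fp >= 2 && fl >= 2)
      expect_identical(as.character(gcpsr_classify(r1)), "high impact")
  }
})

test_that("GCPS-R CSV reader accepts both dialects", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(
    "respondent_id,freq_pain,freq_limit,peg_intensity,peg_enjoyment,peg_activity",
    "a,most days,every day,5,5,5",
    "b,1,0,2,3,4"), f)
  r <- read_gcpsr(f)
  expect_identical(r$freq_pain, c(2L, 1L))
  expect_identical(r$freq_limit, c(3L, 0L))
  expect_identical(peg_score(r), c(15L, 9L))
  f2 <- withr::local_tempfile(fileext = ".csv")
  writeLines("respondent_id,freq_pain", f2)
  expect_error(read_gcpsr(f2), "missing columns")
})
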