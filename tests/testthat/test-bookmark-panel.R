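test_that("individual thresholds are half-up rounded adjacent-score means", {
  vs <- fixed_vignette_set(c(44, 50, 56, 60, 63, 66, 71, 76))
  # vignettes scored 63 and 66 -> threshold 65 (mean 64.5 rounds half-up)
  p <- bookmark_placement("p1", "PLwCP", c(1, 3, 5))
  th <- individual_thresholds(p, vs)
  expect_equal(th$thresholds, c(47, 58, 65))
  expect_equal(th$thresholds[3], 65)
  # identical neighbors give their common score
  vs2 <- fixed_vignette_set(c(44, 50, 60, 60, 63, 66, 71, 76))
  expect_equal(individual_thresholds(
    bookmark_placement("p", "PLwCP", 3), vs2,
    labels = c("none", "mild"))$thresholds, 60)
  # exact mean needs no rounding: (44 + 50) / 2 = 47
  expect_equal(individual_thresholds(
    bookmark_placement("p", "PLwCP", 1), vs,
    labels = c("none", "mild"))$thresholds, 47)
  # gap out of range names the panelist
  expect_error(individual_thresholds(
    bookmark_placement("bad", "PLwCP", c(1, 3, 8)), vs), "bad")
  expect_error(bookmark_placement("p", "PLwCP", c(3, 2, 4)), "nondecreasing")
  # thresholds nondecreasing whenever gaps are (shared gap -> equal cuts)
  th_eq <- individual_thresholds(bookmark_placement("p", "PLwCP", c(2, 2, 5)),
                                 vs)
  expect_true(all(diff(th_eq$thresholds) >= 0))
})

test_that("modal thresholds take the per-boundary mode with the tie rule", {
  vs <- fixed_vignette_set(c(44, 50, 56, 60, 63, 66, 71, 76))
  mk <- function(id, gaps) bookmark_placement(id, "PLwCP", gaps)
  # unique mode: 6 panelists at gap 2 vs 4 at gap 3 on the first boundary
  pls <- c(lapply(1:6, function(i) mk(paste0("a", i), c(2, 4, 6))),
           lapply(1:4, function(i) mk(paste0("b", i), c(3, 4, 6))))
  th <- modal_thresholds(pls, vs)
  expect_equal(th$thresholds[1], 53)  # (50 + 56) / 2
  expect_false(th$ties[1])
  expect_equal(th$n_panelists, 10L)
  # 5 vs 5 tie: nearest the median, then lower -> lower candidate, flagged
  pls2 <- c(lapply(1:5, function(i) mk(paste0("a", i), c(2, 4, 6))),
            lapply(1:5, function(i) mk(paste0("b", i), c(3, 4, 6))))
  th2 <- modal_thresholds(pls2, vs)
  expect_equal(th2$thresholds[1], 53)
  expect_true(th2$ties[1])
  # single panelist: mode of one
  th3 <- modal_thresholds(list(mk("solo", c(1, 3, 5))), vs)
  expect_equal(th3$thresholds, c(47, 58, 65))
  # modal value always belongs to the multiset of individual thresholds
  indiv1 <- vapply(pls, function(p)
    individual_thresholds(p, vs)$thresholds[1], numeric(1))
  expect_true(th$thresholds[1] %in% indiv1)
  # empty panel and non-increasing modal sequence are errors
  expect_error(modal_thresholds(list(), vs), "empty panel")
  expect_error(modal_thresholds(pls, vs, panel_filter = "clinician"),
               "empty panel")
  shared <- lapply(1:3, function(i) mk(paste0("s", i), c(2, 2, 5)))
  expect_error(modal_thresholds(shared, vs), "not strictly increasing")
})

test_that("panel filtering separates PLwCP and clinician thresholds", {
  vs <- fixed_vignette_set(c(44, 50, 56, 60, 63, 66, 71, 76))
  pls <- c(lapply(1:5, function(i)
             bookmark_placement(paste0("p", i), "PLwCP", c(2, 4, 6))),
           lapply(1:5, function(i)
             bookmark_placement(paste0("c", i), "clinician", c(2, 3, 6))))
  th_p <- modal_thresholds(pls, vs, panel_filter = "PLwCP")
  th_c <- modal_thresholds(pls, vs, panel_filter = "clinician")
  expect_equal(th_p$thresholds[2], 62)  # (60 + 63) / 2 rounded half-up
  expect_equal(th_c$thresholds[2], 58)  # clinicians one vignette lower
  expect_equal(th_p$n_panelists, 5L)
})

test_that("threshold_distribution is an exhaustive tally", {
  vs <- fixed_vignette_set(c(44, 50, 56, 60, 63, 66, 71, 76))
  set.seed(21)
  pls <- lapply(1:10, function(i)
    bookmark_placement(paste0("p", i), "PLwCP",
                       sort(sample.int(7, 3, replace = TRUE))))
  dist <- threshold_distribution(pls, vs)
  for (k in 1:3)
    expect_equal(sum(dist$count[dist$boundary == k]), 10)
  # counts match a direct brute-force tally
  for (r in seq_len(nrow(dist))) {
    vals <- vapply(pls, function(p)
      individual_thresholds(p, vs)$thresholds[dist$boundary[r]], numeric(1))
    expect_equal(dist$count[r], sum(vals == dist$threshold[r]))
  }
  # all identical placements: one nonzero cell per boundary
  same <- lapply(1:4, function(i)
    bookmark_placement(paste0("s", i), "PLwCP", c(1, 4, 6)))
  d2 <- threshold_distribution(same, vs)
  expect_equal(nrow(d2), 3)
  expect_true(all(d2$count == 4))
})

test_that("placements CSV and threshold JSON round-trip", {
  pls <- list(bookmark_placement("p1", "PLwCP", c(2, 4, 6)),
              bookmark_placement("c1", "clinician", c(2, 3, 6)))
  f <- withr::local_tempfile(fileext = ".csv")
  write_placements(pls, f)
  back <- read_placements(f)
  expect_equal(back, pls)

  th <- threshold_set(c(52, 61, 72), provenance = "modal", n_panelists = 10L,
                      ties = c(FALSE, TRUE, FALSE))
  fj <- withr::local_tempfile(fileext = ".json")
  write_threshold_set(th, fj)
  expect_equal(read_threshold_set(fj), th)
})

test_that("simulated panels recover generating thresholds (small replicate run)", {
  bank <- reference_bank()
  vs <- build_vignette_set(bank, n_items = 6)
  truth <- true_thresholds_from_gaps(vs)
  half_spacing <- max(diff(calibrated_scores(vs))) / 2
  hits <- 0L
  n_rep <- 50L
  for (s in seq_len(n_rep)) {
    cfg <- simulation_config(seed = 1000 + s, n_panelists = 10L,
                             placement_noise_sd = 2.5)
    th <- modal_thresholds(simulate_panel(cfg, truth, vs), vs)
    if (all(abs(th$thresholds - truth$thresholds) <= half_spacing))
      hits <- hits + 1L
  }
  expect_gte(hits / n_rep, 0.9)
})
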