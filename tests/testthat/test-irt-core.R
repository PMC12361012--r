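test_that("item and bank constructors enforce their invariants", {
  expect_s3_class(symmetric_item(), "item_parameters")
  expect_error(item_parameters("x", a = -1, b = c(-2, -1, 1, 2)), "positive")
  expect_error(item_parameters("x", a = 1, b = c(-2, 1, 1, 2)), "increasing")
  expect_error(item_parameters("x", a = 1, b = c(-1, 0, 1)), "4")
  expect_error(item_parameters("x", a = 1, b = c(-2, -1, 1, 2),
                               category_labels = letters[1:4]), "5 category")
  expect_error(item_bank(list(symmetric_item(), symmetric_item())), "unique")
  expect_error(item_bank(list()), "at least one")
  expect_error(item_bank(list(symmetric_item()), t_mean = 0), "fixed")
})

test_that("boundary_prob matches the logistic closed form", {
  it <- symmetric_item()
  # theta at the boundary location is the logistic midpoint
  for (k in 1:4) expect_equal(boundary_prob(it$b[k], it, k), 0.5)
  # closed form 1 / (1 + exp(-1.7)) for a = 1.7 one unit above the boundary
  it17 <- item_parameters("x", a = 1.7, b = c(-2, -1, 1, 2))
  expect_equal(boundary_prob(it17$b[2] + 1, it17, 2), 1 / (1 + exp(-1.7)),
               tolerance = 1e-12)
  expect_equal(round(boundary_prob(it17$b[2] + 1, it17, 2), 4), 0.8455)
  # tails and monotonicity in theta
  expect_lt(boundary_prob(-30, it, 1), 1e-10)
  th <- seq(-4, 4, by = 0.1)
  expect_true(all(diff(boundary_prob(th, it, 3)) > 0))
  expect_error(boundary_prob(0, it, 5), "1..4")
  expect_error(boundary_prob(Inf, it, 1), "finite")
})

test_that("category_probs are adjacent boundary differences summing to 1", {
  it <- symmetric_item()
  p <- category_probs(0, it)
  expect_equal(sum(p), 1, tolerance = 1e-12)
  expect_equal(unname(p[3]), plogis(2) - plogis(-2), tolerance = 1e-12)
  expect_equal(round(unname(p[3]), 4), 0.7616)
  expect_gt(category_probs(-10, it)[1], 0.999)
  # property: sums to 1 and matches the from-scratch oracle on random items
  set.seed(11)
  for (r in 1:25) {
    a <- exp(rnorm(1, log(1.5), 0.4))
    b <- sort(rnorm(4, 0, 1.5))
    while (any(diff(b) <= 0)) b <- sort(rnorm(4, 0, 1.5))
    it_r <- item_parameters("r", a = a, b = b)
    theta <- rnorm(1, 0, 2)
    expect_equal(sum(category_probs(theta, it_r)), 1, tolerance = 1e-12)
    expect_equal(unname(category_probs(theta, it_r)),
                 oracle_category_probs(theta, a, b), tolerance = 1e-12)
  }
  # extreme category curves are monotone in theta
  th <- seq(-4, 4, by = 0.05)
  pm <- category_probs(th, it)
  expect_true(all(diff(pm[, 1]) < 0))
  expect_true(all(diff(pm[, 5]) > 0))
})

test_that("most_likely_response agrees with the argmax oracle; ties go low", {
  it <- symmetric_item()
  expect_identical(most_likely_response(0, it), 3L)
  expect_identical(most_likely_response(-3, it), 1L)
  set.seed(12)
  for (r in 1:25) {
    b <- sort(rnorm(4, 0, 1.5))
    it_r <- item_parameters("r", a = runif(1, 0.7, 3), b = b)
    theta <- rnorm(1, 0, 2)
    expect_identical(most_likely_response(theta, it_r),
                     oracle_modal_category(theta, it_r$a, it_r$b))
  }
})

test_that("response_map is the nondecreasing modal map over a T grid", {
  it <- symmetric_item()
  expect_identical(response_map(it, c(30, 50, 85)), c(1L, 3L, 5L))
  expect_identical(response_map(it, 50), 3L)
  expect_error(response_map(it, c(50, 40)), "sorted")
  # boundaries far above the grid force constant category 1
  hi <- item_parameters("hi", a = 2, b = c(5, 6, 7, 8))
  expect_identical(response_map(hi, seq(30, 70, by = 5)), rep(1L, 9))
  # nondecreasing for every item of a generated bank
  bank <- reference_bank()
  grid <- seq(20, 90, by = 0.5)
  for (it_b in bank$items)
    expect_true(all(diff(response_map(it_b, grid)) >= 0))
})

test_that("eap_score matches fine-grid integration and behaves at extremes", {
  bk <- one_item_bank()
  s <- eap_score(c(sym1 = 3L), bk)
  expect_equal(s$theta_hat, 0, tolerance = 1e-10)  # posterior symmetry
  expect_equal(s$t_score, 50, tolerance = 1e-8)
  expect_equal(s$t_score, 50 + 10 * s$theta_hat)
  expect_gt(s$se_theta, 0)

  bank <- reference_bank()
  ids <- names(bank$items)
  lo <- eap_score(setNames(rep(1L, 10), ids[1:10]), bank)
  hi <- eap_score(setNames(rep(5L, 10), ids[1:10]), bank)
  expect_lt(lo$t_score, 50)
  expect_gt(hi$t_score, 50)

  set.seed(13)
  for (r in 1:30) {
    pat <- random_pattern(bank, p_missing = 0.2)
    if (all(is.na(pat))) next
    got <- eap_score(pat, bank)
    want <- oracle_eap(pat, bank)
    expect_equal(got$t_score, want$t, tolerance = 0.01)
  }
  expect_error(eap_score(c(sym1 = NA_integer_), bk), "non-missing")
  expect_error(eap_score(c(sym1 = 7L), bk), "1..5")
  expect_error(eap_score(c(nope = 3L), bank), "not in the bank")
})

test_that("adding a modally-answered item pulls the EAP toward its theta", {
  bank <- reference_bank()
  ids <- names(bank$items)
  theta0 <- 2
  pat <- setNames(rep(2L, 5), ids[1:5])  # pattern well below theta0
  base <- eap_score(pat, bank)$theta_hat
  extra <- vapply(ids[6:10], function(id)
    most_likely_response(theta0, bank$items[[id]]), integer(1))
  pat2 <- c(pat, extra)
  expect_lt(abs(eap_score(pat2, bank)$theta_hat - theta0),
            abs(base - theta0))
})

test_that("score_range spans the all-lowest to all-highest patterns", {
  bk <- one_item_bank()
  r <- score_range(bk)
  expect_lt(r["min"], r["max"])
  # symmetric single item: range symmetric about 50
  expect_equal(unname(r["min"] + r["max"]), 100, tolerance = 0.1)
  # doubling the number of identical items widens the range
  bk2 <- item_bank(list(symmetric_item(),
                        item_parameters("sym2", a = 2, b = c(-2, -1, 1, 2))))
  r2 <- score_range(bk2)
  expect_lt(r2["min"], r["min"])
  expect_gt(r2["max"], r["max"])
  expect_error(score_range(bk, character(0)), "non-empty")
})

test_that("item bank JSON and response CSV round-trip", {
  bank <- reference_bank()
  f <- withr::local_tempfile(fileext = ".json")
  write_item_bank(bank, f)
  bank2 <- read_item_bank(f)
  expect_equal(bank2, bank)
  # slope-intercept dialect converts b = -c / a
  j <- jsonlite::read_json(f, simplifyVector = FALSE)
  j$items <- lapply(j$items, function(it) {
    it$c <- -it$a * unlist(it$b); it$b <- NULL; it
  })
  f2 <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(j, f2, auto_unbox = TRUE, digits = NA)
  bank3 <- read_item_bank(f2)
  expect_equal(bank3$items[[1]]$b, bank$items[[1]]$b, tolerance = 1e-12)

  cfg <- simulation_config(seed = 5, n_respondents = 20L)
  resp <- simulate_respondents(cfg, bank)$responses
  resp[1, 2] <- NA
  fc <- withr::local_tempfile(fileext = ".csv")
  write_responses(resp, fc)
  back <- read_responses(fc, bank)
  expect_identical(back, resp)
})
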