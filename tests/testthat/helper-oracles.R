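# Shared fixtures and independent oracles.  The oracles are written from
# first principles (plogis differences, fine-grid integration, record
# expansion) so they never share code with the package paths they check.

`%||%` <- function(a, b) if (is.null(a)) b else a

# the worked-example item used across the spec-style unit tests
symmetric_item <- function() {
  item_parameters("sym1", a = 2, b = c(-2, -1, 1, 2))
}

one_item_bank <- function(item = symmetric_item()) {
  item_bank(list(item), name = "one-item")
}

reference_bank <- function(seed = 42) {
  simulate_bank(simulation_config(seed = seed))
}

# Category probabilities straight from the logistic definition.
oracle_category_probs <- function(theta, a, b) {
  pstar <- c(1, plogis(a * (theta - b)), 0)
  pstar[1:5] - pstar[2:6]
}

oracle_modal_category <- function(theta, a, b) {
  which.max(oracle_category_probs(theta, a, b))
}

# Brute-force EAP: posterior mean/SD by numerical integration on a fine,
# wide grid (independent of the package quadrature choices).
oracle_eap <- function(pattern, bank, n_nodes = 801L, lim = 4) {
  grid <- seq(-lim, lim, length.out = n_nodes)
  post <- dnorm(grid)
  for (id in names(pattern)) {
    if (is.na(pattern[[id]])) next
    it <- bank$items[[id]]
    k <- pattern[[id]]
    pstar <- function(kk) if (kk == 0) 1 else if (kk == 5) 0 else
      plogis(it$a * (grid - it$b[kk]))
    post <- post * (pstar(k - 1) - pstar(k))
  }
  post <- post / sum(post)
  mu <- sum(post * grid)
  list(theta = mu, t = 50 + 10 * mu,
       se = sqrt(sum(post * (grid - mu)^2)))
}

# Random response pattern on a bank (categories uniform, optionally with
# missingness).
random_pattern <- function(bank, p_missing = 0) {
  ids <- names(bank$items)
  x <- sample.int(5L, length(ids), replace = TRUE)
  if (p_missing > 0) x[runif(length(x)) < p_missing] <- NA
  names(x) <- ids
  x
}

# A tiny fixed vignette set with known calibrated scores, for bookmark
# arithmetic tests that should not depend on any bank.
fixed_vignette_set <- function(scores = c(44, 50, 56, 60, 63, 66, 71, 76)) {
  vs <- lapply(seq_along(scores), function(i)
    structure(list(name = paste0("V", i), target_t = scores[i],
                   items = data.frame(item_id = "x", category = 3L,
                                      descriptor = "Somewhat"),
                   calibrated_t = scores[i], rank = i),
              class = "pi_vignette"))
  structure(list(vignettes = vs, bank_name = "fixed", spacing = 5),
            class = "vignette_set")
}

table2_counts <- function() {
  contingency_table(
    matrix(c(6, 5, 0, 0,
             37, 53, 58, 113,
             3, 0, 4, 65,
             0, 1, 4, 60), nrow = 4, byrow = TRUE),
    row_labels = c("no impact", "mild impact", "moderate impact",
                   "high impact"),
    col_labels = c("no impact", "mild impact", "bothersome", "high impact"))
}

table3_groups <- function() {
  group_summaries(
    label = c("No impact", "Mild impact", "Bothersome", "High impact"),
    n = c(46, 59, 66, 238),
    mean = c(55.8, 54.8, 60.7, 66.2),
    sd = c(7.1, 5.7, 4.6, 5.5))
}

# Expand a contingency table into paired unit records.
expand_table <- function(tab) {
  idx <- which(tab > 0, arr.ind = TRUE)
  rows <- rep(idx[, 1], tab[idx])
  cols <- rep(idx[, 2], tab[idx])
  list(a = rows, b = cols)
}
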