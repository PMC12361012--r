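# Seeded generators for every input the pipeline consumes.  The defaults
# state the world the analysis assumes: a 5-category GRM bank whose
# boundaries span roughly theta in [-1, 3] (so vignettes covering the
# clinic range are constructible), a tertiary-clinic score distribution
# well above the population mean, panelists who perceive each true cut with
# a few T points of noise, and GCPS-R components monotonically linked to
# the same latent trait.  All randomness flows from one master seed; each
# stage derives its own sub-seed so stages are independently reproducible.

#' Simulation configuration
#'
#' @param seed Master seed; every generator derives its stream from it.
#' @param n_items Bank size.
#' @param a_log_mean,a_log_sd Lognormal hyperparameters for discriminations.
#' @param b_center_min,b_center_max Range (theta units) over which item
#'   boundary centers are spread; the default \[-1, 2.5\] plus the boundary
#'   offsets makes banks span roughly theta in \[-1, 3\].
#' @param b_spread_mean,b_spread_sd Mean/SD of the half-spread of the four
#'   boundaries around the item center (theta units).
#' @param theta_mean_t,theta_sd_t Respondent trait distribution on the T
#'   metric.  Default T ~ N(62.5, 7.5): a tertiary-clinic shape in which a
#'   small minority falls below any plausible lowest cut and a sizeable
#'   minority above the highest.
#' @param n_respondents Number of simulated respondents.
#' @param n_panelists Panel size (default 10, a typical bookmarking panel).
#' @param placement_noise_sd Panelist perception noise in T units (default
#'   2.5, under half the conventional 5-T vignette spacing, emulating panels
#'   that mostly land within one vignette of each other).
#' @param gcpsr_freq_slope Discrimination of the ordered-logit links from
#'   theta to the two frequency items.
#' @param gcpsr_pain_cuts,gcpsr_limit_cuts Ordered-logit cutpoints (theta
#'   units) for the pain-frequency and limitation-frequency items.
#' @param gcpsr_peg_intercept,gcpsr_peg_slope,gcpsr_peg_sd Linear link from
#'   theta to each 0-10 PEG item (mean = intercept + slope * theta, normal
#'   noise, rounded and clipped to 0..10).
#' @return List of class `simulation_config`.
#' @export
simulation_config <- function(seed = 1L,
                              n_items = 20L,
                              a_log_mean = log(2), a_log_sd = 0.25,
                              b_center_min = -1, b_center_max = 2.5,
                              b_spread_mean = 1.2, b_spread_sd = 0.2,
                              theta_mean_t = 62.5, theta_sd_t = 7.5,
                              n_respondents = 1000L,
                              n_panelists = 10L,
                              placement_noise_sd = 2.5,
                              gcpsr_freq_slope = 1.5,
                              gcpsr_pain_cuts = c(-0.5, 0.4, 1.2),
                              gcpsr_limit_cuts = c(-0.2, 0.8, 1.6),
                              gcpsr_peg_intercept = 3.2,
                              gcpsr_peg_slope = 1.8,
                              gcpsr_peg_sd = 1.6) {
  cfg <- list(seed = as.integer(seed), n_items = as.integer(n_items),
              a_log_mean = a_log_mean, a_log_sd = a_log_sd,
              b_center_min = b_center_min, b_center_max = b_center_max,
              b_spread_mean = b_spread_mean, b_spread_sd = b_spread_sd,
              theta_mean_t = theta_mean_t, theta_sd_t = theta_sd_t,
              n_respondents = as.integer(n_respondents),
              n_panelists = as.integer(n_panelists),
              placement_noise_sd = placement_noise_sd,
              gcpsr_freq_slope = gcpsr_freq_slope,
              gcpsr_pain_cuts = gcpsr_pain_cuts,
              gcpsr_limit_cuts = gcpsr_limit_cuts,
              gcpsr_peg_intercept = gcpsr_peg_intercept,
              gcpsr_peg_slope = gcpsr_peg_slope,
              gcpsr_peg_sd = gcpsr_peg_sd)
  stopifnot(cfg$n_items >= 1L, cfg$n_respondents >= 1L,
            cfg$n_panelists >= 1L, cfg$theta_sd_t >= 0,
            cfg$placement_noise_sd >= 0, cfg$gcpsr_peg_sd >= 0,
            !is.na(cfg$seed))
  class(cfg) <- "simulation_config"
  cfg
}

# Derive a stage-specific seed from the master seed, keeping the result a
# valid 32-bit integer.
stage_seed <- function(cfg, offset) {
  as.integer((as.numeric(cfg$seed) * 97 + offset) %% .Machine$integer.max)
}

with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  code
}

sim_subdomains <- function() {
  c("chores", "social", "work", "cognition", "recreation", "sleep")
}

#' Simulate a GRM item bank
#'
#' Discriminations are lognormal; each item gets a boundary center spread
#' uniformly over the configured range and four boundaries at fixed offsets
#' (-1, -1/3, 1/3, 1) times a random half-spread around it, guaranteeing a
#' strictly increasing `b`.  Subdomain tags cycle through at least 4
#' interference subdomains.  The bank is clearly synthetic: real calibrated
#' item parameters are proprietary and not reproduced.
#'
#' @param cfg A [simulation_config()].
#' @return An [item_bank()] named `"synthetic-pain-interference"`.
#' @export
simulate_bank <- function(cfg = simulation_config()) {
  stopifnot(inherits(cfg, "simulation_config"))
  with_seed(stage_seed(cfg, 1L), {
    doms <- rep_len(sim_subdomains(), cfg$n_items)
    items <- lapply(seq_len(cfg$n_items), function(i) {
      a <- exp(stats::rnorm(1, cfg$a_log_mean, cfg$a_log_sd))
      center <- stats::runif(1, cfg$b_center_min, cfg$b_center_max)
      spread <- max(abs(stats::rnorm(1, cfg$b_spread_mean,
                                     cfg$b_spread_sd)), 0.3)
      b <- center + c(-1, -1/3, 1/3, 1) * spread
      item_parameters(sprintf("SPI%02d", i), a = a, b = b,
                      text = sprintf("Synthetic interference item %d (%s)",
                                     i, doms[i]),
                      subdomain = doms[i])
    })
    item_bank(items, name = "synthetic-pain-interference")
  })
}

#' Simulate respondents from a bank
#'
#' Latent traits are normal on the T metric per the config; responses are
#' drawn from each item's GRM category probabilities.  True traits are
#' returned for recovery tests.
#'
#' @param cfg A [simulation_config()].
#' @param bank An [item_bank()].
#' @return List with `theta` (true traits, theta metric), `t_true` (T
#'   metric) and `responses` (integer matrix respondents x items).
#' @export
simulate_respondents <- function(cfg, bank) {
  stopifnot(inherits(cfg, "simulation_config"), inherits(bank, "item_bank"))
  with_seed(stage_seed(cfg, 2L), {
    n <- cfg$n_respondents
    theta <- stats::rnorm(n, t_to_theta(cfg$theta_mean_t), cfg$theta_sd_t / 10)
    ids <- bank_item_ids(bank)
    resp <- matrix(NA_integer_, n, length(ids),
                   dimnames = list(sprintf("R%05d", seq_len(n)), ids))
    u <- matrix(stats::runif(n * length(ids)), n, length(ids))
    for (j in seq_along(ids)) {
      cp <- cum_probs(theta, bank$items[[ids[j]]])
      # category = 1 + number of boundary curves the uniform falls below
      resp[, j] <- as.integer(1L + rowSums(u[, j] < cp[, 2:5, drop = FALSE]))
    }
    list(theta = theta, t_true = theta_to_t(theta), responses = resp)
  })
}

#' Simulate a bookmarking panel
#'
#' Each panelist perceives every true threshold with independent normal
#' noise (T units) and bookmarks the gap whose midpoint — the mean of the
#' two adjacent calibrated vignette scores — is nearest the perceived value.
#' Gaps are forced nondecreasing by sequential clipping, as a panelist
#' working left to right cannot place a later bookmark before an earlier
#' one.
#'
#' @param cfg A [simulation_config()].
#' @param true_thresholds A [threshold_set()] whose cuts lie inside the
#'   vignette score range.
#' @param vset A [build_vignette_set()].
#' @param panel Panel tag for the generated placements.
#' @return List of [bookmark_placement()] objects, one per panelist.
#' @export
simulate_panel <- function(cfg, true_thresholds, vset, panel = "PLwCP") {
  stopifnot(inherits(cfg, "simulation_config"),
            inherits(true_thresholds, "threshold_set"),
            inherits(vset, "vignette_set"))
  cal <- calibrated_scores(vset)
  th <- true_thresholds$thresholds
  if (any(th < min(cal) | th > max(cal)))
    stop("true thresholds must lie within the vignette score range",
         call. = FALSE)
  mids <- (cal[-length(cal)] + cal[-1L]) / 2
  with_seed(stage_seed(cfg, 3L), {
    lapply(seq_len(cfg$n_panelists), function(p) {
      perceived <- th + stats::rnorm(length(th), 0, cfg$placement_noise_sd)
      gaps <- integer(length(th))
      prev <- 1L
      for (k in seq_along(th)) {
        g <- which.min(abs(mids - perceived[k]))
        gaps[k] <- max(g, prev)
        prev <- gaps[k]
      }
      bookmark_placement(sprintf("P%02d", p), panel, gaps)
    })
  })
}

#' Simulate GCPS-R responses linked to the latent trait
#'
#' Frequency items follow ordered-logit links in theta; PEG items have a
#' linear-in-theta mean with normal noise, rounded and clipped to 0..10.
#' Higher theta stochastically raises every component, so the GCPS-R levels
#' correlate with the trait-based classification without being determined
#' by it.
#'
#' @param cfg A [simulation_config()].
#' @param theta Numeric vector of true traits (theta metric).
#' @return A [gcpsr_responses()] data frame with `nrow = length(theta)`.
#' @export
simulate_gcpsr <- function(cfg, theta) {
  stopifnot(inherits(cfg, "simulation_config"), is.numeric(theta),
            all(is.finite(theta)))
  with_seed(stage_seed(cfg, 4L), {
    n <- length(theta)
    draw_freq <- function(cuts) {
      cum <- vapply(cuts, function(ct)
        stats::plogis(cfg$gcpsr_freq_slope * (theta - ct)), numeric(n))
      if (n == 1L) cum <- matrix(cum, nrow = 1L)
      u <- stats::runif(n)
      as.integer(rowSums(u < cum))  # 0..3
    }
    fp <- draw_freq(cfg$gcpsr_pain_cuts)
    fl <- draw_freq(cfg$gcpsr_limit_cuts)
    draw_peg <- function() {
      mu <- cfg$gcpsr_peg_intercept + cfg$gcpsr_peg_slope * theta
      pmin(pmax(as.integer(round_half_up(
        mu + stats::rnorm(n, 0, cfg$gcpsr_peg_sd))), 0L), 10L)
    }
    gcpsr_responses(fp, fl, draw_peg(), draw_peg(), draw_peg(),
                    respondent_id = sprintf("R%05d", seq_len(n)))
  })
}

#' Simulate a complete study and write its artifacts
#'
#' Runs bank -> vignettes -> respondents -> panel -> GCPS-R with one master
#' seed and writes `bank.json`, `vignettes.json`, `responses.csv`,
#' `panel.csv`, `gcpsr.csv`, `truths.csv` to `out_dir`.  The generating
#' thresholds are the integer midpoint thresholds implied by placing true
#' cuts at the 2nd, 4th and 6th gaps of the vignette set.
#'
#' @param cfg A [simulation_config()].
#' @param out_dir Output directory (created if needed).
#' @param n_vignettes,n_items_per_vignette Vignette-set geometry.
#' @return Invisibly, a list with the in-memory objects (`bank`, `vset`,
#'   `truth`, `respondents`, `placements`, `gcpsr`, `files`).
#' @export
simulate_study <- function(cfg = simulation_config(), out_dir,
                           n_vignettes = 8L, n_items_per_vignette = 6L) {
  stopifnot(inherits(cfg, "simulation_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  bank <- simulate_bank(cfg)
  vset <- build_vignette_set(bank, n_vignettes = n_vignettes,
                             n_items = min(n_items_per_vignette,
                                           length(bank)))
  truth <- true_thresholds_from_gaps(vset, gaps = c(2L, 4L, 6L))
  resp <- simulate_respondents(cfg, bank)
  placements <- simulate_panel(cfg, truth, vset)
  gc <- simulate_gcpsr(cfg, resp$theta)

  files <- list(
    bank = file.path(out_dir, "bank.json"),
    vignettes = file.path(out_dir, "vignettes.json"),
    responses = file.path(out_dir, "responses.csv"),
    panel = file.path(out_dir, "panel.csv"),
    gcpsr = file.path(out_dir, "gcpsr.csv"),
    truths = file.path(out_dir, "truths.csv"))
  write_item_bank(bank, files$bank)
  write_vignette_set(vset, files$vignettes)
  write_responses(resp$responses, files$responses)
  write_placements(placements, files$panel)
  utils::write.csv(as.data.frame(gc), files$gcpsr, row.names = FALSE)
  utils::write.csv(
    data.frame(respondent_id = rownames(resp$responses),
               theta = resp$theta, t_true = resp$t_true),
    files$truths, row.names = FALSE)
  invisible(list(bank = bank, vset = vset, truth = truth,
                 respondents = resp, placements = placements, gcpsr = gc,
                 files = files))
}

#' Threshold set implied by fixed gaps of a vignette set
#'
#' Convenience for simulation truth: the integer midpoint thresholds of the
#' given gaps.
#'
#' @param vset A [build_vignette_set()].
#' @param gaps Integer gap indices, strictly increasing.
#' @param labels Level labels.
#' @export
true_thresholds_from_gaps <- function(vset, gaps = c(2L, 4L, 6L),
                                      labels = default_level_labels()) {
  p <- bookmark_placement("truth", "PLwCP", gaps)
  s <- individual_thresholds(p, vset, labels)
  threshold_set(s$thresholds, labels = s$labels, provenance = "modal",
                n_panelists = 0L)
}
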