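# Two independent classification rubrics: (1) pain-interference T-scores cut
# by a bookmark-derived threshold set; (2) the GCPS-R rubric from two
# frequency items and the 3-item PEG sum.

#' Classify T-scores into impact levels
#'
#' Level = number of thresholds at or below the score: a score exactly equal
#' to a threshold goes to the HIGHER level, because each threshold is the
#' midpoint before the first vignette better described by the higher level.
#'
#' @param t Numeric vector of T-scores.
#' @param thresholds A [threshold_set()] (strictly increasing).
#' @return Ordered factor of level labels, same length as `t`, with the
#'   integer level index (0-based) in attribute `"index"`.
#' @examples
#' th <- threshold_set(c(50, 60, 70))
#' classify_t(c(49, 60, 83.8), th)
#' @export
classify_t <- function(t, thresholds) {
  stopifnot(inherits(thresholds, "threshold_set"))
  if (any(diff(thresholds$thresholds) <= 0))
    stop("thresholds must be strictly increasing for classification",
         call. = FALSE)
  if (!is.numeric(t) || anyNA(t) || any(!is.finite(t)))
    stop("'t' must be finite numeric", call. = FALSE)
  idx <- rowSums(outer(t, thresholds$thresholds, `>=`))
  out <- factor(thresholds$labels[idx + 1L], levels = thresholds$labels,
                ordered = TRUE)
  attr(out, "index") <- as.integer(idx)
  out
}

#' Tabulate impact levels in a sample of scores
#'
#' @param scores Non-empty numeric vector of T-scores.
#' @param thresholds A [threshold_set()].
#' @return Data frame with `level` (0-based index), `label`, `count`,
#'   `proportion`; counts sum to `length(scores)`, proportions to 1.  Every
#'   level appears, including empty ones.
#' @export
classify_sample <- function(scores, thresholds) {
  if (length(scores) == 0L)
    stop("'scores' must be non-empty", call. = FALSE)
  lv <- classify_t(scores, thresholds)
  counts <- table(lv)  # factor levels keep empty categories
  data.frame(level = seq_along(thresholds$labels) - 1L,
             label = thresholds$labels,
             count = as.integer(counts),
             proportion = as.numeric(counts) / length(scores),
             row.names = NULL)
}

gcpsr_freq_levels <- function() c("never", "some days", "most days",
                                  "every day")

gcpsr_level_labels <- function() c("no impact", "mild", "bothersome",
                                   "high impact")

# Accepts verbatim frequency strings or the 0-3 integer dialect; returns an
# integer 0..3 (NA passes through).
parse_freq <- function(x) {
  if (is.numeric(x)) {
    x <- as.integer(x)
    if (any(!is.na(x) & (x < 0L | x > 3L)))
      stop("numeric frequency responses must be 0..3", call. = FALSE)
    return(x)
  }
  x <- trimws(tolower(as.character(x)))
  x[x == ""] <- NA_character_
  m <- match(x, gcpsr_freq_levels()) - 1L
  # mixed dialects in one column (verbatim strings next to 0-3 integers)
  # are tolerated: anything not matching a label must parse as 0..3
  digit <- is.na(m) & !is.na(x) & grepl("^[0-3]$", x)
  m[digit] <- as.integer(x[digit])
  if (any(is.na(m) & !is.na(x)))
    stop("unrecognized frequency response: ",
         paste(unique(x[is.na(m) & !is.na(x)]), collapse = ", "),
         call. = FALSE)
  m
}

#' Construct GCPS-R responses
#'
#' The 6-item Graded Chronic Pain Scale - Revised record: how often the
#' respondent had pain and life-or-work-limiting pain in the last 3 months
#' (never / some days / most days / every day), plus the three 0-10 PEG
#' items (pain intensity, interference with enjoyment of life, interference
#' with general activities).
#'
#' @param freq_pain,freq_limit Frequency responses, verbatim strings or
#'   0-3 integers.
#' @param peg_intensity,peg_enjoyment,peg_activity Integers 0-10.
#' @param respondent_id Optional ids.
#' @return Data frame of class `gcpsr_responses` with integer-coded columns
#'   `freq_pain`, `freq_limit` (0..3) and the three PEG items.
#' @export
gcpsr_responses <- function(freq_pain, freq_limit, peg_intensity,
                            peg_enjoyment, peg_activity,
                            respondent_id = NULL) {
  fp <- parse_freq(freq_pain); fl <- parse_freq(freq_limit)
  pegs <- list(peg_intensity = peg_intensity, peg_enjoyment = peg_enjoyment,
               peg_activity = peg_activity)
  pegs <- lapply(pegs, function(p) {
    p <- as.integer(p)
    if (any(!is.na(p) & (p < 0L | p > 10L)))
      stop("PEG items must be integers in 0..10", call. = FALSE)
    p
  })
  n <- length(fp)
  if (any(vapply(pegs, length, integer(1L)) != n) || length(fl) != n)
    stop("all GCPS-R columns must have the same length", call. = FALSE)
  df <- data.frame(
    respondent_id = respondent_id %||% as.character(seq_len(n)),
    freq_pain = fp, freq_limit = fl,
    peg_intensity = pegs$peg_intensity,
    peg_enjoyment = pegs$peg_enjoyment,
    peg_activity = pegs$peg_activity,
    stringsAsFactors = FALSE)
  class(df) <- c("gcpsr_responses", "data.frame")
  df
}

#' Read GCPS-R responses from CSV
#'
#' Columns: `respondent_id`, `freq_pain`, `freq_limit`, `peg_intensity`,
#' `peg_enjoyment`, `peg_activity`.  Frequency values may be the verbatim
#' strings or 0-3 integers; both dialects are accepted.
#'
#' @param path CSV file path.
#' @return A [gcpsr_responses()] data frame.
#' @export
read_gcpsr <- function(path) {
  df <- utils::read.csv(path, colClasses = c(respondent_id = "character"))
  need <- c("respondent_id", "freq_pain", "freq_limit", "peg_intensity",
            "peg_enjoyment", "peg_activity")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("GCPS-R CSV missing columns: ",
                         paste(miss, collapse = ", "), call. = FALSE)
  gcpsr_responses(df$freq_pain, df$freq_limit, df$peg_intensity,
                  df$peg_enjoyment, df$peg_activity, df$respondent_id)
}

#' PEG score
#'
#' Sum of the three 0-10 PEG items, range 0-30.
#'
#' @param r A [gcpsr_responses()] data frame.
#' @return Integer vector; `NA` where any PEG item is missing.
#' @export
peg_score <- function(r) {
  stopifnot(inherits(r, "gcpsr_responses"))
  r$peg_intensity + r$peg_enjoyment + r$peg_activity
}

#' GCPS-R impact classification
#'
#' High-impact chronic pain (HICP) iff BOTH frequency items are "most days"
#' or "every day".  Otherwise the "no impact" gate applies, then the PEG sum
#' splits mild (< 12) from bothersome (>= 12).
#'
#' The source rubric's "no impact" gate is not fully specified here; two
#' gates are offered:
#' * `"chronic_pain"` (default): no impact iff pain itself is not present on
#'   most/every day (`freq_pain` in never/some days) — consistent with the
#'   chronic-pain definition underlying the scale.
#' * `"never_only"`: no impact iff `freq_pain == never`.
#'
#' @param r A [gcpsr_responses()] data frame.
#' @param gate `"chronic_pain"` or `"never_only"`.
#' @return Ordered factor with levels no impact < mild < bothersome <
#'   high impact.  Records with missing required items get `NA` and a reason
#'   in attribute `"refused"` (a character vector indexed like `r`); no
#'   imputation is performed.
#' @examples
#' r <- gcpsr_responses("most days", "every day", 2, 2, 1)
#' gcpsr_classify(r)  # high impact regardless of PEG
#' @export
gcpsr_classify <- function(r, gate = c("chronic_pain", "never_only")) {
  stopifnot(inherits(r, "gcpsr_responses"))
  gate <- match.arg(gate)
  n <- nrow(r)
  lv <- character(n)
  refused <- rep(NA_character_, n)
  peg <- peg_score(r)
  freq_ok <- !is.na(r$freq_pain) & !is.na(r$freq_limit)
  hicp <- freq_ok & r$freq_pain >= 2L & r$freq_limit >= 2L
  none <- if (gate == "chronic_pain") !is.na(r$freq_pain) & r$freq_pain <= 1L
          else !is.na(r$freq_pain) & r$freq_pain == 0L
  for (i in seq_len(n)) {
    if (!freq_ok[i]) { refused[i] <- "missing_frequency_item"; lv[i] <- NA
    } else if (hicp[i]) { lv[i] <- "high impact"
    } else if (none[i]) { lv[i] <- "no impact"
    } else if (is.na(peg[i])) { refused[i] <- "missing_peg_item"; lv[i] <- NA
    } else lv[i] <- if (peg[i] >= 12L) "bothersome" else "mild"
  }
  out <- factor(lv, levels = gcpsr_level_labels(), ordered = TRUE)
  attr(out, "refused") <- refused
  out
}
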