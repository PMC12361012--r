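# Bookmark standard setting: panelists lay the vignettes out in score order
# and place one bookmark per level boundary in the gap before the first
# vignette better described by the higher level.  A placement in gap g means
# "between vignette g and g+1"; the individual threshold for that boundary is
# the mean of the two adjacent calibrated scores, rounded half-up to integer
# T.  Modal values across the panel become the group thresholds.

default_level_labels <- function() c("none", "mild", "moderate", "high")

round_half_up <- function(x) floor(x + 0.5)

#' Construct a bookmark placement
#'
#' @param panelist_id Panelist identifier.
#' @param panel Panel name, `"PLwCP"` (persons living with chronic pain) or
#'   `"clinician"`.
#' @param gaps Ordered integer vector of gap indices, one per level boundary
#'   (3 boundaries for a 4-level rubric); gap `g` sits between vignettes `g`
#'   and `g + 1` (1-based).  Must be nondecreasing.
#' @return Object of class `bookmark_placement`.
#' @export
bookmark_placement <- function(panelist_id, panel = c("PLwCP", "clinician"),
                               gaps) {
  panel <- match.arg(panel)
  gaps <- as.integer(gaps)
  if (length(gaps) < 1L || anyNA(gaps) || any(gaps < 1L))
    stop("'gaps' must be positive integers", call. = FALSE)
  if (is.unsorted(gaps))
    stop(sprintf("panelist '%s': gaps must be nondecreasing", panelist_id),
         call. = FALSE)
  structure(list(panelist_id = as.character(panelist_id), panel = panel,
                 gaps = gaps),
            class = "bookmark_placement")
}

validate_placement <- function(p, vset) {
  n_gaps <- length(vset) - 1L
  if (any(p$gaps > n_gaps))
    stop(sprintf(
      "panelist '%s': gap index %d out of range (only %d gaps for %d vignettes)",
      p$panelist_id, max(p$gaps), n_gaps, length(vset)), call. = FALSE)
  invisible(p)
}

#' Read bookmark placements from CSV
#'
#' Columns: `panelist_id`, `panel`, then `gap_1 .. gap_K` (one per
#' boundary).
#'
#' @param path CSV file path.
#' @return List of [bookmark_placement()] objects.
#' @export
read_placements <- function(path) {
  df <- utils::read.csv(path, colClasses = c(panelist_id = "character"))
  gap_cols <- grep("^gap_[0-9]+$", names(df), value = TRUE)
  if (length(gap_cols) == 0L)
    stop("placements CSV needs gap_1..gap_K columns", call. = FALSE)
  gap_cols <- gap_cols[order(as.integer(sub("^gap_", "", gap_cols)))]
  lapply(seq_len(nrow(df)), function(i)
    bookmark_placement(df$panelist_id[i], df$panel[i],
                       as.integer(df[i, gap_cols])))
}

#' @rdname read_placements
#' @param placements List of placements.
#' @export
write_placements <- function(placements, path) {
  K <- length(placements[[1L]]$gaps)
  df <- do.call(rbind, lapply(placements, function(p)
    data.frame(panelist_id = p$panelist_id, panel = p$panel,
               t(stats::setNames(p$gaps, paste0("gap_", seq_len(K)))))))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Construct a threshold set
#'
#' `K` cut scores separating `K + 1` ordered impact levels on the T metric.
#'
#' @param thresholds Numeric vector of cut scores.  Must be strictly
#'   increasing unless `strict = FALSE` (individual panelists may place two
#'   bookmarks in the same gap, yielding equal thresholds; modal aggregation
#'   rejects such sequences).
#' @param labels `K + 1` ordered level names.
#' @param provenance `"individual"` or `"modal"`.
#' @param n_panelists Number of panelists contributing.
#' @param ties Logical vector flagging boundaries whose mode was ambiguous.
#' @param strict Enforce strictly increasing thresholds?
#' @return Object of class `threshold_set`.
#' @export
threshold_set <- function(thresholds, labels = default_level_labels(),
                          provenance = c("individual", "modal"),
                          n_panelists = 1L, ties = NULL, strict = TRUE) {
  provenance <- match.arg(provenance)
  thresholds <- as.numeric(thresholds)
  if (length(labels) != length(thresholds) + 1L)
    stop("need exactly one more label than thresholds", call. = FALSE)
  if (strict && any(diff(thresholds) <= 0))
    stop("thresholds must be strictly increasing", call. = FALSE)
  if (!strict && any(diff(thresholds) < 0))
    stop("thresholds must be nondecreasing", call. = FALSE)
  structure(list(thresholds = thresholds, labels = as.character(labels),
                 provenance = provenance,
                 n_panelists = as.integer(n_panelists),
                 ties = ties %||% rep(FALSE, length(thresholds))),
            class = "threshold_set")
}

#' @export
print.threshold_set <- function(x, ...) {
  cat(sprintf("Threshold set (%s, %d panelist%s):\n", x$provenance,
              x$n_panelists, if (x$n_panelists == 1L) "" else "s"))
  for (k in seq_along(x$thresholds))
    cat(sprintf("  %s | %s at T = %g%s\n", x$labels[k], x$labels[k + 1L],
                x$thresholds[k], if (x$ties[k]) " (modal tie)" else ""))
  invisible(x)
}

#' Individual thresholds from one panelist's bookmarks
#'
#' For each boundary, the threshold is the mean of the calibrated scores of
#' the two vignettes adjacent to the bookmark, rounded half-up to integer T
#' (vignettes scored 63 and 66 give a threshold of 65).
#'
#' @param p A [bookmark_placement()].
#' @param vset The [build_vignette_set()] the panelist bookmarked.
#' @param labels Level labels, `length(gaps) + 1` of them.
#' @return A [threshold_set()] with provenance `"individual"`.  Equal
#'   thresholds (two bookmarks sharing a gap) are permitted here and
#'   rejected later by [modal_thresholds()].
#' @export
individual_thresholds <- function(p, vset, labels = default_level_labels()) {
  stopifnot(inherits(p, "bookmark_placement"), inherits(vset, "vignette_set"))
  validate_placement(p, vset)
  cal <- calibrated_scores(vset)
  th <- round_half_up((cal[p$gaps] + cal[p$gaps + 1L]) / 2)
  threshold_set(th, labels = labels[seq_len(length(th) + 1L)],
                provenance = "individual", n_panelists = 1L,
                strict = FALSE)
}

#' Modal group thresholds across a panel
#'
#' Per boundary, the mode of the individual thresholds.  Multimodal ties are
#' resolved toward the candidate nearest the panel median for that boundary
#' (a remaining tie goes to the lower value) and flagged in the result.
#'
#' @param placements List of [bookmark_placement()] objects.
#' @param vset The bookmarked [build_vignette_set()].
#' @param panel_filter Optional panel name (`"PLwCP"` or `"clinician"`) to
#'   restrict to.
#' @param labels Level labels.
#' @return A [threshold_set()] with provenance `"modal"`.  Errors with
#'   diagnostics if the modal sequence is not strictly increasing.
#' @export
modal_thresholds <- function(placements, vset, panel_filter = NULL,
                             labels = default_level_labels()) {
  if (!is.null(panel_filter))
    placements <- Filter(function(p) p$panel == panel_filter, placements)
  if (length(placements) == 0L)
    stop("no placements to aggregate (empty panel after filtering)",
         call. = FALSE)
  indiv <- lapply(placements, individual_thresholds, vset = vset,
                  labels = labels)
  K <- length(indiv[[1L]]$thresholds)
  th <- numeric(K); tie <- logical(K)
  for (k in seq_len(K)) {
    vals <- vapply(indiv, function(s) s$thresholds[k], numeric(1L))
    tab <- table(vals)
    cand <- as.numeric(names(tab)[tab == max(tab)])
    if (length(cand) > 1L) {
      tie[k] <- TRUE
      d <- abs(cand - stats::median(vals))
      cand <- cand[d == min(d)]
      cand <- min(cand)
    }
    th[k] <- cand
  }
  if (any(diff(th) <= 0)) {
    i <- which(diff(th) <= 0)[1L]
    stop(sprintf(
      "modal thresholds not strictly increasing: boundary %d (%s|%s) = %g vs boundary %d (%s|%s) = %g",
      i, labels[i], labels[i + 1L], th[i],
      i + 1L, labels[i + 1L], labels[i + 2L], th[i + 1L]), call. = FALSE)
  }
  threshold_set(th, labels = labels[seq_len(K + 1L)], provenance = "modal",
                n_panelists = length(placements), ties = tie)
}

#' Distribution of individual thresholds across a panel
#'
#' Exhaustive tally of individual threshold values per boundary and panel,
#' the tabular form of the usual threshold-location figure.
#'
#' @inheritParams modal_thresholds
#' @return Tidy data frame with columns `boundary` (1..K), `threshold`,
#'   `count`, `panel`.  Counts within each (boundary, panel) sum to the
#'   panel size.
#' @export
threshold_distribution <- function(placements, vset,
                                   labels = default_level_labels()) {
  stopifnot(length(placements) >= 1L)
  rows <- do.call(rbind, lapply(placements, function(p) {
    s <- individual_thresholds(p, vset, labels)
    data.frame(boundary = seq_along(s$thresholds),
               threshold = s$thresholds, panel = p$panel)
  }))
  agg <- stats::aggregate(list(count = rows$boundary),
                          by = rows[c("boundary", "threshold", "panel")],
                          FUN = length)
  agg[order(agg$panel, agg$boundary, agg$threshold),
      c("boundary", "threshold", "count", "panel")]
}

#' Read / write a threshold set as JSON
#' @param x A [threshold_set()].
#' @param path File path.
#' @export
write_threshold_set <- function(x, path) {
  stopifnot(inherits(x, "threshold_set"))
  jsonlite::write_json(unclass(x), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_threshold_set
#' @export
read_threshold_set <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  threshold_set(raw$thresholds, labels = raw$labels,
                provenance = raw$provenance,
                n_panelists = raw$n_panelists, ties = raw$ties)
}
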