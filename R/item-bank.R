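#' Construct a graded-response-model item
#'
#' An item under the graded response model (GRM) for a 5-category ordinal
#' response.  The boundary curves are logistic in `a * (theta - b[k])`
#' (slope-location form); no additional 1.7 scaling constant is applied, so
#' `a` must already absorb any such constant.  Parameters supplied in
#' slope-intercept form (`a * theta + c[k]`) can be converted with
#' `b = -c / a`, which [read_item_bank()] does automatically when an item
#' carries a `c` field instead of `b`.
#'
#' @param item_id Unique item identifier.
#' @param a Discrimination, strictly positive.
#' @param b Numeric vector of 4 strictly increasing boundary locations on the
#'   theta metric.
#' @param text Item prompt (free text).
#' @param subdomain Content tag used for balancing vignettes across
#'   interference subdomains (e.g. `"chores"`, `"social"`).
#' @param category_labels Character vector of 5 verbal descriptors ordered
#'   from least to most interference.
#' @return An object of class `item_parameters`.
#' @examples
#' it <- item_parameters("PI1", a = 2, b = c(-2, -1, 1, 2))
#' category_probs(0, it)
#' @export
item_parameters <- function(item_id, a, b, text = "", subdomain = "general",
                            category_labels = default_category_labels()) {
  stopifnot(is.character(item_id), length(item_id) == 1L, nzchar(item_id))
  if (!is.numeric(a) || length(a) != 1L || !is.finite(a) || a <= 0)
    stop("'a' must be a single finite positive number", call. = FALSE)
  if (!is.numeric(b) || length(b) != 4L || anyNA(b) || any(!is.finite(b)))
    stop("'b' must be a numeric vector of 4 finite boundary locations",
         call. = FALSE)
  if (any(diff(b) <= 0))
    stop("boundary locations 'b' must be strictly increasing", call. = FALSE)
  if (length(category_labels) != 5L)
    stop("exactly 5 category labels are required (items are scored 1-5)",
         call. = FALSE)
  structure(
    list(item_id = item_id, text = text, subdomain = subdomain,
         a = as.numeric(a), b = as.numeric(b),
         category_labels = as.character(category_labels)),
    class = "item_parameters")
}

default_category_labels <- function() {
  c("Not at all", "A little bit", "Somewhat", "Quite a bit", "Very much")
}

#' @export
print.item_parameters <- function(x, ...) {
  cat(sprintf("GRM item '%s' [%s]  a = %.3f,  b = (%s)\n", x$item_id,
              x$subdomain, x$a, paste(sprintf("%.3f", x$b), collapse = ", ")))
  invisible(x)
}

#' Construct an item bank
#'
#' A named, ordered collection of GRM items calibrated on a T-score metric.
#' The metric constants are fixed at mean 50, SD 10 (the general-population
#' reference used by the pain interference measure).
#'
#' @param items List of [item_parameters()] objects.
#' @param name Bank name.
#' @param t_mean,t_sd T-score metric constants; fixed at (50, 10).
#' @return An object of class `item_bank`.
#' @export
item_bank <- function(items, name = "bank", t_mean = 50, t_sd = 10) {
  if (length(items) < 1L) stop("an item bank needs at least one item",
                               call. = FALSE)
  ok <- vapply(items, inherits, logical(1L), what = "item_parameters")
  if (!all(ok)) stop("all elements of 'items' must be item_parameters",
                     call. = FALSE)
  ids <- vapply(items, `[[`, character(1L), "item_id")
  if (anyDuplicated(ids)) stop("item_ids must be unique", call. = FALSE)
  if (!isTRUE(all.equal(c(t_mean, t_sd), c(50, 10))))
    stop("the T metric is fixed at mean 50, SD 10", call. = FALSE)
  names(items) <- ids
  structure(list(name = name, metric = list(t_mean = 50, t_sd = 10),
                 items = items),
            class = "item_bank")
}

#' @export
print.item_bank <- function(x, ...) {
  cat(sprintf("Item bank '%s': %d GRM items, T metric (M = %g, SD = %g)\n",
              x$name, length(x$items), x$metric$t_mean, x$metric$t_sd))
  doms <- table(vapply(x$items, `[[`, character(1L), "subdomain"))
  cat("  subdomains:", paste(sprintf("%s (%d)", names(doms), doms),
                             collapse = ", "), "\n")
  invisible(x)
}

#' @export
length.item_bank <- function(x) length(x$items)

bank_item_ids <- function(bank) names(bank$items)

bank_get_item <- function(bank, item_id) {
  it <- bank$items[[item_id]]
  if (is.null(it)) stop(sprintf("item '%s' not found in bank '%s'",
                                item_id, bank$name), call. = FALSE)
  it
}

#' Read / write an item bank as JSON
#'
#' The JSON schema is
#' `{"name", "metric": {"t_mean", "t_sd"}, "items": [{"item_id", "text",
#' "subdomain", "a", "b": [4 numbers], "category_labels": [5 strings]}]}`.
#' Items that carry a slope-intercept field `"c"` instead of `"b"` are
#' converted with `b = -c / a`.
#'
#' @param path File path.
#' @param bank An [item_bank()].
#' @return `read_item_bank` returns an `item_bank`; `write_item_bank`
#'   returns `path` invisibly.
#' @export
read_item_bank <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = FALSE)
  items <- lapply(raw$items, function(r) {
    a <- as.numeric(r$a)
    b <- if (!is.null(r$b)) as.numeric(unlist(r$b))
         else if (!is.null(r$c)) sort(-as.numeric(unlist(r$c)) / a)
         else stop("item record needs 'b' (locations) or 'c' (intercepts)",
                   call. = FALSE)
    item_parameters(
      item_id = r$item_id, a = a, b = b,
      text = r$text %||% "", subdomain = r$subdomain %||% "general",
      category_labels = if (is.null(r$category_labels))
        default_category_labels() else unlist(r$category_labels))
  })
  item_bank(items, name = raw$name %||% "bank")
}

#' @rdname read_item_bank
#' @export
write_item_bank <- function(bank, path) {
  stopifnot(inherits(bank, "item_bank"))
  obj <- list(
    name = bank$name, metric = bank$metric,
    items = lapply(unname(bank$items), function(it)
      list(item_id = it$item_id, text = it$text, subdomain = it$subdomain,
           a = it$a, b = it$b, category_labels = it$category_labels)))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Read a respondent response matrix from CSV
#'
#' Expected layout: one row per respondent, first column `respondent_id`,
#' remaining columns named by item id with integer categories 1-5; blank
#' cells are missing.
#'
#' @param path CSV file path.
#' @param bank Optional [item_bank()]; when given, column names are checked
#'   against the bank.
#' @return Integer matrix (respondents x items) with respondent ids as row
#'   names; `NA` marks missing responses.
#' @export
read_responses <- function(path, bank = NULL) {
  df <- utils::read.csv(path, check.names = FALSE,
                        colClasses = c(respondent_id = "character"))
  if (!"respondent_id" %in% names(df))
    stop("response CSV must have a 'respondent_id' column", call. = FALSE)
  ids <- df$respondent_id
  m <- as.matrix(df[setdiff(names(df), "respondent_id")])
  storage.mode(m) <- "integer"
  rownames(m) <- ids
  bad <- !is.na(m) & (m < 1L | m > 5L)
  if (any(bad)) stop("response categories must be in 1..5", call. = FALSE)
  if (!is.null(bank)) {
    unknown <- setdiff(colnames(m), bank_item_ids(bank))
    if (length(unknown))
      stop("response columns not in bank: ",
           paste(unknown, collapse = ", "), call. = FALSE)
  }
  m
}

#' @rdname read_responses
#' @param responses Integer matrix as returned by `read_responses`.
#' @export
write_responses <- function(responses, path) {
  df <- data.frame(respondent_id = rownames(responses),
                   responses, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE, na = "")
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
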