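# Score vignettes: named hypothetical response patterns whose items carry the
# most-probable responses at a target T-score, then calibrated by scoring the
# pattern itself (the set of modal responses need not land on the target,
# because each response is modal over a *range* of scores).

surname_pool <- function() {
  c("Thomas", "Rivera", "Chen", "Okafor", "Patel", "Nguyen", "Smith",
    "Garcia", "Kim", "Hansen", "Ali", "Rossi", "Dubois", "Sato",
    "Novak", "Silva", "Haddad", "Kaur", "Berg", "Moreau", "Ivanov",
    "Mensah", "Tanaka", "Lopez", "Weber", "Osei")
}

vignette_names <- function(n) {
  pool <- surname_pool()
  if (n <= length(pool)) return(paste("Ms.", pool[seq_len(n)]))
  extra <- paste0(pool[1L], " ", seq_len(n - length(pool)) + 1L)
  c(paste("Ms.", pool), paste("Ms.", extra))
}

#' Build a score vignette at a target T-score
#'
#' Selects `n_items` items from the bank and fills each with its most likely
#' response at `target_t`.  With `balance_by_subdomain = TRUE` items are
#' drawn round-robin across subdomains; within a subdomain, the item with the
#' highest Fisher information at the target wins (ties broken by
#' lexicographic item id).  The assembled pattern is then calibrated with
#' [calibrate_vignette()].
#'
#' @param bank An [item_bank()].
#' @param target_t Target T-score in \[30, 85\].
#' @param n_items Number of items; must not exceed the bank size.
#' @param balance_by_subdomain Balance item content across subdomains?
#' @param name Display surname label; default `"Ms. Thomas"`.
#' @return An object of class `pi_vignette` with fields `name`, `target_t`,
#'   `items` (data frame: item_id, category, descriptor), `calibrated_t`
#'   (one-decimal T) and `rank` (assigned when the vignette joins a set).
#' @export
build_vignette <- function(bank, target_t, n_items = min(6L, length(bank)),
                           balance_by_subdomain = TRUE, name = "Ms. Thomas") {
  stopifnot(inherits(bank, "item_bank"))
  if (!is.numeric(target_t) || length(target_t) != 1L ||
      target_t < 30 || target_t > 85)
    stop("'target_t' must be a single T-score in [30, 85]", call. = FALSE)
  n_items <- as.integer(n_items)
  if (n_items < 1L) stop("'n_items' must be at least 1", call. = FALSE)
  if (n_items > length(bank))
    stop("'n_items' exceeds the bank size", call. = FALSE)

  theta0 <- t_to_theta(target_t)
  ids <- select_vignette_items(bank, theta0, n_items, balance_by_subdomain)
  cats <- vapply(ids, function(id)
    most_likely_response(theta0, bank$items[[id]]), integer(1L))
  items <- data.frame(
    item_id = ids,
    category = unname(cats),
    descriptor = vapply(seq_along(ids), function(j)
      bank$items[[ids[j]]]$category_labels[cats[j]], character(1L)),
    stringsAsFactors = FALSE, row.names = NULL)
  v <- structure(list(name = name, target_t = target_t, items = items,
                      calibrated_t = NA_real_, rank = NA_integer_),
                 class = "pi_vignette")
  v$calibrated_t <- calibrate_vignette(v, bank)
  v
}

# Round-robin item selection across subdomains, most informative item at the
# target first within each subdomain; lexicographic item id breaks ties.
select_vignette_items <- function(bank, theta0, n_items, balance) {
  ids <- bank_item_ids(bank)
  info <- vapply(ids, function(id)
    item_information(theta0, bank$items[[id]]), numeric(1L))
  doms <- vapply(bank$items, `[[`, character(1L), "subdomain")
  if (balance && length(unique(doms)) < 2L) {
    warning("only one subdomain present; falling back to unbalanced selection",
            call. = FALSE)
    balance <- FALSE
  }
  ord <- ids[order(-info, ids)]
  if (!balance) return(ord[seq_len(n_items)])
  queues <- split(ord, doms[ord])
  queues <- queues[order(names(queues))]
  out <- character(0L)
  while (length(out) < n_items) {
    for (d in names(queues)) {
      if (length(out) >= n_items) break
      if (length(queues[[d]])) {
        out <- c(out, queues[[d]][1L])
        queues[[d]] <- queues[[d]][-1L]
      }
    }
  }
  out
}

#' Calibrate a vignette by pattern scoring
#'
#' EAP score of the vignette's response pattern, rounded to one decimal T for
#' storage.  Threshold arithmetic downstream re-rounds to integer T.
#'
#' @param v A `pi_vignette`.
#' @param bank The [item_bank()] the vignette was built from.
#' @param ... Passed on to [eap_score()].
#' @return Calibrated T-score (one decimal).
#' @export
calibrate_vignette <- function(v, bank, ...) {
  stopifnot(inherits(v, "pi_vignette"))
  if (nrow(v$items) == 0L) stop("vignette has no items", call. = FALSE)
  s <- eap_score(response_pattern(v$items$category, v$items$item_id, bank),
                 bank, ...)
  round(s$t_score, 1L)
}

#' @export
print.pi_vignette <- function(x, ...) {
  cat(sprintf("Vignette %s: target T = %g, calibrated T = %.1f (%d items)\n",
              x$name, x$target_t, x$calibrated_t, nrow(x$items)))
  invisible(x)
}

#' Build an ordered set of score vignettes
#'
#' Equally spaced targets across `[t_min, t_max]` (the default 8 vignettes
#' over \[45, 80\] gives the conventional 5-T = 0.5-SD spacing), each built
#' with [build_vignette()], calibrated, sorted by calibrated score, and
#' labeled with surnames from a fixed pool.  Construction fails if the
#' calibrated scores are not strictly increasing, naming the offending pair.
#'
#' @param bank An [item_bank()].
#' @param t_min,t_max Target range endpoints (T units), `t_min < t_max`.
#' @param n_vignettes Number of vignettes, at least 2; default 8.
#' @param n_items Items per vignette.
#' @param balance_by_subdomain Passed to [build_vignette()].
#' @return An object of class `vignette_set`: list with `vignettes` (ordered
#'   by calibrated score, ranks 1..n), `bank_name` and `spacing` (target
#'   spacing in T units).
#' @export
build_vignette_set <- function(bank, t_min = 45, t_max = 80, n_vignettes = 8L,
                               n_items = min(6L, length(bank)),
                               balance_by_subdomain = TRUE) {
  n_vignettes <- as.integer(n_vignettes)
  if (n_vignettes < 2L) stop("need at least 2 vignettes", call. = FALSE)
  if (!(t_min < t_max)) stop("'t_min' must be below 't_max'", call. = FALSE)
  targets <- seq(t_min, t_max, length.out = n_vignettes)
  nms <- vignette_names(n_vignettes)
  vs <- lapply(seq_along(targets), function(i)
    build_vignette(bank, targets[i], n_items, balance_by_subdomain,
                   name = nms[i]))
  cal <- vapply(vs, `[[`, numeric(1L), "calibrated_t")
  ord <- order(cal)
  vs <- vs[ord]; cal <- cal[ord]
  if (any(diff(cal) <= 0)) {
    i <- which(diff(cal) <= 0)[1L]
    stop(sprintf(
      "calibrated scores not strictly increasing: %s (%.1f) vs %s (%.1f)",
      vs[[i]]$name, cal[i], vs[[i + 1L]]$name, cal[i + 1L]), call. = FALSE)
  }
  for (i in seq_along(vs)) vs[[i]]$rank <- i
  structure(list(vignettes = vs, bank_name = bank$name,
                 spacing = diff(targets)[1L]),
            class = "vignette_set")
}

#' @export
print.vignette_set <- function(x, ...) {
  cat(sprintf("Vignette set (%d vignettes, target spacing %.1f T, bank '%s')\n",
              length(x$vignettes), x$spacing, x$bank_name))
  for (v in x$vignettes)
    cat(sprintf("  %d. %-14s target %5.1f  calibrated %5.1f\n",
                v$rank, v$name, v$target_t, v$calibrated_t))
  invisible(x)
}

#' @export
length.vignette_set <- function(x) length(x$vignettes)

calibrated_scores <- function(vset) {
  vapply(vset$vignettes, `[[`, numeric(1L), "calibrated_t")
}

#' Read / write a vignette set as JSON
#'
#' Round-trips losslessly through the schema
#' `{"bank_name", "spacing", "vignettes": [{"name", "target_t",
#' "calibrated_t", "rank", "items": [{"item_id", "category",
#' "descriptor"}]}]}`.
#'
#' @param vset A [build_vignette_set()] result.
#' @param path File path.
#' @export
write_vignette_set <- function(vset, path) {
  stopifnot(inherits(vset, "vignette_set"))
  obj <- list(
    bank_name = vset$bank_name, spacing = vset$spacing,
    vignettes = lapply(vset$vignettes, function(v)
      list(name = v$name, target_t = v$target_t,
           calibrated_t = v$calibrated_t, rank = v$rank,
           items = lapply(seq_len(nrow(v$items)), function(j)
             as.list(v$items[j, ])))))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_vignette_set
#' @export
read_vignette_set <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = FALSE)
  vs <- lapply(raw$vignettes, function(r) {
    items <- do.call(rbind, lapply(r$items, function(it)
      data.frame(item_id = it$item_id, category = as.integer(it$category),
                 descriptor = it$descriptor, stringsAsFactors = FALSE)))
    structure(list(name = r$name, target_t = as.numeric(r$target_t),
                   items = items,
                   calibrated_t = as.numeric(r$calibrated_t),
                   rank = as.integer(r$rank)),
              class = "pi_vignette")
  })
  vs <- vs[order(vapply(vs, `[[`, integer(1L), "rank"))]
  structure(list(vignettes = vs, bank_name = raw$bank_name %||% "bank",
                 spacing = as.numeric(raw$spacing %||% NA_real_)),
            class = "vignette_set")
}
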