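#' T-score / theta metric conversion
#'
#' The latent trait theta is reported on a T metric via `T = 50 + 10 * theta`.
#'
#' @param t,theta Numeric vectors.
#' @return Numeric vector on the other metric.
#' @export
t_to_theta <- function(t) (t - 50) / 10

#' @rdname t_to_theta
#' @export
theta_to_t <- function(theta) 50 + 10 * theta

#' GRM boundary probability
#'
#' Probability of responding in category `k + 1` or above,
#' `P*_k(theta) = 1 / (1 + exp(-a * (theta - b[k])))`.
#'
#' @param theta Latent trait value(s), theta metric.
#' @param item An [item_parameters()] object.
#' @param k Boundary index in 1..4.
#' @return Probability vector, same length as `theta`, in (0, 1).
#' @export
boundary_prob <- function(theta, item, k) {
  stopifnot(inherits(item, "item_parameters"))
  if (length(k) != 1L || !(k %in% 1:4))
    stop("boundary index 'k' must be in 1..4", call. = FALSE)
  if (!is.numeric(theta) || anyNA(theta) || any(!is.finite(theta)))
    stop("'theta' must be finite numeric", call. = FALSE)
  stats::plogis(item$a * (theta - item$b[k]))
}

# Cumulative boundary probabilities for a vector of thetas: matrix
# length(theta) x 6 with the fixed outer columns P*_0 = 1, P*_5 = 0.
cum_probs <- function(theta, item) {
  z <- outer(theta, item$b, function(th, b) stats::plogis(item$a * (th - b)))
  cbind(1, z, 0)
}

#' GRM category probabilities
#'
#' Adjacent differences of the boundary curves:
#' `P_k = P*_(k-1) - P*_k`, with `P*_0 = 1`, `P*_5 = 0`.
#'
#' @inheritParams boundary_prob
#' @return For scalar `theta` a length-5 probability vector; for vector
#'   `theta` a `length(theta) x 5` matrix.  Rows are non-negative and sum
#'   to 1.
#' @export
category_probs <- function(theta, item) {
  stopifnot(inherits(item, "item_parameters"))
  if (!is.numeric(theta) || anyNA(theta) || any(!is.finite(theta)))
    stop("'theta' must be finite numeric", call. = FALSE)
  cp <- cum_probs(theta, item)
  p <- cp[, 1:5, drop = FALSE] - cp[, 2:6, drop = FALSE]
  colnames(p) <- paste0("cat", 1:5)
  if (length(theta) == 1L) drop(p) else p
}

#' Most likely response at a trait value
#'
#' The modal category of the GRM category curves at `theta`.  Ties are
#' broken toward the lower category (deterministic, conservative toward
#' less impact).
#'
#' @inheritParams boundary_prob
#' @return Integer vector of categories in 1..5, one per `theta`.
#' @export
most_likely_response <- function(theta, item) {
  p <- category_probs(theta, item)
  if (is.null(dim(p))) p <- matrix(p, nrow = 1L)
  as.integer(apply(p, 1L, which.max))  # which.max takes the first (lower) tie
}

#' Most-likely-response map across a score grid
#'
#' For each T-score in `t_grid`, the most likely response to `item`.  This is
#' the map used to assemble score vignettes: a response is the most likely
#' one over a *range* of scores, and the map is nondecreasing because the
#' boundary locations are ordered.
#'
#' @param item An [item_parameters()] object.
#' @param t_grid Finite numeric vector of T-scores, sorted ascending.
#' @return Integer vector of categories, same length as `t_grid`,
#'   nondecreasing.
#' @export
response_map <- function(item, t_grid) {
  if (!is.numeric(t_grid) || length(t_grid) < 1L || anyNA(t_grid) ||
      any(!is.finite(t_grid)))
    stop("'t_grid' must be finite numeric", call. = FALSE)
  if (is.unsorted(t_grid, strictly = FALSE))
    stop("'t_grid' must be sorted ascending", call. = FALSE)
  most_likely_response(t_to_theta(t_grid), item)
}

#' GRM item information
#'
#' Fisher information of a single item at `theta`:
#' `I(theta) = sum_k (dP_k/dtheta)^2 / P_k` with
#' `dP_k/dtheta = a * (P*_(k-1)(1 - P*_(k-1)) - P*_k(1 - P*_k))`.
#' Used to pick the most informative item per subdomain when balancing
#' vignette content.
#'
#' @inheritParams boundary_prob
#' @return Information value(s), non-negative.
#' @export
item_information <- function(theta, item) {
  stopifnot(inherits(item, "item_parameters"))
  cp <- cum_probs(theta, item)
  d <- item$a * (cp * (1 - cp))
  dp <- d[, 1:5, drop = FALSE] - d[, 2:6, drop = FALSE]
  p <- cp[, 1:5, drop = FALSE] - cp[, 2:6, drop = FALSE]
  drop(rowSums(dp^2 / pmax(p, .Machine$double.eps)))
}

#' Construct a response pattern
#'
#' A carrier for one respondent's answers: a named integer vector mapping
#' item ids to categories 1..5.  `NA` marks a missing response; missing
#' items are dropped from the scoring likelihood.
#'
#' @param categories Integer vector of categories (1..5 or `NA`).
#' @param item_ids Character vector of item ids, same length.
#' @param bank Optional [item_bank()] to validate ids against.
#' @return Named integer vector of class `response_pattern`.
#' @export
response_pattern <- function(categories, item_ids = names(categories),
                             bank = NULL) {
  if (is.null(item_ids) || length(item_ids) != length(categories))
    stop("'categories' must be named by item id (or supply 'item_ids')",
         call. = FALSE)
  x <- as.integer(categories)
  bad <- !is.na(x) & (x < 1L | x > 5L)
  if (any(bad)) stop("categories must be in 1..5 (or NA)", call. = FALSE)
  if (!is.null(bank)) {
    unknown <- setdiff(item_ids, bank_item_ids(bank))
    if (length(unknown))
      stop("pattern references items not in the bank: ",
           paste(unknown, collapse = ", "), call. = FALSE)
  }
  names(x) <- item_ids
  class(x) <- "response_pattern"
  x
}

# Quadrature nodes/weights for EAP: equally spaced nodes, rectangle weights
# times the prior normal density, renormalized.
eap_quadrature <- function(n_nodes = 81L, theta_range = c(-4, 4),
                           prior_mean = 0, prior_sd = 1) {
  nodes <- seq(theta_range[1L], theta_range[2L], length.out = n_nodes)
  w <- stats::dnorm(nodes, prior_mean, prior_sd)
  list(nodes = nodes, weights = w / sum(w))
}

#' EAP score for a response pattern
#'
#' Expected-a-posteriori estimate of theta under a normal prior and the GRM
#' likelihood of the answered items, evaluated on a fixed quadrature grid
#' (81 equally spaced nodes on theta in \[-4, 4\] by default, rectangle
#' weights times the prior density, renormalized).  Missing responses are
#' dropped from the likelihood.  This is how score vignettes are
#' calibrated: the vignette's pattern is scored as though it were an
#' individual's responses to a custom short form.
#'
#' @param pattern A [response_pattern()] or named integer vector of
#'   categories.
#' @param bank An [item_bank()] containing every referenced item.
#' @param n_nodes,theta_range Quadrature grid; defaults 81 nodes on
#'   \[-4, 4\].
#' @param prior_mean,prior_sd Prior on theta, default standard normal
#'   (i.e. T ~ N(50, 10)); configurable for sensitivity runs.
#' @return Object of class `scored_value` with fields `theta_hat`,
#'   `t_score` (= 50 + 10 * theta_hat), `se_theta` (posterior SD) and
#'   `n_items`.
#' @examples
#' bk <- item_bank(list(item_parameters("i1", a = 2, b = c(-2, -1, 1, 2))))
#' eap_score(c(i1 = 3), bk)$t_score  # symmetric item, middle category -> 50
#' @export
eap_score <- function(pattern, bank, n_nodes = 81L, theta_range = c(-4, 4),
                      prior_mean = 0, prior_sd = 1) {
  stopifnot(inherits(bank, "item_bank"))
  if (!inherits(pattern, "response_pattern"))
    pattern <- response_pattern(pattern, bank = bank)
  pattern <- pattern[!is.na(pattern)]
  if (length(pattern) == 0L)
    stop("pattern has no non-missing responses to score", call. = FALSE)
  unknown <- setdiff(names(pattern), bank_item_ids(bank))
  if (length(unknown))
    stop("pattern references items not in the bank: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  q <- eap_quadrature(n_nodes, theta_range, prior_mean, prior_sd)
  loglik <- numeric(length(q$nodes))
  for (j in seq_along(pattern)) {
    it <- bank$items[[names(pattern)[j]]]
    cp <- cum_probs(q$nodes, it)
    k <- unclass(pattern)[j]
    loglik <- loglik + log(pmax(cp[, k] - cp[, k + 1L],
                                .Machine$double.xmin))
  }
  post <- q$weights * exp(loglik - max(loglik))
  post <- post / sum(post)
  theta_hat <- sum(post * q$nodes)
  se_theta <- sqrt(max(sum(post * (q$nodes - theta_hat)^2), 0))
  structure(list(theta_hat = theta_hat,
                 t_score = theta_to_t(theta_hat),
                 se_theta = se_theta,
                 n_items = length(pattern)),
            class = "scored_value")
}

#' @export
print.scored_value <- function(x, ...) {
  cat(sprintf("EAP score: T = %.2f (theta = %.3f, SE = %.3f, %d items)\n",
              x$t_score, x$theta_hat, x$se_theta, x$n_items))
  invisible(x)
}

#' EAP scores for a response matrix
#'
#' @param responses Integer matrix (respondents x items) as from
#'   [read_responses()].
#' @param bank An [item_bank()].
#' @param ... Passed on to [eap_score()].
#' @return Data frame with `respondent_id`, `theta_hat`, `t_score`,
#'   `se_theta`, `n_items`.
#' @export
score_responses <- function(responses, bank, ...) {
  stopifnot(is.matrix(responses))
  out <- lapply(seq_len(nrow(responses)), function(i) {
    s <- eap_score(responses[i, ], bank, ...)
    data.frame(respondent_id = rownames(responses)[i] %||% as.character(i),
               theta_hat = s$theta_hat, t_score = s$t_score,
               se_theta = s$se_theta, n_items = s$n_items)
  })
  do.call(rbind, out)
}

#' Achievable score range of an item subset
#'
#' EAP T-scores of the all-lowest and all-highest response patterns on a
#' subset of the bank: the floor and ceiling of the short form built from
#' those items.
#'
#' @param bank An [item_bank()].
#' @param item_subset Character vector of item ids; default the whole bank.
#' @param ... Passed on to [eap_score()].
#' @return Named numeric vector `c(min, max)` in T units.
#' @export
score_range <- function(bank, item_subset = bank_item_ids(bank), ...) {
  if (length(item_subset) == 0L)
    stop("'item_subset' must be non-empty", call. = FALSE)
  lo <- eap_score(response_pattern(rep(1L, length(item_subset)),
                                   item_subset, bank), bank, ...)
  hi <- eap_score(response_pattern(rep(5L, length(item_subset)),
                                   item_subset, bank), bank, ...)
  c(min = lo$t_score, max = hi$t_score)
}
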