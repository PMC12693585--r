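# Positional hotspot detection along an alignment: the G function, its
# maximal climb (delta G), and a Monte Carlo null of n sites sampled
# without replacement from the alignment columns.

#' G function of event positions along an alignment
#'
#' For `n` sorted event positions `x_1 < ... < x_n` in an alignment of `L`
#' columns, `G_k = k/n - x_k/L`: the difference between the relative
#' occurrence of a change and its relative position. Runs of events closer
#' together than expected under uniformity produce climbs of G; the
#' consecutive differences are returned as `delta_g`.
#'
#' Positions are 1-based alignment columns (events at one column must be
#' merged before calling).
#'
#' @param positions Strictly increasing 1-based alignment columns of the
#'   (collapsed) events; `n >= 2`.
#' @param L Alignment width in columns.
#' @return Object of class `g_series`: list with `L`, `n`, `positions`,
#'   `g` and `delta_g` (length `n - 1`).
#' @export
g_function <- function(positions, L) {
  positions <- as.integer(positions)
  L <- as.integer(L)
  n <- length(positions)
  if (n < 2L) stop("need at least 2 events")
  if (is.unsorted(positions, strictly = TRUE))
    stop("positions must be strictly increasing; merge events at one site first")
  if (positions[1L] < 1L || positions[n] > L)
    stop("positions must lie in [1, L]")
  g <- seq_len(n) / n - positions / L
  structure(list(L = L, n = n, positions = positions,
                 g = g, delta_g = diff(g)),
            class = "g_series")
}

#' Maximal climb of the G function
#'
#' The event run `(i, j)`, `i < j`, maximising `G_j - G_i` — the tightest
#' stretch of events relative to a uniform accumulation. Ties are broken by
#' smaller `i`, then smaller `j`.
#'
#' @param gs A `g_series` ([g_function()]).
#' @return List with `start_event`, `end_event` (1-based event indices) and
#'   `delta` (`G_j - G_i`).
#' @export
max_stretch <- function(gs) {
  stopifnot(inherits(gs, "g_series"))
  g <- gs$g
  n <- gs$n
  best <- -Inf; bi <- 1L; bj <- 2L
  min_i <- 1L
  for (j in 2L:n) {
    d <- g[j] - g[min_i]
    if (d > best) { best <- d; bi <- min_i; bj <- j }
    if (g[j] < g[min_i]) min_i <- j
  }
  list(start_event = bi, end_event = bj, delta = best)
}

#' Monte Carlo null distribution of the maximal G climb
#'
#' Draws `n` distinct positions uniformly from the `L` alignment columns
#' (sampling sites without replacement), computes the maximal G climb of
#' each resample, and returns the empirical null distribution.
#'
#' @param n Number of events.
#' @param L Alignment width.
#' @param n_resamples Number of Monte Carlo resamples (default 100000).
#' @param seed Optional integer seed for reproducibility.
#' @return Numeric vector of `n_resamples` maximal climbs.
#' @export
monte_carlo_null <- function(n, L, n_resamples = 100000L, seed = NULL) {
  if (n < 2L || n > L) stop("need 2 <= n <= L")
  if (!is.null(seed)) set.seed(seed)
  out <- .null_max_climb(as.integer(n), as.integer(L),
                         as.integer(n_resamples))
  attr(out, "n") <- as.integer(n)
  attr(out, "L") <- as.integer(L)
  out
}

#' Call positional hotspots against a Monte Carlo null
#'
#' Tests the maximal G climb of the observed events against the null with
#' the empirical estimator `p = (1 + #\{null >= observed\}) / (1 + B)`
#' (never exactly 0). A significant stretch is reported, its events are
#' masked, and the procedure recurses on the remaining events against a
#' null re-simulated at the reduced event count, until no significant
#' stretch remains or fewer than 2 events are left.
#'
#' @param gs A `g_series` of the observed (collapsed) events.
#' @param null_dist Null distribution from [monte_carlo_null()] at the same
#'   `(n, L)`; when `NULL` it is simulated here.
#' @param alpha Significance level on the empirical p-value (default 0.05).
#' @param n_resamples Resamples for the initial and re-simulated nulls.
#' @param seed Optional seed (set once, before any simulation).
#' @return data.frame of hotspot calls sorted by span start, with columns
#'   `start_event`, `end_event` (indices into the *original* event vector),
#'   `span_start`, `span_end` (alignment columns), `delta`, `p_empirical`
#'   and `n_resamples`. Zero rows when nothing is significant.
#' @export
call_hotspots <- function(gs, null_dist = NULL, alpha = 0.05,
                          n_resamples = if (!is.null(null_dist))
                            length(null_dist) else 100000L,
                          seed = NULL) {
  stopifnot(inherits(gs, "g_series"))
  if (!is.null(seed)) set.seed(seed)
  if (is.null(null_dist))
    null_dist <- .null_max_climb(gs$n, gs$L, as.integer(n_resamples))
  nd <- attr(null_dist, "n"); ld <- attr(null_dist, "L")
  if ((!is.null(nd) && nd != gs$n) || (!is.null(ld) && ld != gs$L))
    stop("null distribution simulated at a different (n, L)")
  empty <- data.frame(start_event = integer(0), end_event = integer(0),
                      span_start = integer(0), span_end = integer(0),
                      delta = numeric(0), p_empirical = numeric(0),
                      n_resamples = integer(0))
  if (alpha <= 0) return(empty)
  active <- seq_len(gs$n)   # indices into the original event vector
  positions <- gs$positions
  calls <- empty
  repeat {
    if (length(active) < 2L) break
    cur <- g_function(positions[active], gs$L)
    ms <- max_stretch(cur)
    B <- length(null_dist)
    p <- (1 + sum(null_dist >= ms$delta)) / (1 + B)
    if (p > alpha) break
    idx <- active[ms$start_event:ms$end_event]
    calls <- rbind(calls, data.frame(
      start_event = idx[1L], end_event = idx[length(idx)],
      span_start = positions[idx[1L]], span_end = positions[idx[length(idx)]],
      delta = ms$delta, p_empirical = p, n_resamples = B))
    active <- setdiff(active, idx)
    if (length(active) < 2L) break
    null_dist <- .null_max_climb(length(active), gs$L,
                                 as.integer(n_resamples))
  }
  calls <- calls[order(calls$span_start), , drop = FALSE]
  rownames(calls) <- NULL
  calls
}
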