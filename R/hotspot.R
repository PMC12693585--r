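# Sliding event scores and promoter hotspot scores.

# centered window sum with truncation at the ends
.window_sum <- function(x, window) {
  window <- as.integer(window)
  if (window < 1L || window %% 2L == 0L) stop("window must be odd positive")
  h <- (window - 1L) %/% 2L
  n <- length(x)
  cs <- c(0, cumsum(x))
  lo <- pmax(seq_len(n) - h, 1L)
  hi <- pmin(seq_len(n) + h, n)
  cs[hi + 1L] - cs[lo]
}

#' Sliding event score (Se)
#'
#' Sum of change events in a five-base window centered on each reference
#' offset, truncated at the window ends. Accepts a single species-pair
#' event vector or a multi-pair tally.
#'
#' @param events An `event_vector` ([pairwise_events()]) or `event_tally`
#'   ([tally_events()]).
#' @param window Odd window width in bases (default 5).
#' @return Object of class `se_profile`: list with `offsets`, `se`, `window`
#'   and `n_pairs` (1 for a single pair).
#' @export
sliding_event_score <- function(events, window = 5L) {
  if (inherits(events, "event_vector")) {
    x <- events$bits; n_pairs <- 1L
  } else if (inherits(events, "event_tally")) {
    x <- events$counts; n_pairs <- events$n_pairs
  } else if (is.numeric(events)) {
    x <- events; n_pairs <- NA_integer_
  } else stop("events must be an event_vector, event_tally or numeric vector")
  off <- if (is.numeric(events)) seq_along(x) - 1L else events$offsets
  structure(list(offsets = off, se = .window_sum(x, window),
                 window = as.integer(window), n_pairs = n_pairs),
            class = "se_profile")
}

.region_idx <- function(offsets, region) {
  if (length(region) != 2L || region[1L] > region[2L])
    stop("region must be c(lo, hi) with lo <= hi")
  idx <- which(offsets >= region[1L] & offsets <= region[2L])
  if (!length(idx)) stop("region outside the profile offsets")
  if (min(offsets) > region[1L] || max(offsets) < region[2L])
    stop("profile does not cover the full region")
  idx
}

#' Control-group baseline Se score (Se^C)
#'
#' Global mean of all Se values of all control profiles restricted to the
#' scored region — a single scalar baseline, not a per-offset profile.
#'
#' @param control_profiles List of `se_profile` objects from the control
#'   gene group.
#' @param region Inclusive offset interval `c(lo, hi)` (default the 350-nt
#'   promoter region, see [d_score()]).
#' @return The scalar baseline Se^C.
#' @export
control_baseline <- function(control_profiles, region = c(-380L, -31L)) {
  if (!length(control_profiles)) stop("no control profiles supplied")
  vals <- unlist(lapply(control_profiles, function(p) {
    p$se[.region_idx(p$offsets, region)]
  }))
  mean(vals)
}

#' Promoter hotspot score (d)
#'
#' Percentage of change events in the 350-nt promoter region whose sliding
#' event score strictly exceeds the control baseline Se^C:
#' `d = 100 * n_exceeding / N`, with `N` the total events in the region.
#' The default region is offsets `[-380, -31]` — the 350 nucleotides
#' upstream of a TATA box estimated at offset -30.
#'
#' With `d_mode = "events"` (default) the numerator counts events, so d is
#' guaranteed to lie in `[0, 100]`; `d_mode = "positions"` counts all
#' region positions with Se above baseline over the same denominator.
#'
#' @param profile An `se_profile` ([sliding_event_score()]).
#' @param events The `event_vector`/`event_tally` the profile was built
#'   from (event counts per offset).
#' @param se_baseline Scalar baseline Se^C ([control_baseline()]).
#' @param region Inclusive offset interval scored (350 nt by default).
#' @param d_mode `"events"` or `"positions"` (see Details).
#' @param unit Optional gene/group label.
#' @return Object of class `d_score`: list with `unit`, `region`,
#'   `se_baseline`, `n_events`, `n_exceeding`, `d` (percent) and `status`
#'   (`"ok"` or `"no_events"`; d is reported as 0 but flagged when the
#'   region holds no events).
#' @export
d_score <- function(profile, events, se_baseline, region = c(-380L, -31L),
                    d_mode = c("events", "positions"), unit = NULL) {
  d_mode <- match.arg(d_mode)
  stopifnot(inherits(profile, "se_profile"))
  counts <- if (inherits(events, "event_vector")) events$bits
            else if (inherits(events, "event_tally")) events$counts
            else as.numeric(events)
  if (length(counts) != length(profile$offsets))
    stop("events and profile cover different offsets")
  idx <- .region_idx(profile$offsets, region)
  w <- counts[idx]
  se <- profile$se[idx]
  n_events <- sum(w)
  exceeds <- se > se_baseline
  n_exceeding <- if (d_mode == "events") sum(w[exceeds]) else sum(exceeds)
  if (n_events == 0) {
    d <- 0; status <- "no_events"; n_exceeding <- 0L
  } else {
    d <- 100 * n_exceeding / n_events; status <- "ok"
  }
  structure(list(unit = unit, region = region, se_baseline = se_baseline,
                 n_events = as.integer(n_events),
                 n_exceeding = as.integer(n_exceeding),
                 d = d, status = status, d_mode = d_mode),
            class = "d_score")
}

#' @export
print.d_score <- function(x, ...) {
  cat(sprintf("d = %.2f%% (%d of %d events above Se^C = %.4g%s)\n",
              x$d, x$n_exceeding, x$n_events, x$se_baseline,
              if (x$status == "no_events") "; no events in region" else ""))
  invisible(x)
}

#' PhyloP-based promoter hotspot score (d^P)
#'
#' Percentage of positions in the 350-nt promoter region whose per-base
#' conservation score falls strictly below the control-group baseline p^C.
#' Missing values are excluded from both numerator and denominator with a
#' warning.
#'
#' @param values Named numeric vector of per-base conservation scores
#'   indexed by signed TSS offsets (see [track_offsets()]).
#' @param p_baseline Scalar control baseline p^C (mean control conservation
#'   over the same region).
#' @param region Inclusive offset interval scored.
#' @param unit Optional gene/group label.
#' @return Object of class `phylop_d_score`: list with `unit`, `region`,
#'   `p_baseline`, `n_positions`, `n_below` and `d_p` (percent).
#' @export
phylop_d_score <- function(values, p_baseline, region = c(-380L, -31L),
                           unit = NULL) {
  offs <- as.integer(names(values))
  if (!length(offs) || anyNA(offs))
    stop("values must be named by signed TSS offsets")
  idx <- .region_idx(offs, region)
  v <- values[idx]
  if (anyNA(v)) {
    warning(sprintf("%d missing conservation values excluded", sum(is.na(v))))
    v <- v[!is.na(v)]
  }
  if (!length(v)) stop("no usable conservation values in region")
  n_below <- sum(v < p_baseline)
  structure(list(unit = unit, region = region, p_baseline = p_baseline,
                 n_positions = length(v), n_below = as.integer(n_below),
                 d_p = 100 * n_below / length(v)),
            class = "phylop_d_score")
}

#' Metagene profile across TSS-aligned tracks
#'
#' Arithmetic per-offset mean of per-base signals across genes aligned at
#' their TSSs; missing values are skipped per offset.
#'
#' @param tracks List of equal-length numeric vectors (offset-aligned, as
#'   from [track_offsets()]).
#' @return Named numeric vector of per-offset means.
#' @export
metagene_profile <- function(tracks) {
  if (!length(tracks)) stop("no tracks supplied")
  n <- unique(lengths(tracks))
  if (length(n) != 1L) stop("tracks must share the same offset span")
  m <- do.call(rbind, lapply(tracks, as.numeric))
  out <- colMeans(m, na.rm = TRUE)
  names(out) <- names(tracks[[1L]])
  out
}

#' Unpaired two-sided Student t-test between groups
#'
#' @param group_a,group_b Numeric vectors (n >= 2 each; pooled variance
#'   must be nonzero).
#' @return List with `t` and `p`.
#' @export
compare_means_ttest <- function(group_a, group_b) {
  if (length(group_a) < 2L || length(group_b) < 2L)
    stop("each group needs n >= 2")
  if (sd(c(group_a - mean(group_a), group_b - mean(group_b))) == 0)
    stop("degenerate pooled variance")
  tt <- t.test(group_a, group_b, var.equal = TRUE)
  list(t = unname(tt$statistic), p = tt$p.value)
}

#' 2x2 chi-squared comparison of hotspot-score fractions
#'
#' Pearson chi-squared without continuity correction on the 2x2 table of
#' `[exceeding, not exceeding] x [group, control]` event counts, with
#' Bonferroni correction across a stated family of comparisons.
#'
#' @param n_exceeding_a,n_events_a Exceeding and total event counts in the
#'   test group.
#' @param n_exceeding_b,n_events_b Same for the control group.
#' @param n_comparisons Family size for Bonferroni (default 1).
#' @return List with `chi2`, `p_raw` and `p_bonferroni`.
#' @export
compare_groups_chi2 <- function(n_exceeding_a, n_events_a,
                                n_exceeding_b, n_events_b,
                                n_comparisons = 1L) {
  counts <- c(n_exceeding_a, n_events_a, n_exceeding_b, n_events_b)
  if (any(counts < 0) || n_events_a <= 0 || n_events_b <= 0)
    stop("counts must be non-negative with positive totals")
  if (n_exceeding_a > n_events_a || n_exceeding_b > n_events_b)
    stop("exceeding counts cannot surpass totals")
  tab <- matrix(c(n_exceeding_a, n_events_a - n_exceeding_a,
                  n_exceeding_b, n_events_b - n_exceeding_b),
                nrow = 2L, byrow = TRUE)
  if (any(colSums(tab) == 0) || any(rowSums(tab) == 0))
    stop("zero marginal in the 2x2 table")
  ct <- suppressWarnings(chisq.test(tab, correct = FALSE))
  list(chi2 = unname(ct$statistic), p_raw = ct$p.value,
       p_bonferroni = min(1, ct$p.value * n_comparisons))
}
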