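# Shared fixture builders (everything generated in code; no binary files).

# Two-row toy alignment with an explicit TSS column.
toy_aln <- function(ref, other, tss_column, ref_name = "mel",
                    other_name = "sim", gene = "toy") {
  promoter_alignment(setNames(c(ref, other), c(ref_name, other_name)),
                     ref_species = ref_name, tss_column = tss_column,
                     gene = gene)
}

# Write lines to a temp file and return its path.
tmpfile <- function(lines, ext = ".txt") {
  path <- tempfile(fileext = ext)
  writeLines(lines, path)
  path
}

# Brute-force G function: the direct per-event formula.
g_oracle <- function(positions, L) {
  n <- length(positions)
  vapply(seq_len(n), function(k) k / n - positions[k] / L, numeric(1))
}

# Exhaustive maximal-climb search with the documented tie-break
# (smaller i, then smaller j).
max_stretch_oracle <- function(g) {
  best <- -Inf; bi <- NA; bj <- NA
  for (i in seq_len(length(g) - 1L)) {
    for (j in (i + 1L):length(g)) {
      if (g[j] - g[i] > best) { best <- g[j] - g[i]; bi <- i; bj <- j }
    }
  }
  list(start_event = bi, end_event = bj, delta = best)
}

# Brute-force centered window sum.
window_sum_oracle <- function(x, window = 5L) {
  h <- (window - 1L) %/% 2L
  vapply(seq_along(x), function(i) {
    sum(x[max(1L, i - h):min(length(x), i + h)])
  }, numeric(1))
}

# Brute-force d: enumerate events, compare their window sums to a baseline.
d_oracle <- function(bits, baseline, window = 5L) {
  se <- window_sum_oracle(bits, window)
  ev <- which(bits >= 1)
  if (!length(ev)) return(0)
  100 * sum(bits[ev][se[ev] > baseline]) / sum(bits[ev])
}

# Expand a generator truth table (one species) to per-offset 0/1 vectors.
truth_to_bits <- function(truth, upstream = 1000L, downstream = 300L) {
  W <- upstream + downstream
  base <- integer(W); indel <- integer(W)
  at <- function(off) off + upstream + 1L
  for (r in seq_len(nrow(truth))) {
    i <- at(truth$offset[r])
    switch(truth$kind[r],
           substitution = { base[i] <- 1L },
           deletion = { indel[i:min(W, i + truth$length[r] - 1L)] <- 1L },
           insertion = { indel[i] <- 1L })
  }
  list(base = base, indel = indel, all = as.integer(base | indel))
}
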