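# Expression divergence between species and between hybrid alleles, and its
# relation to promoter hotspot scores.

#' Transcripts per million (TPM)
#'
#' Length-normalised expression: `rate_g = count_g / length_g(kb)`,
#' `TPM_g = 1e6 * rate_g / sum(rates)` per sample, so every column sums to
#' one million. Plain length-in-kb normalisation is used (no effective
#' lengths).
#'
#' @param counts Non-negative integer gene x sample matrix with gene
#'   rownames.
#' @param lengths Positive gene lengths in nucleotides, one per row of
#'   `counts`.
#' @return Gene x sample TPM matrix.
#' @export
tpm <- function(counts, lengths) {
  counts <- as.matrix(counts)
  if (length(lengths) != nrow(counts))
    stop("need one gene length per row")
  if (any(lengths <= 0)) stop("gene lengths must be positive")
  if (any(counts < 0)) stop("counts must be non-negative")
  if (any(colSums(counts) == 0)) stop("all-zero sample column")
  rate <- counts / (lengths / 1000)
  sweep(rate, 2L, colSums(rate), `/`) * 1e6
}

#' log2 fold change of mean expression between two sample groups
#'
#' `log2((mean_a + pseudocount) / (mean_b + pseudocount))`. The default
#' pseudocount of 1 TPM stabilises low-expression genes.
#'
#' @param tpm_a,tpm_b Non-negative per-sample expression values (>= 1 sample
#'   per side). Matrices are averaged row-wise, giving one value per gene.
#' @param pseudocount Added to both means (default 1).
#' @return log2 fold change (a over b); vector when matrices are supplied.
#' @export
log2fc <- function(tpm_a, tpm_b, pseudocount = 1) {
  if (any(tpm_a < 0, na.rm = TRUE) || any(tpm_b < 0, na.rm = TRUE))
    stop("expression values must be non-negative")
  ma <- if (is.matrix(tpm_a)) rowMeans(tpm_a) else mean(tpm_a)
  mb <- if (is.matrix(tpm_b)) rowMeans(tpm_b) else mean(tpm_b)
  log2((ma + pseudocount) / (mb + pseudocount))
}

#' Significance call for differential expression records
#'
#' A gene is called significant when `|log2fc| >= lfc_min` and
#' `adj_p <= p_max` (both boundaries inclusive). Genes with a missing
#' adjusted p-value are never significant and are flagged in the
#' `"n_missing_p"` attribute.
#'
#' @param log2fc Per-gene log2 fold changes.
#' @param adj_p Per-gene adjusted p-values (may contain `NA`).
#' @param lfc_min Minimum absolute log2 fold change (default 0.5).
#' @param p_max Maximum adjusted p-value (default 0.05).
#' @return Logical vector; attribute `n_missing_p` counts records with a
#'   missing adjusted p-value.
#' @export
classify_de <- function(log2fc, adj_p, lfc_min = 0.5, p_max = 0.05) {
  if (length(adj_p) != length(log2fc))
    stop("log2fc and adj_p lengths differ")
  miss <- is.na(adj_p)
  sig <- !miss & abs(log2fc) >= lfc_min & adj_p <= p_max
  attr(sig, "n_missing_p") <- sum(miss)
  sig
}

#' Filter a hybrid allele expression table
#'
#' Removes genes on excluded chromosomes (mono-allelic inheritance, e.g.
#' the X inherited from only one parent species) and genes expressed in
#' fewer than `min_samples` of the pooled allele x replicate columns.
#'
#' @param table data.frame with columns `gene`, `chrom`, `allele` and one
#'   count column per sample; exactly two allele labels per gene.
#' @param min_samples Minimum number of pooled columns (across both allele
#'   rows) with nonzero counts (default 4).
#' @param exclude_chrom Chromosome labels to drop (default `"X"`).
#' @return The filtered table (same shape).
#' @export
hybrid_allele_filter <- function(table, min_samples = 4L,
                                 exclude_chrom = "X") {
  need <- c("gene", "chrom", "allele")
  if (!all(need %in% names(table)))
    stop("table needs columns gene, chrom, allele plus count columns")
  cnt_cols <- setdiff(names(table), need)
  if (!length(cnt_cols)) stop("no count columns found")
  table <- table[!table$chrom %in% exclude_chrom, , drop = FALSE]
  nonzero <- vapply(split(table[cnt_cols], table$gene),
                    function(d) sum(as.matrix(d) > 0), integer(1))
  keep <- names(nonzero)[nonzero >= min_samples]
  out <- table[table$gene %in% keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Fraction of significantly diverging genes per group
#'
#' Per-group percentage of significant genes plus a 2x2 chi-squared test of
#' every non-control group against the control group, Benjamini-Hochberg
#' corrected across the family.
#'
#' @param groups Named list of gene identifier vectors.
#' @param de data.frame with columns `gene` and `significant` (logical), or
#'   `gene`, `log2fc`, `adj_p` to be classified with [classify_de()]
#'   defaults.
#' @param control Name of the control group (default the last group).
#' @return data.frame with columns `group`, `n`, `n_significant`,
#'   `pct_significant`, `chi2`, `p_raw`, `p_adj` (NA for the control row).
#' @export
divergence_fraction <- function(groups, de, control = names(groups)[length(groups)]) {
  if (!length(groups) || is.null(names(groups)))
    stop("groups must be a named list")
  if (any(!lengths(groups))) stop("empty group")
  if (!control %in% names(groups)) stop("unknown control group")
  if (!"significant" %in% names(de))
    de$significant <- classify_de(de$log2fc, de$adj_p)
  stat <- lapply(groups, function(g) {
    sig <- de$significant[match(g, de$gene)]
    if (anyNA(sig)) stop("group gene missing from the DE table")
    c(n = length(sig), k = sum(sig))
  })
  out <- data.frame(group = names(groups),
                    n = vapply(stat, `[[`, 0, "n"),
                    n_significant = vapply(stat, `[[`, 0, "k"))
  out$pct_significant <- 100 * out$n_significant / out$n
  out$chi2 <- out$p_raw <- NA_real_
  ctrl <- stat[[control]]
  for (i in seq_len(nrow(out))) {
    if (out$group[i] == control) next
    ct <- tryCatch(compare_groups_chi2(stat[[i]]["k"], stat[[i]]["n"],
                                       ctrl["k"], ctrl["n"]),
                   error = function(e) NULL)  # degenerate 2x2 -> NA
    if (is.null(ct)) next
    out$chi2[i] <- ct$chi2
    out$p_raw[i] <- ct$p_raw
  }
  out$p_adj <- NA_real_
  tested <- !is.na(out$p_raw)
  out$p_adj[tested] <- p.adjust(out$p_raw[tested], method = "BH")
  rownames(out) <- NULL
  out
}

#' Expression-change enrichment across promoter-score tertiles
#'
#' Bins genes by promoter hotspot score d into `(0,33]`, `(33,66]`,
#' `(66,100]` (d = 0 falls in the first bin) and reports, per bin, the
#' percentage of genes with `log2fc > lfc_abs` or `< -lfc_abs` (strict
#' inequalities). When a control group is supplied, each bin is compared
#' against the matching control bin by 2x2 chi-squared.
#'
#' @param d_scores Named numeric vector of per-gene d scores in `[0, 100]`.
#' @param de data.frame with columns `gene` and `log2fc`, covering every
#'   gene in `d_scores`.
#' @param lfc_abs Strict absolute log2 fold-change threshold (default 1).
#' @param control_d,control_de Optional control-group d scores and DE table.
#' @param breaks Bin boundaries (default `c(0, 33, 66, 100)`).
#' @return data.frame with per-bin `n`, `n_changed`, `pct_changed` and,
#'   with a control, the control columns plus `chi2` and `p_raw`.
#' @export
tertile_enrichment <- function(d_scores, de, lfc_abs = 1,
                               control_d = NULL, control_de = NULL,
                               breaks = c(0, 33, 66, 100)) {
  bin_stats <- function(d, tab) {
    if (any(d < 0 | d > 100)) stop("d scores must lie in [0, 100]")
    lfc <- tab$log2fc[match(names(d), tab$gene)]
    if (anyNA(lfc)) stop("gene missing from the DE table")
    bin <- cut(d, breaks = breaks, include.lowest = TRUE)
    changed <- abs(lfc) > lfc_abs
    data.frame(bin = levels(bin),
               n = as.integer(table(bin)),
               n_changed = as.integer(tapply(changed, bin, sum,
                                             default = 0L)))
  }
  out <- bin_stats(d_scores, de)
  out$pct_changed <- ifelse(out$n > 0, 100 * out$n_changed / out$n, NA_real_)
  if (!is.null(control_d)) {
    ctrl <- bin_stats(control_d, control_de)
    out$ctrl_n <- ctrl$n
    out$ctrl_n_changed <- ctrl$n_changed
    out$ctrl_pct_changed <- ifelse(ctrl$n > 0,
                                   100 * ctrl$n_changed / ctrl$n, NA_real_)
    out$chi2 <- out$p_raw <- NA_real_
    for (i in seq_len(nrow(out))) {
      ok <- out$n[i] > 0 && ctrl$n[i] > 0 &&
        (out$n_changed[i] + ctrl$n_changed[i]) > 0 &&
        (out$n_changed[i] < out$n[i] || ctrl$n_changed[i] < ctrl$n[i])
      if (!ok) next
      ct <- compare_groups_chi2(out$n_changed[i], out$n[i],
                                ctrl$n_changed[i], ctrl$n[i])
      out$chi2[i] <- ct$chi2
      out$p_raw[i] <- ct$p_raw
    }
  }
  out
}

#' Mann-Whitney U test for a shift between log2 fold-change distributions
#'
#' Two-sided; exact for small samples (n <= 8 per side, no ties), normal
#' approximation with tie correction otherwise.
#'
#' @param log2fc_a,log2fc_b Numeric vectors (n >= 1 each).
#' @return List with `U` (statistic of the first sample) and `p`.
#' @export
distribution_shift_test <- function(log2fc_a, log2fc_b) {
  if (!length(log2fc_a) || !length(log2fc_b)) stop("empty sample")
  ties <- anyDuplicated(c(log2fc_a, log2fc_b)) > 0
  exact <- length(log2fc_a) <= 8L && length(log2fc_b) <= 8L && !ties
  wt <- suppressWarnings(wilcox.test(log2fc_a, log2fc_b, exact = exact))
  list(U = unname(wt$statistic), p = wt$p.value)
}

#' Allele log2 fold change from gel band densitometry
#'
#' Band intensities are normalised to fragment length (digested fragments
#' are shorter, so intensity per stained base is what is comparable); the
#' per-allele signal is the sum of `intensity / fragment_length` over that
#' allele's bands, and the result is `log2(signal_ref / signal_other)`.
#'
#' @param bands data.frame with columns `allele`, `intensity` (>= 0) and
#'   `fragment_length` (> 0, nucleotides), exactly two allele labels.
#' @param ref_allele Allele placed in the numerator.
#' @return Allele log2 fold change (ref over other).
#' @export
densitometry_log2fc <- function(bands, ref_allele) {
  need <- c("allele", "intensity", "fragment_length")
  if (!all(need %in% names(bands)))
    stop("bands needs columns allele, intensity, fragment_length")
  if (any(bands$intensity < 0)) stop("intensities must be non-negative")
  if (any(bands$fragment_length <= 0)) stop("fragment lengths must be positive")
  alleles <- unique(bands$allele)
  if (length(alleles) != 2L) stop("exactly two allele labels required")
  if (!ref_allele %in% alleles) stop("unknown ref_allele")
  sig <- tapply(bands$intensity / bands$fragment_length, bands$allele, sum)
  if (any(sig == 0))
    stop("zero normalised signal for one allele; log2 ratio undefined")
  other <- setdiff(alleles, ref_allele)
  unname(log2(sig[[ref_allele]] / sig[[other]]))
}

#' Hybrid versus non-hybrid log2 fold-change ratio
#'
#' Normalises the hybrid-allele log2 fold change to the non-hybrid
#' (between-species) value: `(1 / log2FC_nonhybrid) * log2FC_hybrid`.
#' A value near 1 means the species difference is maintained in hybrids
#' (cis regulation); large or sign-flipped values flag dominance or trans
#' effects.
#'
#' @param log2fc_nonhybrid Non-hybrid between-species log2 fold change
#'   (nonzero).
#' @param log2fc_hybrid Hybrid-allele log2 fold change.
#' @return `log2fc_hybrid / log2fc_nonhybrid` (vectorised).
#' @export
hybrid_vs_nonhybrid_ratio <- function(log2fc_nonhybrid, log2fc_hybrid) {
  if (any(log2fc_nonhybrid == 0))
    stop("non-hybrid log2 fold change of 0: ratio undefined")
  log2fc_hybrid / log2fc_nonhybrid
}

#' Reference hybrid RT-PCR log2 fold changes
#'
#' Reads the shipped table of non-hybrid and hybrid-allele log2 fold
#' changes (D. melanogaster vs D. simulans) for the five RT-PCR-assayed
#' genes Rpl32, CG30486, Obp56f, CG11598 and CG15117.
#'
#' @return data.frame with columns `gene`, `log2fc_nonhybrid`,
#'   `log2fc_hybrid`.
#' @export
hybrid_rtpcr_table <- function() {
  read_tsv(system.file("extdata", "hybrid_allele_log2fc.tsv",
                       package = "promevol", mustWork = TRUE))
}

#' Map gene identifiers through an ortholog table
#'
#' Renames the rows of a count/expression matrix from one species'
#' identifiers to another's via a two-column ortholog map; genes without an
#' ortholog are dropped with a message.
#'
#' @param mat Matrix with gene rownames.
#' @param map data.frame whose first two columns are (current id, target id).
#' @return The matrix restricted to mapped genes, rows renamed.
#' @export
map_orthologs <- function(mat, map) {
  idx <- match(rownames(mat), map[[1L]])
  drop <- is.na(idx)
  if (any(drop))
    message(sprintf("dropping %d genes without orthologs", sum(drop)))
  out <- mat[!drop, , drop = FALSE]
  rownames(out) <- map[[2L]][idx[!drop]]
  out
}
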