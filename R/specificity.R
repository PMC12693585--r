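# Tissue specificity (tau) and gene-set construction.

#' Graded tissue-specificity index tau
#'
#' \deqn{\tau = \frac{\sum_{i=1}^{N}(1 - x_i/x_{max})}{N - 1}}
#'
#' where `x_i` is the expression of the gene in tissue `i` and `N` the number
#' of tissues. tau is 0 for perfectly uniform expression and 1 for expression
#' confined to a single tissue.
#'
#' @param profile Non-negative expression values across tissues (length >= 2).
#' @param log_transform If `TRUE`, apply `log2(x + 1)` before computing tau.
#'   Off by default: tau is computed on the expression values as supplied.
#' @return tau in `[0, 1]`, or `NA_real_` for an all-zero profile (tau is
#'   undefined there; never reported as 0).
#' @examples
#' tau(c(0, 0, 5, 0))      # 1
#' tau(c(3, 3, 3))         # 0
#' tau(c(10, 1, 1, 1, 1))  # 0.9
#' @export
tau <- function(profile, log_transform = FALSE) {
  profile <- as.numeric(profile)
  if (length(profile) < 2L) stop("tau needs >= 2 tissues")
  if (any(is.na(profile)) || any(profile < 0))
    stop("expression profile must be non-negative and complete")
  if (log_transform) profile <- log2(profile + 1)
  m <- max(profile)
  if (m == 0) return(NA_real_)
  sum(1 - profile / m) / (length(profile) - 1L)
}

.check_tissue_matrix <- function(mat) {
  if (is.null(rownames(mat)) || is.null(colnames(mat)))
    stop("tissue matrix needs gene rownames and tissue colnames")
  if (anyDuplicated(rownames(mat))) stop("duplicate gene identifiers")
  if (ncol(mat) < 2L) stop("tissue matrix needs >= 2 tissues")
  if (any(mat < 0)) stop("tissue matrix must be non-negative")
  invisible(mat)
}

#' tau and top tissue for every gene of an expression matrix
#'
#' @param mat Non-negative gene x tissue matrix with gene rownames and
#'   tissue colnames.
#' @param log_transform Passed to [tau()].
#' @return data.frame with columns `gene`, `tau`, `top_tissue` (tissue
#'   attaining the row maximum; ties resolved by column order). `top_tissue`
#'   is `NA` for all-zero genes.
#' @export
tau_table <- function(mat, log_transform = FALSE) {
  .check_tissue_matrix(mat)
  tv <- apply(mat, 1L, tau, log_transform = log_transform)
  top <- colnames(mat)[max.col(mat, ties.method = "first")]
  top[rowSums(mat) == 0] <- NA_character_
  data.frame(gene = rownames(mat), tau = unname(tv), top_tissue = top,
             stringsAsFactors = FALSE)
}

#' Select genes highly specific to one tissue
#'
#' Keeps genes whose tau reaches `tau_min` and whose expression maximum lies
#' in `target_tissue`; input order is preserved. This operationalises
#' "highly concentrated expression" in a tissue: tau alone does not say
#' which tissue dominates.
#'
#' @inheritParams tau_table
#' @param target_tissue Tissue that must attain the row maximum.
#' @param tau_min Minimum tau (default 0.9, the conventional threshold for
#'   tissue-specific genes).
#' @return Character vector of gene identifiers.
#' @export
select_gene_set <- function(mat, target_tissue, tau_min = 0.9,
                            log_transform = FALSE) {
  .check_tissue_matrix(mat)
  if (!target_tissue %in% colnames(mat))
    stop(sprintf("unknown tissue '%s'", target_tissue))
  tt <- tau_table(mat, log_transform = log_transform)
  keep <- !is.na(tt$tau) & tt$tau >= tau_min &
    !is.na(tt$top_tissue) & tt$top_tissue == target_tissue
  tt$gene[keep]
}

#' Top-k most specific genes of a tissue
#'
#' [select_gene_set()] followed by ranking on tau (descending) and
#' truncation to `k`; ties broken by gene identifier. Used for size-matched
#' control sets such as a Malpighian-tubule control.
#'
#' @inheritParams select_gene_set
#' @param k Number of genes to keep.
#' @return Character vector of at most `k` gene identifiers.
#' @export
top_specific_genes <- function(mat, target_tissue, k = 50L, tau_min = 0.9,
                               log_transform = FALSE) {
  genes <- select_gene_set(mat, target_tissue, tau_min, log_transform)
  if (!length(genes)) return(character(0))
  tt <- tau_table(mat, log_transform = log_transform)
  tv <- tt$tau[match(genes, tt$gene)]
  genes[order(-tv, genes)][seq_len(min(k, length(genes)))]
}

#' Seeded random control gene sample
#'
#' Draws `k` distinct genes from `universe` after removing `exclude`
#' (e.g. a random genome sample of the same size as a focal gene set,
#' excluding that set).
#'
#' @param universe Candidate gene identifiers.
#' @param exclude Genes that must not be drawn.
#' @param k Sample size.
#' @param seed Optional integer seed; identical seeds give identical samples.
#' @return Character vector of `k` genes.
#' @export
random_control_sample <- function(universe, exclude = character(0), k,
                                  seed = NULL) {
  pool <- setdiff(universe, exclude)
  if (k > length(pool))
    stop(sprintf("cannot sample %d genes from a pool of %d", k, length(pool)))
  if (!is.null(seed)) set.seed(seed)
  if (k == 0L) return(character(0))
  sample(pool, k)
}
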