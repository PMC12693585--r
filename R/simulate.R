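# Synthetic data generator.
#
# Emits every external input the pipeline consumes (multi-species promoter
# alignments, conservation and CAGE tracks, TSS anchors, tissue expression
# matrices, species and hybrid count tables) together with exact truth
# records. Events are generated directly on the reference coordinate frame
# and the alignment emitted with explicit gaps, so the generator's
# bookkeeping is an exact oracle for the event-coding stage — no aligner is
# in the loop and misalignment noise is out of scope.

.BASES <- c("A", "C", "G", "T")

#' Simulation configuration
#'
#' Collects every tunable of the synthetic-data generator with defaults
#' emulating the real study conditions: a -1000/+300 promoter window, four
#' non-reference species on a melanogaster-subgroup-like divergence ladder,
#' an elevated-rate hotspot inside the 350-nt scored promoter region,
#' CAGE peaks at annotated candidate TSSs with one dominant peak, a
#' conservation track depressed where events occur, and negative binomial
#' expression with three replicates per condition.
#'
#' @param seed Integer seed used by [simulate_dataset()].
#' @param n_genes Number of genes with alignments/tracks.
#' @param upstream,downstream Promoter window extent (1000/300).
#' @param sub_rate Background substitution probability per reference site at
#'   divergence 1.
#' @param indel_rate Background indel initiation probability per site at
#'   divergence 1 (split evenly between deletions and insertions).
#' @param indel_mean_len Mean of the geometric indel length distribution.
#' @param divergence Named divergence scalars for the non-reference species
#'   (ladder qualitatively echoing simulans/sechellia/yakuba/erecta).
#' @param ref_species Reference species name.
#' @param hotspot_region Inclusive offset interval with elevated rates.
#' @param hotspot_multiplier Rate multiplier inside the hotspot (>= 1; 1
#'   disables the hotspot).
#' @param cage_peak_height Range of CAGE peak heights (signal units).
#' @param cage_n_candidates Annotated candidate TSSs per gene.
#' @param cage_dominance Height multiplier of the dominant peak.
#' @param cons_mean,cons_sd Gaussian background of the conservation track.
#' @param cons_depression Conservation drop at event positions.
#' @param nb_mean,nb_dispersion Negative binomial mean and dispersion of the
#'   expression counts.
#' @param lfc_sd SD of the per-gene true log2 fold-change distribution.
#' @param n_reps Replicates per species/allele.
#' @param n_expr_genes Genes in the expression tables.
#' @param hybrid_scenario `"cis_maintained"` (allele ratio equals the
#'   species ratio), `"dominant_A"` or `"dominant_B"` (fixed dominance of
#'   one allele irrespective of the species ratio).
#' @param dominance_log2 log2 allele ratio under a dominance scenario.
#' @param x_fraction Fraction of expression genes labelled chromosome X
#'   (mono-allelic in hybrids: the reference allele is absent).
#' @param n_tissues,n_tissue_genes,specific_fraction,leakage Tissue-matrix
#'   shape: number of tissues and genes, fraction of planted
#'   tissue-specific genes, and their maximal relative leakage outside the
#'   dominant tissue.
#' @return List of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_genes = 12L,
                       upstream = 1000L, downstream = 300L,
                       sub_rate = 0.05, indel_rate = 0.01,
                       indel_mean_len = 3,
                       divergence = c(Dsim = 0.4, Dsec = 0.5,
                                      Dyak = 1.0, Dere = 1.2),
                       ref_species = "Dmel",
                       hotspot_region = c(-380L, -31L),
                       hotspot_multiplier = 5,
                       cage_peak_height = c(20, 100),
                       cage_n_candidates = 3L,
                       cage_dominance = 5,
                       cons_mean = 1.5, cons_sd = 0.5,
                       cons_depression = 2,
                       nb_mean = 200, nb_dispersion = 0.1,
                       lfc_sd = 1, n_reps = 3L, n_expr_genes = 300L,
                       hybrid_scenario = c("cis_maintained", "dominant_A",
                                           "dominant_B"),
                       dominance_log2 = 2, x_fraction = 0.2,
                       n_tissues = 10L, n_tissue_genes = 100L,
                       specific_fraction = 0.3, leakage = 0.03) {
  hybrid_scenario <- match.arg(hybrid_scenario)
  stopifnot(sub_rate >= 0, sub_rate <= 1, indel_rate >= 0, indel_rate <= 1,
            hotspot_multiplier >= 1, n_reps >= 2L, indel_mean_len >= 1,
            !is.null(names(divergence)))
  structure(as.list(environment()), class = "sim_config")
}

# deterministic genomic layout for synthetic genes (all on "+")
.sim_tss_position <- function(cfg, i) 10000L + (i - 1L) * 5000L
.SIM_CHROM <- "chr2R"

# per-offset rate multiplier implementing the hotspot
.hotspot_mult <- function(cfg) {
  off <- seq.int(-cfg$upstream, cfg$downstream - 1L)
  m <- rep(1, length(off))
  m[off >= cfg$hotspot_region[1L] & off <= cfg$hotspot_region[2L]] <-
    cfg$hotspot_multiplier
  m
}

.rgeom_len <- function(n, mean_len) {
  if (mean_len <= 1) rep(1L, n) else rgeom(n, 1 / mean_len) + 1L
}

#' Simulate one multi-species promoter alignment with exact truth
#'
#' Draws a uniform-ACGT reference over the promoter window and derives each
#' non-reference species by per-site substitutions and geometric-length
#' indels at divergence-scaled rates, multiplied inside the hotspot region.
#' The emitted alignment interleaves every species' insertions as separate
#' columns, so each pairwise reference comparison reads back exactly the
#' generated events.
#'
#' Uses the current RNG state; seed via `set.seed()` or use
#' [simulate_dataset()].
#'
#' @param cfg A [sim_config()].
#' @param gene Gene identifier.
#' @return List with `alignment` (a [promoter_alignment()]) and `truth`
#'   (data.frame `species`, `column`, `offset`, `kind`, `length`, sorted by
#'   column within species — the oracle for [event_positions_5prime()]).
#' @export
simulate_promoter_alignment <- function(cfg, gene = "gene1") {
  W <- cfg$upstream + cfg$downstream
  offsets <- seq.int(-cfg$upstream, cfg$downstream - 1L)
  mult <- .hotspot_mult(cfg)
  ref <- sample(.BASES, W, replace = TRUE)
  species <- names(cfg$divergence)

  per_sp <- lapply(species, function(sp) {
    s <- cfg$divergence[[sp]]
    sub <- runif(W) < pmin(cfg$sub_rate * s * mult, 0.9)
    gap <- logical(W)
    dstart <- which(runif(W) < pmin(cfg$indel_rate / 2 * s * mult, 0.5))
    for (i in dstart) {
      len <- .rgeom_len(1L, cfg$indel_mean_len)
      gap[i:min(W, i + len - 1L)] <- TRUE
    }
    ins_len <- integer(W)
    istart <- which(runif(W) < pmin(cfg$indel_rate / 2 * s * mult, 0.5))
    for (i in istart) ins_len[i] <- ins_len[i] + .rgeom_len(1L, cfg$indel_mean_len)
    sub[gap] <- FALSE
    chars <- ref
    for (i in which(sub)) chars[i] <- sample(setdiff(.BASES, ref[i]), 1L)
    chars[gap] <- "-"
    ins_bases <- lapply(seq_len(W), function(i) {
      if (ins_len[i] > 0L) sample(.BASES, ins_len[i], replace = TRUE)
      else character(0)
    })
    list(sub = sub, gap = gap, ins_len = ins_len, chars = chars,
         ins_bases = ins_bases)
  })
  names(per_sp) <- species

  # column layout: each reference position contributes its own column plus
  # one column per inserted base, species blocks in fixed order
  ins_mat <- vapply(per_sp, `[[`, integer(W), "ins_len")  # W x n_species
  width_at <- 1L + as.integer(rowSums(ins_mat))
  col_end <- cumsum(width_at)
  colof <- col_end - width_at + 1L     # column of reference base i
  Wtot <- col_end[W]

  rows <- matrix("-", nrow = length(species) + 1L, ncol = Wtot,
                 dimnames = list(c(cfg$ref_species, species), NULL))
  rows[1L, colof] <- ref
  for (k in seq_along(species)) {
    rows[k + 1L, colof] <- per_sp[[k]]$chars
  }
  ins_pos <- which(rowSums(ins_mat) > 0L)
  ins_start <- matrix(0L, nrow = W, ncol = length(species))
  for (i in ins_pos) {
    at <- colof[i] + 1L
    for (k in seq_along(species)) {
      li <- ins_mat[i, k]
      if (li > 0L) {
        rows[k + 1L, at:(at + li - 1L)] <- per_sp[[k]]$ins_bases[[i]]
        ins_start[i, k] <- at
        at <- at + li
      }
    }
  }

  truth <- lapply(seq_along(species), function(k) {
    ps <- per_sp[[k]]
    ev <- list()
    si <- which(ps$sub)
    if (length(si))
      ev[[length(ev) + 1L]] <- data.frame(
        species = species[k], column = colof[si], offset = offsets[si],
        kind = "substitution", length = 1L)
    # deletion runs, split where the same species inserts inside the run
    r <- rle(ps$gap)
    ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
    for (ri in which(r$values)) {
      i <- starts[ri]; j <- ends[ri]
      cuts <- i - 1L
      if (j > i)
        cuts <- c(cuts, intersect(i:(j - 1L), which(ps$ins_len > 0L)))
      cuts <- c(cuts, j)
      for (ci in seq_len(length(cuts) - 1L)) {
        a <- cuts[ci] + 1L; b <- cuts[ci + 1L]
        ev[[length(ev) + 1L]] <- data.frame(
          species = species[k], column = colof[a], offset = offsets[a],
          kind = "deletion", length = b - a + 1L)
      }
    }
    ii <- which(ps$ins_len > 0L)
    if (length(ii))
      ev[[length(ev) + 1L]] <- data.frame(
        species = species[k], column = ins_start[ii, k],
        offset = offsets[ii], kind = "insertion", length = ps$ins_len[ii])
    if (!length(ev)) return(NULL)
    out <- do.call(rbind, ev)
    out[order(out$column), , drop = FALSE]
  })
  truth <- do.call(rbind, truth)
  if (is.null(truth))
    truth <- data.frame(species = character(0), column = integer(0),
                        offset = integer(0), kind = character(0),
                        length = integer(0))
  rownames(truth) <- NULL

  aln <- promoter_alignment(
    setNames(apply(rows, 1L, paste, collapse = ""), rownames(rows)),
    ref_species = cfg$ref_species,
    tss_column = colof[cfg$upstream + 1L],
    gene = gene)
  list(alignment = aln, truth = truth)
}

#' Simulate a per-base conservation track for one gene
#'
#' Gaussian background with the score depressed by `cons_depression` at
#' every reference base touched by an event in any species (substituted
#' bases, deleted spans, insertion anchors) — emulating the lower
#' conservation of fast-evolving promoter positions.
#'
#' @param cfg A [sim_config()].
#' @param truth Truth table from [simulate_promoter_alignment()].
#' @param gene_index Index of the gene in the synthetic genome layout.
#' @return A [signal_track] over the gene's promoter window (values rounded
#'   to 4 decimals so on-disk bedGraph round trips exactly).
#' @export
simulate_conservation_track <- function(cfg, truth, gene_index = 1L) {
  W <- cfg$upstream + cfg$downstream
  offsets <- seq.int(-cfg$upstream, cfg$downstream - 1L)
  v <- rnorm(W, cfg$cons_mean, cfg$cons_sd)
  hit <- logical(W)
  for (r in seq_len(nrow(truth))) {
    i <- truth$offset[r] + cfg$upstream + 1L
    span <- if (truth$kind[r] == "deletion")
      i:min(W, i + truth$length[r] - 1L) else i
    hit[span] <- TRUE
  }
  v[hit] <- v[hit] - cfg$cons_depression
  t0 <- .sim_tss_position(cfg, gene_index)
  signal_track(.SIM_CHROM, t0 - cfg$upstream, t0 + cfg$downstream,
               round(v, 4L), strand = "+")
}

#' Simulate a CAGE track and candidate TSSs for one gene
#'
#' Places `cage_n_candidates` annotated candidate TSSs (offset 0 is always
#' one of them), gives each a Poisson-jittered peak over a 5-base kernel,
#' and scales one randomly chosen candidate by `cage_dominance`.
#'
#' @inheritParams simulate_conservation_track
#' @return List with `track` (a [signal_track]), `candidates` (data.frame
#'   `gene`, `offset`, `position` 0-based genomic) and `dominant_offset`
#'   (truth).
#' @export
simulate_cage <- function(cfg, gene = "gene1", gene_index = 1L) {
  W <- cfg$upstream + cfg$downstream
  k <- cfg$cage_n_candidates
  repeat {
    cand <- c(0L, sample(setdiff(seq.int(-300L, 100L), 0L), k - 1L))
    if (k == 1L || min(diff(sort(cand))) >= 12L) break
  }
  heights <- runif(k, cfg$cage_peak_height[1L], cfg$cage_peak_height[2L])
  dom <- sample.int(k, 1L)
  heights[dom] <- max(heights) * cfg$cage_dominance
  kernel <- c(0.1, 0.3, 1, 0.3, 0.1)
  v <- numeric(W)
  for (j in seq_len(k)) {
    center <- cand[j] + cfg$upstream + 1L
    for (o in -2:2) {
      p <- center + o
      if (p >= 1L && p <= W)
        v[p] <- v[p] + rpois(1L, heights[j] * kernel[o + 3L])
    }
  }
  t0 <- .sim_tss_position(cfg, gene_index)
  track <- signal_track(.SIM_CHROM, t0 - cfg$upstream, t0 + cfg$downstream,
                        v, strand = "+")
  list(track = track,
       candidates = data.frame(gene = gene, offset = cand,
                               position = t0 + cand),
       dominant_offset = cand[dom])
}

#' Simulate species and hybrid expression tables with known log2FCs
#'
#' Negative binomial counts for two species (A is the reference-species
#' role) with per-gene true log2 fold changes, plus a hybrid allele table
#' under the configured scenario: `cis_maintained` reuses the species
#' ratio per gene; `dominant_A`/`dominant_B` impose a fixed
#' `dominance_log2` allele ratio irrespective of it. A configured fraction
#' of genes is labelled chromosome X and rendered mono-allelic (allele A
#' absent) in the hybrid.
#'
#' @param cfg A [sim_config()].
#' @return List with `counts_a`, `counts_b` (gene x replicate matrices),
#'   `lengths`, `chrom`, `truth_lfc` (named, A over B) and `hybrid`
#'   (data.frame `gene`, `chrom`, `allele`, replicate count columns).
#' @export
simulate_expression <- function(cfg) {
  G <- cfg$n_expr_genes
  genes <- sprintf("g%04d", seq_len(G))
  lengths <- sample(500:3000, G, replace = TRUE)
  chrom <- sample(c("X", "2L", "2R", "3L", "3R"), G, replace = TRUE,
                  prob = c(cfg$x_fraction, rep((1 - cfg$x_fraction) / 4, 4)))
  lfc <- rnorm(G, 0, cfg$lfc_sd)
  size <- 1 / cfg$nb_dispersion
  mu_a <- cfg$nb_mean * 2^(lfc / 2)
  mu_b <- cfg$nb_mean * 2^(-lfc / 2)
  draw <- function(mu) {
    m <- vapply(seq_len(cfg$n_reps), function(r) rnbinom(G, mu = mu, size = size),
                numeric(G))
    dimnames(m) <- list(genes, sprintf("rep%d", seq_len(cfg$n_reps)))
    m
  }
  counts_a <- draw(mu_a)
  counts_b <- draw(mu_b)

  ratio <- switch(cfg$hybrid_scenario,
                  cis_maintained = lfc,
                  dominant_A = rep(cfg$dominance_log2, G),
                  dominant_B = rep(-cfg$dominance_log2, G))
  mu_ha <- 0.5 * cfg$nb_mean * 2^(ratio / 2)
  mu_hb <- 0.5 * cfg$nb_mean * 2^(-ratio / 2)
  mu_ha[chrom == "X"] <- 0
  ha <- draw(pmax(mu_ha, 0))
  ha[mu_ha == 0, ] <- 0L
  hb <- draw(mu_hb)
  hybrid <- rbind(
    data.frame(gene = genes, chrom = chrom, allele = "A", ha,
               check.names = FALSE),
    data.frame(gene = genes, chrom = chrom, allele = "B", hb,
               check.names = FALSE))
  hybrid <- hybrid[order(hybrid$gene, hybrid$allele), ]
  rownames(hybrid) <- NULL
  list(counts_a = counts_a, counts_b = counts_b, lengths = lengths,
       chrom = chrom, truth_lfc = setNames(lfc, genes), hybrid = hybrid)
}

#' Simulate a gene x tissue expression matrix with planted specific genes
#'
#' A configured fraction of genes is tissue-specific (one dominant tissue,
#' relative leakage at most `leakage` elsewhere, so tau >= 1 - leakage);
#' the rest express near-uniformly across tissues.
#'
#' @param cfg A [sim_config()].
#' @return List with `matrix` (gene x tissue) and `truth` (data.frame
#'   `gene`, `tissue` of the planted specific genes).
#' @export
simulate_tissue_matrix <- function(cfg) {
  tissues <- c("accessory_gland", "malpighian_tubule", "testis", "head",
               "midgut", "fat_body", "ovary", "carcass", "salivary_gland",
               "crop")[seq_len(cfg$n_tissues)]
  G <- cfg$n_tissue_genes
  genes <- sprintf("t%04d", seq_len(G))
  n_spec <- round(cfg$specific_fraction * G)
  spec_tissue <- sample(tissues, n_spec, replace = TRUE)
  m <- matrix(0, nrow = G, ncol = length(tissues),
              dimnames = list(genes, tissues))
  for (i in seq_len(n_spec)) {
    xmax <- runif(1L, 100, 1000)
    row <- xmax * cfg$leakage * runif(length(tissues))
    row[match(spec_tissue[i], tissues)] <- xmax
    m[i, ] <- row
  }
  for (i in seq_len(G - n_spec) + n_spec) {
    m[i, ] <- runif(1L, 5, 50) * runif(length(tissues), 0.7, 1.3)
  }
  list(matrix = m,
       truth = data.frame(gene = genes[seq_len(n_spec)],
                          tissue = spec_tissue))
}

#' Write a complete synthetic dataset to a directory
#'
#' Seeds the RNG from `cfg$seed` and emits alignments (aligned FASTA),
#' conservation and CAGE tracks (bedGraph), TSS candidate anchors (BED),
#' species and hybrid count tables, a tissue matrix, an identity ortholog
#' map (TSV), JSON truth files and a manifest. Identical configurations
#' produce byte-identical directories.
#'
#' @param cfg A [sim_config()].
#' @param dir Output directory (created if missing).
#' @return Invisibly, the manifest as a list.
#' @export
simulate_dataset <- function(cfg, dir) {
  set.seed(cfg$seed)
  dir.create(file.path(dir, "alignments"), recursive = TRUE,
             showWarnings = FALSE)
  dir.create(file.path(dir, "tracks"), showWarnings = FALSE)
  dir.create(file.path(dir, "truth"), showWarnings = FALSE)

  genes <- sprintf("gene%03d", seq_len(cfg$n_genes))
  aln_truth <- list(); cage_truth <- list(); cand_all <- list()
  for (i in seq_along(genes)) {
    g <- genes[i]
    sim <- simulate_promoter_alignment(cfg, g)
    Biostrings::writeXStringSet(
      Biostrings::BStringSet(sim$alignment$rows),
      file.path(dir, "alignments", paste0(g, ".fasta")))
    aln_truth[[g]] <- list(tss_column = sim$alignment$tss_column,
                           events = sim$truth)
    cons <- simulate_conservation_track(cfg, sim$truth, i)
    write_bedgraph(cons, file.path(dir, "tracks", paste0(g, "_phylop.bedGraph")))
    cage <- simulate_cage(cfg, g, i)
    write_bedgraph(cage$track,
                   file.path(dir, "tracks", paste0(g, "_cage.bedGraph")))
    cage_truth[[g]] <- cage$dominant_offset
    cand_all[[g]] <- cage$candidates
  }
  cand <- do.call(rbind, cand_all)
  cand_gr <- GenomicRanges::GRanges(
    seqnames = .SIM_CHROM,
    ranges = IRanges::IRanges(start = cand$position + 1L, width = 1L),
    strand = "+")
  names(cand_gr) <- cand$gene
  write_tss_bed(cand_gr, file.path(dir, "tss.bed"))

  expr <- simulate_expression(cfg)
  write_tsv(data.frame(gene = rownames(expr$counts_a),
                       length = expr$lengths, chrom = expr$chrom,
                       expr$counts_a, check.names = FALSE),
            file.path(dir, "counts_a.tsv"))
  write_tsv(data.frame(gene = rownames(expr$counts_b),
                       length = expr$lengths, chrom = expr$chrom,
                       expr$counts_b, check.names = FALSE),
            file.path(dir, "counts_b.tsv"))
  write_tsv(expr$hybrid, file.path(dir, "hybrid_counts.tsv"))
  write_tsv(data.frame(gene_a = rownames(expr$counts_a),
                       gene_b = paste0(rownames(expr$counts_a), "_spB")),
            file.path(dir, "orthologs.tsv"))

  tm <- simulate_tissue_matrix(cfg)
  write_tsv(data.frame(gene = rownames(tm$matrix), round(tm$matrix, 4L),
                       check.names = FALSE),
            file.path(dir, "tissues.tsv"))

  jsonlite::write_json(
    lapply(aln_truth, function(x)
      list(tss_column = x$tss_column, events = x$events)),
    file.path(dir, "truth", "alignment_events.json"),
    auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(cage_truth,
                       file.path(dir, "truth", "dominant_tss.json"),
                       auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(as.list(round(expr$truth_lfc, 10)),
                       file.path(dir, "truth", "log2fc.json"),
                       auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(tm$truth, file.path(dir, "truth", "tissue_specific.json"),
                       digits = NA)

  manifest <- list(
    genes = genes,
    files = c("tss.bed", "counts_a.tsv", "counts_b.tsv",
              "hybrid_counts.tsv", "orthologs.tsv", "tissues.tsv"),
    config = cfg[setdiff(names(cfg), "")]
  )
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
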