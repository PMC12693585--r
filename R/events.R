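# Event coding of reference-anchored multi-species promoter alignments.
#
# Every comparison is one non-reference species against the designated
# reference row (the D. melanogaster role), never all-pairs. Per-reference-
# base 0/1 vectors drive the sliding event score; collapsed 5'-start events
# drive the positional G-function analysis.

.ALN_ALPHABET <- c("A", "C", "G", "T", "N", "-")

#' Reference-anchored promoter alignment
#'
#' @param rows Named character vector of gapped sequences of equal width
#'   (names are species identifiers; gap character `-`). Lowercase input is
#'   uppercased. Only `A C G T N -` are allowed.
#' @param ref_species Name of the reference row; the TSS column must carry a
#'   reference base.
#' @param tss_column 1-based alignment column aligned to the reference TSS
#'   base (offset 0).
#' @param gene Optional gene identifier.
#' @return Object of class `promoter_alignment`.
#' @export
promoter_alignment <- function(rows, ref_species, tss_column, gene = NULL) {
  if (is.null(names(rows)) || anyDuplicated(names(rows)))
    stop("alignment rows must have unique species names")
  rows <- toupper(unlist(rows))
  w <- unique(nchar(rows))
  if (length(w) != 1L) stop("alignment rows must have equal gapped width")
  if (!ref_species %in% names(rows))
    stop(sprintf("reference species '%s' not in alignment", ref_species))
  bad <- unique(unlist(strsplit(rows, "", fixed = TRUE)))
  bad <- setdiff(bad, .ALN_ALPHABET)
  if (length(bad))
    stop(sprintf("unsupported alignment characters: %s",
                 paste(bad, collapse = " ")))
  refc <- strsplit(rows[[ref_species]], "", fixed = TRUE)[[1L]]
  if (all(refc == "-")) stop("reference row is gap-only")
  tss_column <- as.integer(tss_column)
  if (is.na(tss_column) || tss_column < 1L || tss_column > w)
    stop("tss_column outside alignment")
  if (refc[tss_column] == "-")
    stop("tss_column must carry a reference base, not a gap")
  structure(list(gene = gene, ref_species = ref_species, rows = rows,
                 tss_column = tss_column, width = w),
            class = "promoter_alignment")
}

#' @export
print.promoter_alignment <- function(x, ...) {
  cat(sprintf("promoter_alignment%s: %d species x %d columns, ref %s, TSS column %d\n",
              if (is.null(x$gene)) "" else paste0(" [", x$gene, "]"),
              length(x$rows), x$width, x$ref_species, x$tss_column))
  invisible(x)
}

.aln_chars <- function(aln, species) {
  strsplit(aln$rows[[species]], "", fixed = TRUE)[[1L]]
}

# signed TSS offset of every alignment column; NA where the reference is gapped
.ref_offsets <- function(aln) {
  refc <- .aln_chars(aln, aln$ref_species)
  off <- rep(NA_integer_, aln$width)
  base <- refc != "-"
  rank <- cumsum(base)
  off[base] <- rank[base] - rank[aln$tss_column]
  off
}

#' Trim an alignment to the promoter window around the TSS
#'
#' Restricts the alignment to reference offsets `[-upstream, downstream)`
#' counted in reference (non-gap) bases. Alignment columns that are gaps in
#' the reference between retained columns are kept. If the reference extends
#' less far than requested, the truncated window is returned with a warning
#' and the realised offset range recorded in attribute `offset_range`.
#'
#' @param aln A [promoter_alignment()].
#' @param upstream,downstream Window extent in reference bases (defaults
#'   1000 and 300, i.e. offsets -1000 .. +299).
#' @return A trimmed [promoter_alignment()].
#' @export
trim_to_window <- function(aln, upstream = 1000L, downstream = 300L) {
  stopifnot(inherits(aln, "promoter_alignment"))
  off <- .ref_offsets(aln)
  keep <- which(!is.na(off) & off >= -upstream & off <= downstream - 1L)
  if (!length(keep)) stop("no reference bases inside the requested window")
  first <- min(keep); last <- max(keep)
  got <- range(off[keep])
  if (got[1L] > -upstream || got[2L] < downstream - 1L)
    warning(sprintf("reference covers offsets [%d, %d] of requested [%d, %d]",
                    got[1L], got[2L], -upstream, downstream - 1L))
  out <- promoter_alignment(substring(aln$rows, first, last),
                            aln$ref_species, aln$tss_column - first + 1L,
                            gene = aln$gene)
  attr(out, "offset_range") <- got
  out
}

# shared column classification for one species pair; drops both-gap columns
.pair_columns <- function(aln, other_species) {
  if (other_species == aln$ref_species)
    stop("other_species must differ from the reference")
  if (!other_species %in% names(aln$rows))
    stop(sprintf("species '%s' not in alignment", other_species))
  refc <- .aln_chars(aln, aln$ref_species)
  othc <- .aln_chars(aln, other_species)
  off <- .ref_offsets(aln)
  keep <- !(refc == "-" & othc == "-")
  cols <- which(keep)
  refc <- refc[keep]; othc <- othc[keep]; off <- off[keep]
  kind <- rep("conserved", length(cols))
  kind[refc != "-" & othc == "-"] <- "deletion"
  kind[refc == "-" & othc != "-"] <- "insertion"
  sub <- refc != "-" & othc != "-" & refc != othc & refc != "N" & othc != "N"
  kind[sub] <- "substitution"
  list(column = cols, offset = off, kind = kind)
}

#' Per-reference-base 0/1 change coding of a species pair
#'
#' Codes each reference base of the window as 0 (conserved) or 1 (changed)
#' against one other species. In `base` mode a 1 marks a nucleotide
#' mismatch (both rows carry a base; `N` counts as conserved). In `indel`
#' mode every reference base aligned to a gap in the other row (deletion) is
#' a 1, and each insertion in the other row contributes a single 1 at the
#' reference base immediately 5' of the inserted block. `all` is the
#' elementwise OR of the two.
#'
#' @param aln A [promoter_alignment()] (typically from [trim_to_window()]).
#' @param other_species Non-reference species to compare.
#' @param mode `"all"`, `"base"` or `"indel"`.
#' @return Object of class `event_vector`: list with `gene`, `ref`, `other`,
#'   `mode`, `offsets` (signed reference offsets) and `bits` (0/1 integers,
#'   one per offset).
#' @export
pairwise_events <- function(aln, other_species,
                            mode = c("all", "base", "indel")) {
  mode <- match.arg(mode)
  pc <- .pair_columns(aln, other_species)
  ref_base <- !is.na(pc$offset)
  offsets <- pc$offset[ref_base]
  base_bit <- as.integer(pc$kind[ref_base] == "substitution")
  del_bit <- as.integer(pc$kind[ref_base] == "deletion")
  ins_bit <- integer(length(offsets))
  ins_cols <- which(pc$kind == "insertion")
  if (length(ins_cols)) {
    # index of the last reference base at or before each position
    ref_rank <- cumsum(ref_base)
    anchor <- ref_rank[ins_cols]
    orphan <- anchor == 0L
    if (any(orphan)) {
      warning("insertion before the first reference base dropped (no 5' anchor)")
      anchor <- anchor[!orphan]
    }
    ins_bit[unique(anchor)] <- 1L
  }
  indel_bit <- as.integer(del_bit | ins_bit)
  bits <- switch(mode,
                 base = base_bit,
                 indel = indel_bit,
                 all = as.integer(base_bit | indel_bit))
  structure(list(gene = aln$gene, ref = aln$ref_species,
                 other = other_species, mode = mode,
                 offsets = offsets, bits = bits),
            class = "event_vector")
}

#' Collapsed change events positioned at their 5' start
#'
#' The event list consumed by the positional G-function analysis: each
#' maximal run of deleted reference bases collapses to one deletion event at
#' its 5' start; each inserted block collapses to one insertion event at the
#' reference base immediately 5' of the block; base changes are single
#' events. Run contiguity is judged after removing columns gapped in both
#' rows.
#'
#' @inheritParams pairwise_events
#' @return data.frame sorted by alignment column with columns `column`
#'   (1-based alignment column of the event's 5' start), `offset` (signed
#'   reference offset), `kind` (`substitution`, `deletion`, `insertion`) and
#'   `length` (bases affected).
#' @export
event_positions_5prime <- function(aln, other_species) {
  pc <- .pair_columns(aln, other_species)
  n <- length(pc$column)
  ref_rank <- cumsum(!is.na(pc$offset))
  run <- rle(pc$kind)
  ends <- cumsum(run$lengths)
  starts <- ends - run$lengths + 1L
  out <- list()
  for (r in seq_along(run$values)) {
    kind <- run$values[r]
    if (kind == "conserved") next
    i <- starts[r]; j <- ends[r]
    if (kind == "substitution") {
      for (k in i:j) {
        out[[length(out) + 1L]] <- data.frame(
          column = pc$column[k], offset = pc$offset[k],
          kind = "substitution", length = 1L)
      }
    } else if (kind == "deletion") {
      out[[length(out) + 1L]] <- data.frame(
        column = pc$column[i], offset = pc$offset[i],
        kind = "deletion", length = j - i + 1L)
    } else { # insertion
      if (ref_rank[i] == 0L) {
        warning("insertion before the first reference base dropped (no 5' anchor)")
        next
      }
      anchor <- which(ref_rank == ref_rank[i] & !is.na(pc$offset))[1L]
      out[[length(out) + 1L]] <- data.frame(
        column = pc$column[i], offset = pc$offset[anchor],
        kind = "insertion", length = j - i + 1L)
    }
  }
  if (!length(out))
    return(data.frame(column = integer(0), offset = integer(0),
                      kind = character(0), length = integer(0)))
  out <- do.call(rbind, out)
  out <- out[order(out$column), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Tally event vectors across species pairs or genes
#'
#' Per-offset sum of 0/1 event vectors sharing mode and offset range, e.g.
#' a concatenated gene-group tally across all species comparisons.
#'
#' @param vectors List of [pairwise_events()] results with identical `mode`
#'   and `offsets`.
#' @param group Optional tally label.
#' @return Object of class `event_tally`: list with `group`, `mode`,
#'   `offsets`, `counts` and `n_pairs`.
#' @export
tally_events <- function(vectors, group = NULL) {
  if (!length(vectors)) stop("no event vectors supplied")
  if (!all(vapply(vectors, inherits, logical(1), "event_vector")))
    stop("tally_events expects event_vector objects")
  modes <- unique(vapply(vectors, `[[`, "", "mode"))
  if (length(modes) != 1L)
    stop(sprintf("mixed event modes: %s", paste(modes, collapse = ", ")))
  off <- vectors[[1L]]$offsets
  same <- vapply(vectors, function(v) identical(v$offsets, off), logical(1))
  if (!all(same)) stop("event vectors cover different offset ranges")
  counts <- Reduce(`+`, lapply(vectors, `[[`, "bits"))
  structure(list(group = group, mode = modes, offsets = off,
                 counts = as.integer(counts), n_pairs = length(vectors)),
            class = "event_tally")
}
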