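# File formats and coordinate plumbing.
#
# All internal coordinates are 0-based half-open, matching BED/bedGraph on
# disk. Positions relative to a TSS use signed offsets with the TSS base at
# offset 0 and upstream negative; on "-" strand genes per-base tracks are
# reversed so offsets always increase downstream.

#' Per-base signal track
#'
#' A `signal_track` holds one real value per base over a genomic interval.
#' It is the in-memory form of a bedGraph slice (PhyloP conservation, CAGE
#' 5' signal) used throughout the pipeline.
#'
#' @param chrom Chromosome identifier.
#' @param start,end 0-based half-open interval; `start < end`.
#' @param values Numeric vector, one finite value per base
#'   (`length(values) == end - start`).
#' @param strand `"+"` or `"-"`.
#' @return An object of class `signal_track`.
#' @export
signal_track <- function(chrom, start, end, values, strand = "+") {
  start <- as.integer(start); end <- as.integer(end)
  if (is.na(start) || is.na(end) || start < 0L || start >= end)
    stop("invalid interval: need 0 <= start < end")
  if (!strand %in% c("+", "-")) stop("strand must be '+' or '-'")
  values <- as.numeric(values)
  if (length(values) != end - start)
    stop("length(values) must equal end - start")
  if (any(is.infinite(values) | is.nan(values)))
    stop("track values must be finite (NA marks missing bases)")
  structure(list(chrom = as.character(chrom), start = start, end = end,
                 strand = strand, values = values),
            class = "signal_track")
}

#' @export
print.signal_track <- function(x, ...) {
  cat(sprintf("signal_track %s:%d-%d(%s), %d bases, mean %.4g\n",
              x$chrom, x$start, x$end, x$strand, length(x$values),
              mean(x$values)))
  invisible(x)
}

#' @export
length.signal_track <- function(x) length(x$values)

# light-weight field validation of one BED body; returns a data.frame
.parse_bed_lines <- function(lines, path) {
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  bad <- which(nf < 4L)
  if (length(bad))
    stop(sprintf("malformed BED line %d in '%s': fewer than 4 fields",
                 bad[1L], path))
  start <- suppressWarnings(as.integer(vapply(fields, `[`, "", 2L)))
  end <- suppressWarnings(as.integer(vapply(fields, `[`, "", 3L)))
  bad <- which(is.na(start) | is.na(end))
  if (length(bad))
    stop(sprintf("malformed BED line %d in '%s': non-integer coordinates",
                 bad[1L], path))
  bad <- which(start >= end | start < 0L)
  if (length(bad))
    stop(sprintf("coordinate error at BED line %d in '%s': need 0 <= start < end",
                 bad[1L], path))
  strand <- vapply(seq_along(fields), function(i) {
    if (nf[i] >= 6L && fields[[i]][6L] %in% c("+", "-")) fields[[i]][6L]
    else "+"
  }, "")
  data.frame(chrom = vapply(fields, `[`, "", 1L), start = start, end = end,
             name = vapply(fields, `[`, "", 4L), strand = strand,
             stringsAsFactors = FALSE)
}

#' Read width-1 TSS anchors from a BED file
#'
#' Reads a BED3+ file whose name column carries gene identifiers and whose
#' records are width-1 TSS anchors. Strand is taken from column 6 when
#' present, else `"+"`.
#'
#' @param path Path to a BED file.
#' @return A [GenomicRanges::GRanges] of width-1 anchors, `names` set to the
#'   gene identifiers (BED name column).
#' @export
read_tss_bed <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (!length(lines))
    return(GenomicRanges::GRanges())
  df <- .parse_bed_lines(lines, path)
  if (any(df$end - df$start != 1L))
    stop("TSS anchors must have width 1 (end == start + 1)")
  gr <- GenomicRanges::GRanges(
    seqnames = df$chrom,
    ranges = IRanges::IRanges(start = df$start + 1L, end = df$end),
    strand = df$strand)
  names(gr) <- df$name
  gr
}

#' Write width-1 TSS anchors to BED6
#'
#' @param tss A named `GRanges` of width-1 anchors (as from [read_tss_bed()]).
#' @param path Output path.
#' @export
write_tss_bed <- function(tss, path) {
  strand <- as.character(BiocGenerics::strand(tss))
  strand[strand == "*"] <- "+"
  df <- data.frame(chrom = as.character(GenomicRanges::seqnames(tss)),
                   start = BiocGenerics::start(tss) - 1L,
                   end = BiocGenerics::end(tss),
                   name = names(tss), score = 0L, strand = strand)
  write.table(df, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a per-base signal slice from a bedGraph file
#'
#' Expands sparse bedGraph records to one value per base over the requested
#' interval. Bases not covered by any record receive `fill` (tracks such as
#' CAGE are genuinely zero where unobserved; conservation tracks can be
#' re-filled with `NA` if missingness should propagate).
#'
#' @param path Path to a bedGraph file.
#' @param chrom,start,end Requested 0-based half-open interval.
#' @param strand Strand stored on the returned track (values stay in genomic
#'   order; see [track_offsets()] for TSS-relative orientation).
#' @param fill Value for uncovered bases (default 0).
#' @return A [signal_track] covering exactly `[start, end)`.
#' @export
read_bedgraph <- function(path, chrom, start, end, strand = "+", fill = 0) {
  start <- as.integer(start); end <- as.integer(end)
  if (start >= end) stop("requested interval has length <= 0")
  gr <- rtracklayer::import(path, format = "bedGraph")
  gr <- gr[as.character(GenomicRanges::seqnames(gr)) == chrom]
  if (!length(gr)) {
    warning(sprintf("chromosome '%s' absent from '%s'; returning all-fill track",
                    chrom, path))
    return(signal_track(chrom, start, end, rep(fill, end - start), strand))
  }
  if (!IRanges::isDisjoint(GenomicRanges::ranges(gr)))
    stop("overlapping bedGraph records: per-base signal is ambiguous")
  values <- rep(as.numeric(fill), end - start)
  s <- pmax(BiocGenerics::start(gr) - 1L, start)   # back to 0-based
  e <- pmin(BiocGenerics::end(gr), end)
  keep <- which(s < e)
  for (i in keep) {
    values[(s[i] - start + 1L):(e[i] - start)] <- gr$score[i]
  }
  signal_track(chrom, start, end, values, strand)
}

#' Write a signal track as bedGraph
#'
#' Adjacent equal values are merged into one record; `fill`-valued runs can
#' optionally be omitted so that a write/read round trip is exact.
#'
#' @param track A [signal_track].
#' @param path Output path.
#' @param omit Value whose runs are not written (default `NULL`: write all).
#' @export
write_bedgraph <- function(track, path, omit = NULL) {
  v <- track$values
  r <- rle(v)
  end <- track$start + cumsum(r$lengths)
  start <- end - r$lengths
  keep <- if (is.null(omit)) rep(TRUE, length(r$values)) else r$values != omit
  df <- data.frame(chrom = track$chrom, start = start[keep], end = end[keep],
                   value = format(r$values[keep], digits = 15L,
                                  trim = TRUE, scientific = FALSE))
  write.table(df, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a multi-species alignment from aligned FASTA
#'
#' @param path Path to an aligned FASTA file (all records the same gapped
#'   width; gap character `-`).
#' @param ref_species Record name of the reference species; must be present.
#' @return A named character vector of uppercase gapped sequences with
#'   attribute `ref_species`.
#' @export
read_alignment_fasta <- function(path, ref_species) {
  seqs <- Biostrings::readBStringSet(path)
  rows <- toupper(as.character(seqs))
  if (!length(rows)) stop("empty alignment file")
  w <- nchar(rows)
  if (length(unique(w)) != 1L)
    stop(sprintf("ragged alignment in '%s': gapped lengths %s", path,
                 paste(sort(unique(w)), collapse = ", ")))
  if (!ref_species %in% names(rows))
    stop(sprintf("reference species '%s' absent from '%s'", ref_species, path))
  attr(rows, "ref_species") <- ref_species
  rows
}

#' TSS-relative promoter window
#'
#' Genomic interval covering offsets `[-upstream, +downstream)` around a
#' width-1 TSS anchor, respecting strand.
#'
#' @param tss A width-1 `GRanges` anchor.
#' @param upstream,downstream Window extent in bases (defaults 1000/300).
#' @return 0-based half-open `(start, end)` integer vector.
#' @export
promoter_window <- function(tss, upstream = 1000L, downstream = 300L) {
  t0 <- BiocGenerics::start(tss) - 1L  # 0-based TSS base
  if (as.character(BiocGenerics::strand(tss)) == "-") {
    c(start = t0 - downstream + 1L, end = t0 + upstream + 1L)
  } else {
    c(start = t0 - upstream, end = t0 + downstream)
  }
}

#' Orient a promoter track onto TSS offsets
#'
#' Maps a [signal_track] covering a gene's promoter window to a named vector
#' indexed by signed TSS offsets (`-upstream .. downstream-1`). On `"-"`
#' strand the values are reversed so offsets increase downstream.
#'
#' @param track A [signal_track] covering exactly the window returned by
#'   [promoter_window()] for this TSS.
#' @param upstream,downstream Window extent used to build the track.
#' @return Named numeric vector; names are the signed offsets.
#' @export
track_offsets <- function(track, upstream = 1000L, downstream = 300L) {
  n <- upstream + downstream
  if (length(track$values) != n)
    stop("track does not cover the requested promoter window")
  v <- if (track$strand == "-") rev(track$values) else track$values
  names(v) <- as.character(seq.int(-upstream, downstream - 1L))
  v
}

#' Read a tab-separated table with a header row
#'
#' @param path Input path.
#' @return A data.frame (strings kept as character).
#' @export
read_tsv <- function(path) {
  read.table(path, header = TRUE, sep = "\t", quote = "",
             stringsAsFactors = FALSE, check.names = FALSE)
}

#' Write a tab-separated table with a header row
#'
#' @param df A data.frame.
#' @param path Output path.
#' @export
write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
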