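# Toy alignments use a 30-base upstream / 5-base downstream frame:
# 35 reference bases, TSS at column 31, offsets -30 .. +4.
ref35 <- strrep("ACGTA", 7)

test_that("identical rows give all-zero event vectors and no events", {
  aln <- toy_aln(ref35, ref35, 31)
  for (mode in c("all", "base", "indel")) {
    ev <- pairwise_events(aln, "sim", mode)
    expect_equal(ev$offsets, -30:4)
    expect_true(all(ev$bits == 0L))
  }
  expect_equal(nrow(event_positions_5prime(aln, "sim")), 0L)
})

test_that("a single mismatch appears only in base and all modes", {
  other <- ref35
  substr(other, 21, 21) <- "G"  # column 21 = offset -10; ref has A there
  aln <- toy_aln(ref35, other, 31)
  base <- pairwise_events(aln, "sim", "base")
  expect_equal(base$offsets[base$bits == 1L], -10L)
  expect_equal(pairwise_events(aln, "sim", "all")$bits, base$bits)
  expect_true(all(pairwise_events(aln, "sim", "indel")$bits == 0L))
  ev <- event_positions_5prime(aln, "sim")
  expect_equal(ev$offset, -10L)
  expect_equal(ev$kind, "substitution")
  expect_equal(ev$length, 1L)
})

test_that("a 3-base deletion marks each base in indel mode and collapses 5'", {
  other <- ref35
  substr(other, 11, 13) <- "---"  # offsets -20, -19, -18
  aln <- toy_aln(ref35, other, 31)
  indel <- pairwise_events(aln, "sim", "indel")
  expect_equal(indel$offsets[indel$bits == 1L], c(-20L, -19L, -18L))
  expect_true(all(pairwise_events(aln, "sim", "base")$bits == 0L))
  ev <- event_positions_5prime(aln, "sim")
  expect_equal(nrow(ev), 1L)
  expect_equal(ev$offset, -20L)
  expect_equal(ev$kind, "deletion")
  expect_equal(ev$length, 3L)
})

test_that("an insertion collapses to a single 1 at the 5' flanking base", {
  # 2 inserted bases between offsets -7 and -6 (after reference column 24)
  ref_g <- paste0(substr(ref35, 1, 24), "--", substr(ref35, 25, 35))
  oth_g <- paste0(substr(ref35, 1, 24), "CC", substr(ref35, 25, 35))
  aln <- toy_aln(ref_g, oth_g, 33)  # TSS base shifted by the 2 gap columns
  indel <- pairwise_events(aln, "sim", "indel")
  expect_equal(indel$offsets[indel$bits == 1L], -7L)
  expect_true(all(pairwise_events(aln, "sim", "base")$bits == 0L))
  ev <- event_positions_5prime(aln, "sim")
  expect_equal(nrow(ev), 1L)
  expect_equal(ev$offset, -7L)
  expect_equal(ev$kind, "insertion")
  expect_equal(ev$length, 2L)
})

test_that("N is conserved, invalid characters are rejected", {
  other <- ref35
  substr(other, 5, 5) <- "N"
  aln <- toy_aln(ref35, other, 31)
  expect_true(all(pairwise_events(aln, "sim", "all")$bits == 0L))
  expect_error(toy_aln(ref35, sub("A", "R", ref35), 31), "characters")
  expect_error(pairwise_events(toy_aln(ref35, ref35, 31), "mel"),
               "differ from the reference")
})

test_that("insertions before any reference base are dropped with a warning", {
  aln <- toy_aln(paste0("--", ref35), paste0("GG", ref35), 33)
  expect_warning(ev <- event_positions_5prime(aln, "sim"), "5' anchor")
  expect_equal(nrow(ev), 0L)
  expect_warning(iv <- pairwise_events(aln, "sim", "indel"), "5' anchor")
  expect_true(all(iv$bits == 0L))
})

test_that("trimming keeps the requested reference window and gap columns", {
  aln <- toy_aln(ref35, ref35, 31)
  tr <- trim_to_window(aln, upstream = 30, downstream = 5)
  expect_identical(tr$rows, aln$rows)  # already exactly the window
  tr2 <- trim_to_window(aln, upstream = 10, downstream = 5)
  expect_equal(tr2$width, 15L)
  expect_equal(tr2$tss_column, 11L)
  expect_equal(pairwise_events(tr2, "sim", "all")$offsets, -10:4)
  expect_warning(trim_to_window(aln, upstream = 50, downstream = 5),
                 "covers offsets")
  tr3 <- suppressWarnings(trim_to_window(aln, upstream = 50, downstream = 5))
  expect_equal(attr(tr3, "offset_range"), c(-30L, 4L))
})

test_that("trimming preserves interior reference-gap columns", {
  ref_g <- paste0(substr(ref35, 1, 20), "--", substr(ref35, 21, 35))
  oth_g <- paste0(substr(ref35, 1, 20), "TT", substr(ref35, 21, 35))
  aln <- toy_aln(ref_g, oth_g, 33)
  tr <- trim_to_window(aln, upstream = 15, downstream = 5)
  # offsets -15..+4 = 20 reference bases; insertion block of 2 kept between
  expect_equal(tr$width, 22L)
  ev <- event_positions_5prime(tr, "sim")
  expect_equal(ev$kind, "insertion")
  expect_equal(ev$offset, -11L)
})

test_that("event vectors ignore identical flanking sequence outside the window", {
  pad <- strrep("GT", 10)
  other <- ref35
  substr(other, 21, 21) <- "G"
  a1 <- toy_aln(ref35, other, 31)
  a2 <- toy_aln(paste0(pad, ref35, pad), paste0(pad, other, pad), 51)
  t1 <- trim_to_window(a1, 30, 5)
  t2 <- trim_to_window(a2, 30, 5)
  for (mode in c("all", "base", "indel")) {
    expect_identical(pairwise_events(t1, "sim", mode)$bits,
                     pairwise_events(t2, "sim", mode)$bits)
  }
})

test_that("tallies sum bits across pairs and refuse mixed modes", {
  o1 <- ref35; substr(o1, 11, 11) <- "G"
  o2 <- ref35; substr(o2, 11, 11) <- "C"; substr(o2, 25, 25) <- "G"
  aln <- promoter_alignment(c(mel = ref35, sim = o1, yak = o2), "mel", 31)
  v1 <- pairwise_events(aln, "sim", "base")
  v2 <- pairwise_events(aln, "yak", "base")
  tal <- tally_events(list(v1, v2), group = "toy")
  expect_equal(tal$n_pairs, 2L)
  expect_equal(tal$counts[tal$offsets == -20L], 2L)
  expect_equal(sum(tal$counts), 3L)
  expect_identical(tally_events(list(v1))$counts, v1$bits)
  vi <- pairwise_events(aln, "yak", "indel")
  expect_error(tally_events(list(v1, vi)), "mixed")
})

test_that("all mode is the OR of base and indel modes on random alignments", {
  set.seed(101)
  cfg <- sim_config(sub_rate = 0.08, indel_rate = 0.03)
  sim <- simulate_promoter_alignment(cfg, "prop")
  for (sp in names(cfg$divergence)) {
    b <- pairwise_events(sim$alignment, sp, "base")$bits
    i <- pairwise_events(sim$alignment, sp, "indel")$bits
    a <- pairwise_events(sim$alignment, sp, "all")$bits
    expect_identical(a, as.integer(b | i))
  }
})

test_that("event coding reproduces the generator's truth exactly", {
  for (seed in c(7, 8, 9)) {
    set.seed(seed)
    cfg <- sim_config()
    sim <- simulate_promoter_alignment(cfg, "truthcheck")
    for (sp in names(cfg$divergence)) {
      tr_sp <- sim$truth[sim$truth$species == sp, -1L]
      rownames(tr_sp) <- NULL
      got <- event_positions_5prime(sim$alignment, sp)
      expect_identical(got[c("column", "offset", "kind", "length")],
                       tr_sp[c("column", "offset", "kind", "length")])
      # per-base vectors match the truth expansion
      bits <- truth_to_bits(tr_sp, cfg$upstream, cfg$downstream)
      expect_identical(pairwise_events(sim$alignment, sp, "base")$bits,
                       bits$base)
      expect_identical(pairwise_events(sim$alignment, sp, "indel")$bits,
                       bits$indel)
      expect_identical(pairwise_events(sim$alignment, sp, "all")$bits,
                       bits$all)
      # collapsed deletion lengths account for every reference base that is
      # aligned to a gap in the other row (direct count on the raw rows)
      refc <- strsplit(sim$alignment$rows[["Dmel"]], "")[[1]]
      othc <- strsplit(sim$alignment$rows[[sp]], "")[[1]]
      expect_equal(sum(got$length[got$kind == "deletion"]),
                   sum(refc != "-" & othc == "-"))
    }
  }
})
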