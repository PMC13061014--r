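# Hand-checkable single-gene fixture: reference "TTAAGGCCTT" under a 10 bp
# read; sense-strand Ts at positions 0, 1, 8, 9.
count_fixture <- function(dir, reads) {
  seqs <- list(c1 = paste0("TTAAGGCCTT", strrep("G", 30)))
  exons <- tibble::tibble(gene_id = "g1", transcript_id = "t1", chrom = "c1",
                          start = 0L, end = 40L, strand = "+")
  fa <- write_fixture_fasta(seqs, dir)
  gm <- load_annotation(write_fixture_gtf(exons, dir))
  aln <- load_alignments(write_fixture_sam(reads, c(c1 = 40L), dir), fa)
  asn <- assign_and_annotate(aln, gm)
  build_base_table(aln, asn, fa)
}

test_that("T>C conversions are counted per read against the sense-strand reference", {
  dir <- withr::local_tempdir()
  bt <- count_fixture(dir, tibble::tibble(
    qname = "r1", flag = 0L, chrom = "c1", pos = 0L, cigar = "10M",
    seq = "TCAAGGCCTT", qual = strrep("I", 10)))
  rc <- read_conversion_counts(filter_base_table(bt, q_floor = 0L))
  expect_equal(rc$n_T, 4L)
  expect_equal(rc$k, 1L)

  # the same read with the converted position masked
  rc2 <- read_conversion_counts(filter_base_table(
    bt, mask = tibble::tibble(chrom = "c1", pos = 1L), q_floor = 0L))
  expect_equal(rc2$n_T, 3L)
  expect_equal(rc2$k, 0L)

  # a read with no sense-strand T in its window contributes nothing
  bt3 <- count_fixture(dir, tibble::tibble(
    qname = "r3", flag = 0L, chrom = "c1", pos = 3L, cigar = "5M",
    seq = "AGGCC", qual = strrep("I", 5)))
  rc3 <- read_conversion_counts(filter_base_table(bt3, q_floor = 0L))
  expect_equal(nrow(rc3), 0L)
})

test_that("base quality floor and trim windows exclude positions from both k and n_T", {
  dir <- withr::local_tempdir()
  # qualities: position 1 (the conversion) below the floor
  qual <- paste0("I", rawToChar(as.raw(33 + 5)), strrep("I", 8))
  bt <- count_fixture(dir, tibble::tibble(
    qname = "r1", flag = 0L, chrom = "c1", pos = 0L, cigar = "10M",
    seq = "TCAAGGCCTT", qual = qual))
  rc <- read_conversion_counts(filter_base_table(bt, q_floor = 20L))
  expect_equal(rc$n_T, 3L)
  expect_equal(rc$k, 0L)

  # trimming the first 2 read positions removes T0 and the converted T1
  bt2 <- count_fixture(dir, tibble::tibble(
    qname = "r1", flag = 0L, chrom = "c1", pos = 0L, cigar = "10M",
    seq = "TCAAGGCCTT", qual = strrep("I", 10)))
  f <- filter_base_table(bt2, trim5 = 2L, q_floor = 0L)
  rc2 <- read_conversion_counts(f)
  expect_equal(rc2$n_T, 2L)
  expect_equal(rc2$k, 0L)
  # trim guard: trimmed positions are absent from the site table too
  st <- site_table(f)
  expect_false(any(st$gpos %in% c(0L, 1L)))
})

test_that("paired-end overlap positions count once; discordant positions can be dropped", {
  dir <- withr::local_tempdir()
  # mates overlap on [4,10); mate2 has a discordant base at position 8 (T->C)
  reads <- tibble::tibble(
    qname = "frag1", flag = c(99L, 147L), chrom = "c1", pos = c(0L, 4L),
    cigar = c("10M", "10M"),
    seq = c("TCAAGGCCTT", paste0("GGCCCT", "GGGG")),
    qual = c(strrep("I", 10), paste0(strrep("5", 6), strrep("I", 4))))
  bt <- count_fixture(dir, reads)

  once <- read_conversion_counts(filter_base_table(bt, q_floor = 0L))
  # union of covered positions [0,14): sense Ts at 0,1,8,9; counted once each
  expect_equal(once$n_T, 4L)
  # mate1 wins on quality at position 8 (I > 5): its base is the reference T,
  # so only mate1's conversion at position 1 counts
  expect_equal(once$k, 1L)

  dropd <- read_conversion_counts(filter_base_table(
    bt, q_floor = 0L, pair_policy = "drop_discordant"))
  # position 8 disagrees between the mates and is excluded entirely
  expect_equal(dropd$n_T, 3L)
  expect_equal(dropd$k, 1L)

  # disjoint mates: plain union, nothing dropped
  reads2 <- tibble::tibble(
    qname = "frag2", flag = c(99L, 147L), chrom = "c1", pos = c(0L, 20L),
    cigar = c("10M", "10M"),
    seq = c("TCAAGGCCTT", strrep("G", 10)),
    qual = strrep("I", 10))
  bt2 <- count_fixture(dir, reads2)
  rc2 <- read_conversion_counts(filter_base_table(bt2, q_floor = 0L))
  expect_equal(rc2$n_T, 4L)
  expect_equal(rc2$k, 1L)
})

test_that("gene aggregation sums weighted counts and flags low-coverage genes", {
  rc <- tibble::tibble(read_id = c("a", "b"), gene_id = "g1",
                       n_T = c(10L, 8L), k = c(1L, 0L), weight = 1)
  agg <- aggregate_gene_counts(rc, min_reads = 20)
  expect_equal(agg$K, 1)
  expect_equal(agg$N_T, 18)
  expect_equal(agg$read_count, 2)
  expect_true(agg$low_coverage)

  rc$weight <- 0.5
  agg2 <- aggregate_gene_counts(rc, min_reads = 1)
  expect_equal(agg2$K, 0.5)
  expect_equal(agg2$N_T, 9)
  expect_equal(agg2$read_count, 1)
  expect_false(agg2$low_coverage)

  # empty gene present in the annotation is reported with zeros
  dir <- withr::local_tempdir()
  exons <- tibble::tibble(gene_id = c("g1", "g2"),
                          transcript_id = c("t1", "t2"),
                          chrom = "c1", start = c(0L, 100L),
                          end = c(50L, 150L), strand = "+")
  gm <- load_annotation(write_fixture_gtf(exons, dir))
  agg3 <- aggregate_gene_counts(rc, gene_models = gm, min_reads = 20)
  g2 <- agg3[agg3$gene_id == "g2", ]
  expect_equal(g2$K, 0)
  expect_equal(g2$read_count, 0)
  expect_true(g2$low_coverage)
})

test_that("counts conserve against the site table and shrink monotonically under masking", {
  sim <- small_sim(seed = 11L)
  aln <- load_alignments(sim$sam, sim$fasta)
  gm <- load_annotation(sim$gtf)
  bt <- build_base_table(aln, assign_and_annotate(aln, gm), sim$fasta)
  f0 <- filter_base_table(bt, q_floor = 0L)

  # conservation: per-gene K totals equal the site-table conversion totals
  rc <- read_conversion_counts(f0)
  st <- site_table(f0)
  expect_equal(sum(rc$k), sum(st$tc_count))

  # monotonicity: growing the mask never increases K or N_T
  masks <- list(
    sim$truth$snps[0, c("chrom", "pos")],
    sim$truth$snps[1:2, c("chrom", "pos")],
    sim$truth$snps[, c("chrom", "pos")],
    dplyr::bind_rows(sim$truth$snps[, c("chrom", "pos")],
                     tibble::tibble(chrom = "chrT", pos = st$gpos[1:50]))
  )
  prev_k <- Inf; prev_n <- Inf
  for (m in masks) {
    rcm <- read_conversion_counts(filter_base_table(bt, mask = m, q_floor = 0L))
    expect_lte(sum(rcm$k), prev_k)
    expect_lte(sum(rcm$n_T), prev_n)
    prev_k <- sum(rcm$k); prev_n <- sum(rcm$n_T)
  }

  # chunked profile sums equal the unchunked totals
  prof <- conversion_profile(f0, chunks = 7L)
  glob <- conversion_profile(f0, chunks = 1L)
  sums <- prof |> dplyr::group_by(rpos) |>
    dplyr::summarise(t_coverage = sum(t_coverage), tc_count = sum(tc_count),
                     .groups = "drop")
  expect_equal(sums$t_coverage, glob$t_coverage)
  expect_equal(sums$tc_count, glob$tc_count)
})

test_that("counts match an independent brute-force pileup on a small fixture", {
  sim <- small_sim(seed = 3L)
  aln <- load_alignments(sim$sam, sim$fasta)
  gm <- load_annotation(sim$gtf)
  bt <- build_base_table(aln, assign_and_annotate(aln, gm), sim$fasta)

  for (cfg in list(list(mask = NULL, trim5 = 0L, trim3 = 0L),
                   list(mask = sim$truth$snps$pos, trim5 = 3L, trim3 = 2L))) {
    mine <- read_conversion_counts(filter_base_table(
      bt,
      mask = if (is.null(cfg$mask)) NULL else
        tibble::tibble(chrom = "chrT", pos = cfg$mask),
      trim5 = cfg$trim5, trim3 = cfg$trim3, q_floor = 0L))
    oracle <- oracle_pileup(sim$sam, sim$ref$genome, sim$ref$genes,
                            mask = cfg$mask, trim5 = cfg$trim5,
                            trim3 = cfg$trim3)
    j <- dplyr::full_join(mine, oracle, by = c("read_id", "gene_id"),
                          suffix = c("", "_oracle"))
    expect_true(all(!is.na(j$n_T) & !is.na(j$n_T_oracle)))
    expect_equal(j$n_T, j$n_T_oracle)
    expect_equal(j$k, j$k_oracle)
  }
})
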