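test_that("reference generation is deterministic and structurally correct", {
  cfg <- sim_config(n_genes = 5L, reads_per_gene = 10L, seed = 2L)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  r1 <- simulate_reference(cfg, dir = d1)
  r2 <- simulate_reference(cfg, dir = d2)
  expect_identical(readLines(r1$fasta), readLines(r2$fasta))

  gm <- load_annotation(r1$gtf)
  expect_equal(nrow(gm$genes), 5L)
  # two exons per transcript -> exactly one intron per gene
  expect_equal(nrow(gm$introns), 5L)
  expect_true(all(gm$introns$end - gm$introns$start == cfg$intron_length))
})

test_that("reads are conversion-free when every conversion source is off, saturated when p_new = 1", {
  dir <- withr::local_tempdir()
  clean <- simulate_slam(
    sim_config(n_genes = 2L, reads_per_gene = 20L, read_length = 40L,
               exon_length = 80L, pi = 0, p_new = 0.5, p_old = 0,
               snp_n = 0L, artifact_len5 = 0L, artifact_rate = 0,
               base_error_rate = 0, seed = 3L),
    out_dir = file.path(dir, "clean"))
  oc <- oracle_pileup(clean$sam, clean$ref$genome, clean$ref$genes)
  expect_true(all(oc$k == 0L))
  expect_true(all(clean$truth$reads$conv_pos == ""))

  sat <- simulate_slam(
    sim_config(n_genes = 2L, reads_per_gene = 20L, read_length = 40L,
               exon_length = 80L, pi = 1, p_new = 1, p_old = 0,
               snp_n = 0L, artifact_len5 = 0L, artifact_rate = 0,
               base_error_rate = 0, seed = 3L),
    out_dir = file.path(dir, "sat"))
  os <- oracle_pileup(sat$sam, sat$ref$genome, sat$ref$genes)
  expect_true(all(os$k == os$n_T))
  expect_true(all(os$n_T > 0L))
})

test_that("total conversions match the analytic mixture expectation", {
  sim <- simulate_slam(
    sim_config(n_genes = 1L, reads_per_gene = 500L, read_length = 80L,
               exon_length = 300L, pi = 0.4, p_new = 0.05, p_old = 0.001,
               snp_n = 0L, artifact_len5 = 0L, artifact_rate = 0,
               base_error_rate = 0, seed = 13L),
    out_dir = withr::local_tempdir())
  oc <- oracle_pileup(sim$sam, sim$ref$genome, sim$ref$genes)
  n_tot <- sum(oc$n_T)
  rate <- 0.4 * 0.05 + 0.6 * 0.001
  expected <- n_tot * rate
  sd3 <- 3 * sqrt(n_tot * rate * (1 - rate))
  expect_lt(abs(sum(oc$k) - expected), sd3)
})

test_that("ground-truth conversion positions replay to the emitted sequences exactly", {
  sim <- simulate_slam(
    sim_config(n_genes = 3L, reads_per_gene = 15L, read_length = 40L,
               exon_length = 80L, snp_n = 5L, base_error_rate = 0, seed = 9L),
    out_dir = withr::local_tempdir())
  sam <- readLines(sim$sam)
  sam <- sam[!startsWith(sam, "@")]
  recs <- strsplit(sam, "\t", fixed = TRUE)
  genome <- sim$ref$genome
  strand_of <- stats::setNames(sim$ref$genes$strand, sim$ref$genes$gene_id)
  truth <- sim$truth$reads
  for (r in recs) {
    tr <- truth[truth$read_id == r[1], ]
    pos <- as.integer(r[4]) - 1L
    L <- nchar(r[10])
    ref_win <- substr(genome, pos + 1L, pos + L)
    expected <- strsplit(ref_win, "")[[1]]
    if (nzchar(tr$conv_pos)) {
      cp <- as.integer(strsplit(tr$conv_pos, ",")[[1]])
      off <- cp - pos
      expected[off + 1L] <- if (strand_of[[tr$gene_id]] == "+") "C" else "G"
    }
    expect_equal(paste(expected, collapse = ""), r[10])
  }
})

test_that("identical seeds give byte-identical simulation outputs", {
  cfg <- sim_config(n_genes = 2L, reads_per_gene = 30L, read_length = 40L,
                    exon_length = 80L, seed = 4L)
  s1 <- simulate_slam(cfg, out_dir = withr::local_tempdir())
  s2 <- simulate_slam(cfg, out_dir = withr::local_tempdir())
  expect_identical(readLines(s1$sam), readLines(s2$sam))
  expect_identical(readLines(s1$truth_paths$reads),
                   readLines(s2$truth_paths$reads))
})

test_that("paired mode emits overlapping proper pairs that quantify like single-end data", {
  sim <- simulate_slam(
    sim_config(n_genes = 2L, reads_per_gene = 40L, read_length = 40L,
               exon_length = 120L, pi = c(0.2, 0.8), snp_n = 0L,
               artifact_len5 = 0L, artifact_rate = 0, base_error_rate = 0,
               paired = TRUE, seed = 6L),
    out_dir = withr::local_tempdir())
  aln <- load_alignments(sim$sam, sim$fasta)
  expect_true(all(aln$is_paired))
  expect_equal(nrow(aln), 2L * 2L * 40L)
  gm <- load_annotation(sim$gtf)
  bt <- build_base_table(aln, assign_and_annotate(aln, gm), sim$fasta)
  f <- filter_base_table(bt, q_floor = 0L)
  # both mates of each fragment are assigned, and overlap positions dedupe:
  # fragment coverage equals fragment length, not 2 x read length
  cov <- f |> dplyr::distinct(read_id, gpos) |> dplyr::count(read_id)
  expect_true(all(cov$n == 64L))  # fragment length 1.6 x 40
})
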