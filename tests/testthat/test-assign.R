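# A compact two-gene layout exercised by most assignment tests:
#   g1: exons [0,100) + [200,300) on '+', g2: exon [250,400) on '+'
#   (g1 and g2 overlap on [250,300))
assign_fixture <- function(dir) {
  seqs <- list(c1 = strrep("TTAAGGCCTT", 60))
  exons <- tibble::tibble(
    gene_id = c("g1", "g1", "g2"), transcript_id = c("t1", "t1", "t2"),
    chrom = "c1", start = c(0L, 200L, 250L), end = c(100L, 300L, 400L),
    strand = "+")
  list(fa = write_fixture_fasta(seqs, dir),
       gm = load_annotation(write_fixture_gtf(exons, dir)),
       seq = seqs$c1)
}

test_that("default mode: sense exonic reads assign with weight 1, antisense and multi-gene do not count", {
  dir <- withr::local_tempdir()
  fx <- assign_fixture(dir)
  reads <- tibble::tibble(
    qname = c("in_exon", "antisense", "two_genes", "intergenic"),
    flag = c(0L, 16L, 0L, 0L),
    chrom = "c1", pos = c(10L, 10L, 260L, 120L), cigar = "20M",
    seq = substring(fx$seq, c(11, 11, 261, 121), c(30, 30, 280, 140)),
    qual = strrep("I", 20))
  aln <- load_alignments(write_fixture_sam(reads, c(c1 = 600L), dir), fx$fa)
  a <- assign_reads(aln, fx$gm, mode = "default")

  expect_equal(a$category[a$read_id == "in_exon"], "exonic")
  expect_equal(a$weight[a$read_id == "in_exon"], 1)
  expect_equal(a$category[a$read_id == "antisense"], "unassigned")
  expect_setequal(a$category[a$read_id == "two_genes"],
                  rep("ambiguous", 2))
  expect_equal(sum(a$weight[a$read_id == "two_genes"]), 0)
  expect_equal(a$category[a$read_id == "intergenic"], "unassigned")
})

test_that("compat weighting: read over 2 genes with 2 reported alignments gets 1/(2*2) per gene", {
  dir <- withr::local_tempdir()
  fx <- assign_fixture(dir)
  reads <- tibble::tibble(
    qname = "multi", flag = 0L, chrom = "c1", pos = 260L, cigar = "20M",
    seq = substring(fx$seq, 261, 280), qual = strrep("I", 20), nh = 2L)
  aln <- load_alignments(write_fixture_sam(reads, c(c1 = 600L), dir), fx$fa)
  a <- assign_reads(aln, fx$gm, mode = "compat")
  expect_equal(nrow(a), 2L)
  expect_setequal(a$gene_id, c("g1", "g2"))
  expect_equal(a$weight, c(0.25, 0.25))
  # total assigned weight equals 1 / n_alignments
  expect_equal(sum(a$weight), 1 / 2)
})

test_that("compat intronic and lenient acceptance extend the default rules", {
  dir <- withr::local_tempdir()
  fx <- assign_fixture(dir)
  reads <- tibble::tibble(
    qname = c("intronic", "half_in"),
    flag = 0L, chrom = "c1",
    pos = c(120L, 90L),               # intron g1 = [100,200)
    cigar = "20M",
    seq = substring(fx$seq, c(121, 91), c(140, 110)),
    qual = strrep("I", 20))
  aln <- load_alignments(write_fixture_sam(reads, c(c1 = 600L), dir), fx$fa)

  a_def <- assign_reads(aln, fx$gm, mode = "default")
  expect_true(all(a_def$category %in% "unassigned"))

  a_cmp <- assign_reads(aln, fx$gm, mode = "compat")
  expect_equal(a_cmp$category[a_cmp$read_id == "intronic"], "intronic")
  expect_equal(a_cmp$gene_id[a_cmp$read_id == "intronic"], "g1")
  # 10 of 20 bases in the exon: exactly the 50% lenient floor
  expect_equal(a_cmp$category[a_cmp$read_id == "half_in"], "exonic")

  # individually disabling behaviors restores default results
  a_off <- assign_reads(aln, fx$gm, mode = "compat",
                        compat_intronic = "off", compat_lenient = "off")
  expect_true(all(a_off$category %in% "unassigned"))
})

test_that("splice junction concordance gates lenient acceptance of spliced reads", {
  dir <- withr::local_tempdir()
  fx <- assign_fixture(dir)
  # both reads overlap g1 exons well above 50% but are not fully contained;
  # only the one whose junction matches the annotation is accepted
  reads <- tibble::tibble(
    qname = c("good_junc", "bad_junc"),
    flag = 0L, chrom = "c1",
    pos = c(90L, 90L),
    cigar = c("10M100N105M",          # junction [100,200) = annotated
              "10M95N20M"),           # junction [100,195): not annotated
    seq = c(paste0(substring(fx$seq, 91, 100), substring(fx$seq, 201, 305)),
            paste0(substring(fx$seq, 91, 100), substring(fx$seq, 196, 215))),
    qual = c(strrep("I", 115), strrep("I", 30)))
  aln <- load_alignments(write_fixture_sam(reads, c(c1 = 600L), dir), fx$fa)
  a <- assign_reads(aln, fx$gm, mode = "compat")
  expect_equal(a$category[a$read_id == "good_junc"], "exonic")
  expect_equal(a$gene_id[a$read_id == "good_junc"], "g1")
  expect_equal(a$category[a$read_id == "bad_junc"], "unassigned")
})

test_that("reads accepted under default rules are also accepted under compat (lenient is a superset)", {
  sim <- small_sim(seed = 7L)
  aln <- load_alignments(sim$sam, sim$fasta)
  gm <- load_annotation(sim$gtf)
  a_def <- assign_reads(aln, gm, mode = "default")
  a_cmp <- assign_reads(aln, gm, mode = "compat")
  accepted_def <- a_def[a_def$category == "exonic" & a_def$weight > 0, ]
  joined <- dplyr::inner_join(
    accepted_def[, c("read_id", "gene_id")],
    a_cmp[a_cmp$category %in% c("exonic", "intronic"),
          c("read_id", "gene_id")],
    by = c("read_id", "gene_id"))
  expect_equal(nrow(joined), nrow(accepted_def))
  # and per-read total weight never exceeds 1 in either mode
  for (a in list(a_def, a_cmp)) {
    totals <- tapply(a$weight, a$read_id, sum)
    expect_true(all(totals <= 1 + 1e-12))
  }
})
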