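# Shared fixture builders and independent oracles. Everything here is
# deliberately naive/spelled-out so it can serve as a cross-check on the
# vectorised implementations in the package.

write_fixture_fasta <- function(seqs, dir = withr::local_tempdir(.local_envir = parent.frame())) {
  path <- file.path(dir, "ref.fa")
  writeLines(unlist(lapply(names(seqs), function(n) c(paste0(">", n), seqs[[n]]))),
             path)
  path
}

# exons: tibble(gene_id, transcript_id, chrom, start, end, strand) 0-based
write_fixture_gtf <- function(exons, dir) {
  path <- file.path(dir, "genes.gtf")
  writeLines(sprintf(
    '%s\ttest\texon\t%d\t%d\t.\t%s\t.\tgene_id "%s"; transcript_id "%s";',
    exons$chrom, exons$start + 1L, exons$end, exons$strand,
    exons$gene_id, exons$transcript_id), path)
  path
}

# reads: tibble(qname, flag, chrom, pos (0-based), cigar, seq, qual, nh)
write_fixture_sam <- function(reads, seqlens, dir, sorted = TRUE) {
  path <- file.path(dir, "reads.sam")
  if (sorted) reads <- reads[order(reads$chrom, reads$pos), ]
  hdr <- c("@HD\tVN:1.6\tSO:coordinate",
           sprintf("@SQ\tSN:%s\tLN:%d", names(seqlens), unname(seqlens)))
  rec <- sprintf("%s\t%d\t%s\t%d\t255\t%s\t*\t0\t0\t%s\t%s\tNH:i:%d",
                 reads$qname, reads$flag, reads$chrom, reads$pos + 1L,
                 reads$cigar, reads$seq, reads$qual, if ("nh" %in% names(reads)) reads$nh else 1L)
  writeLines(c(hdr, rec), path)
  path
}

default_qual <- function(seq) strrep("I", nchar(seq))

# --- independent pileup oracle -------------------------------------------
# Counts per-read (n_T, k) by walking the SAM text and the genome string
# base by base; supports only full-match single-block reads (what the hand
# fixtures and the simulator emit). Returns tibble(read_id, n_T, k).
oracle_pileup <- function(sam_path, genome, gene_ranges, mask = NULL,
                          trim5 = 0L, trim3 = 0L, q_floor = 0L) {
  lines <- readLines(sam_path)
  lines <- lines[!startsWith(lines, "@")]
  out <- list()
  for (ln in lines) {
    f <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    flag <- as.integer(f[2])
    if (bitwAnd(flag, 4L) != 0L) next
    pos <- as.integer(f[4]) - 1L
    seq <- f[10]; qual <- f[11]
    L <- nchar(seq)
    minus_aln <- bitwAnd(flag, 16L) != 0L
    # which gene contains this read?
    g <- gene_ranges[gene_ranges$start <= pos & gene_ranges$end >= pos + L, ]
    if (nrow(g) != 1L) next
    n_T <- 0L; k <- 0L
    for (i in seq_len(L)) {
      gpos <- pos + i - 1L
      rp <- if (minus_aln) L - i else i - 1L
      if (rp < trim5 || rp >= L - trim3) next
      if (!is.null(mask) && gpos %in% mask) next
      q <- as.integer(charToRaw(substr(qual, i, i))) - 33L
      if (q < q_floor) next
      rb <- substr(genome, gpos + 1L, gpos + 1L)
      ob <- substr(seq, i, i)
      if (g$strand == "-") {
        rb <- chartr("ACGT", "TGCA", rb); ob <- chartr("ACGT", "TGCA", ob)
      }
      if (rb == "T") {
        n_T <- n_T + 1L
        if (ob == "C") k <- k + 1L
      }
    }
    out[[length(out) + 1L]] <- tibble::tibble(read_id = f[1], gene_id = g$gene_id,
                                              n_T = n_T, k = k)
  }
  dplyr::bind_rows(out)
}

# --- piecewise-fit oracle -------------------------------------------------
# Naive enumeration with stats::lm over every breakpoint placement; must
# match the package's search exactly on short curves.
oracle_pwl_best <- function(x, y, m) {
  cand <- x[seq(3L, length(x) - 2L)]
  n_bp <- m - 1L
  combos <- utils::combn(cand, n_bp)
  if (n_bp > 1L) {
    keep <- apply(combos, 2, function(b) all(diff(b) >= 2))
    combos <- combos[, keep, drop = FALSE]
  }
  best <- Inf; best_bp <- NULL
  for (j in seq_len(ncol(combos))) {
    bp <- combos[, j]
    d <- data.frame(x = x, y = y)
    for (i in seq_along(bp)) d[[paste0("h", i)]] <- pmax(x - bp[i], 0)
    fit <- stats::lm(y ~ ., data = d)
    rss <- sum(stats::residuals(fit)^2)
    if (rss < best - 1e-15) { best <- rss; best_bp <- bp }
  }
  list(rss = best, breakpoints = best_bp)
}

# --- exact-likelihood grid oracle for the gene EM -------------------------
oracle_grid_pi <- function(k, n, w, p_new, p_old, step = 1e-3) {
  grid <- seq(0, 1, by = step)
  lf1 <- dbinom(k, n, p_new)
  lf0 <- dbinom(k, n, p_old)
  ll <- vapply(grid, function(p) sum(w * log(p * lf1 + (1 - p) * lf0)), 0)
  grid[which.max(ll)]
}

# --- abstract chunked-profile generator (planted end artifacts) -----------
make_artifact_profile <- function(t5, t3, seed, L = 50L, reads = 2000L,
                                  chunks = 10L, base = 0.02, art = 0.10) {
  set.seed(seed)
  purrr::map_dfr(0:(chunks - 1L), function(c) {
    nr <- reads / chunks
    tibble::tibble(chunk = c, rpos = 0:(L - 1L)) |>
      dplyr::mutate(t_coverage = stats::rbinom(L, nr, 0.25),
                    rate = ifelse(rpos < t5 | rpos >= L - t3, art, base),
                    tc_count = stats::rbinom(L, t_coverage, rate)) |>
      dplyr::select(-rate)
  })
}

# --- site-table generator (error sites + planted het SNPs) ----------------
make_snp_sites <- function(n_error = 5000L, n_snp = 60L, coverage = 50L,
                           p_error = 0.005, p_snp = 0.5, seed = 1L) {
  set.seed(seed)
  tibble::tibble(
    chrom = "c1",
    gpos = seq_len(n_error + n_snp) - 1L,
    coverage = coverage,
    tc_count = c(stats::rbinom(n_error, coverage, p_error),
                 stats::rbinom(n_snp, coverage, p_snp)),
    ta_count = 0L, tg_count = 0L,
    is_snp = rep(c(FALSE, TRUE), c(n_error, n_snp))
  )
}

# --- cached flagship simulation + pipeline run ----------------------------
# One 20-gene benchmark (seed 13) shared across acceptance tests.
.flagship_cache <- new.env(parent = emptyenv())

flagship_sim <- function() {
  if (is.null(.flagship_cache$sim)) {
    dir <- file.path(tempdir(), "slamkit-flagship-sim")
    .flagship_cache$sim <- simulate_slam(sim_config(seed = 13L), out_dir = dir)
  }
  .flagship_cache$sim
}

flagship_run <- function() {
  if (is.null(.flagship_cache$run)) {
    sim <- flagship_sim()
    .flagship_cache$run <- suppressMessages(run_quant(
      bam = sim$sam, fasta = sim$fasta, gtf = sim$gtf,
      out_prefix = file.path(tempdir(), "slamkit-flagship-run", "out"),
      qc_report = TRUE, seed = 13L))
  }
  .flagship_cache$run
}

# small 2-gene simulation reused by counting/pipeline tests
small_sim <- function(seed = 5L, ...) {
  simulate_slam(
    sim_config(n_genes = 2L, reads_per_gene = 25L, read_length = 40L,
               exon_length = 80L, snp_n = 4L, artifact_len5 = 0L,
               artifact_rate = 0, base_error_rate = 0, seed = seed, ...),
    out_dir = withr::local_tempdir(.local_envir = parent.frame()))
}
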