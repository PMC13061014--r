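#' Simulation configuration
#'
#' Defines the synthetic SLAM-seq benchmark: a toy multi-gene genome with
#' exon/intron structure, reads drawn from per-gene new/old fractions with
#' conversion rate `p_new` (labeled) and background `p_old` (pre-existing),
#' planted genomic T>C SNPs at heterozygous/homozygous fractions, elevated
#' conversion artifacts in windows at the read ends, and uniform base-call
#' errors. Defaults are the package's benchmark conditions: 20 genes, 500
#' single-end reads per gene of length 80 (about 20 reference-T positions per
#' read at uniform base composition), `p_new = 0.05`, `p_old = 0.001`,
#' per-gene NTR drawn uniform(0, 1), 30 planted SNPs (half heterozygous),
#' a 5-position 5' artifact window at rate 0.15, and base-error rate 0.001.
#'
#' @param n_genes Number of genes.
#' @param exons_per_gene Exons per transcript (one transcript per gene).
#' @param exon_length,intron_length,intergenic Geometry in bp.
#' @param reads_per_gene Reads simulated per gene.
#' @param read_length Read length L.
#' @param p_new,p_old Conversion rates in new/old RNA.
#' @param pi Per-gene NTR values (recycled), or `NULL` to draw uniform(0,1).
#' @param snp_n Number of planted SNP sites (at sense-T positions in exons).
#' @param snp_het_prop Proportion of SNPs that are heterozygous (fraction
#'   0.5); the rest are homozygous (fraction 1.0).
#' @param artifact_len5,artifact_len3 Artifact window lengths at the read
#'   5'/3' ends (must sum to < L/2).
#' @param artifact_rate Conversion probability inside artifact windows (all
#'   reads).
#' @param base_error_rate Per-base probability of a uniform sequencing error.
#' @param paired Emit overlapping paired-end fragments instead of single-end
#'   reads.
#' @param fragment_length Fragment length for paired mode (default 1.6 L).
#' @param seed Integer seed; fixed seed gives byte-identical outputs.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_genes = 20L, exons_per_gene = 2L,
                       exon_length = 300L, intron_length = 150L,
                       intergenic = 200L,
                       reads_per_gene = 500L, read_length = 80L,
                       p_new = 0.05, p_old = 0.001, pi = NULL,
                       snp_n = 30L, snp_het_prop = 0.5,
                       artifact_len5 = 5L, artifact_len3 = 0L,
                       artifact_rate = 0.15,
                       base_error_rate = 0.001,
                       paired = FALSE, fragment_length = NULL,
                       seed = 1L) {
  stopifnot(p_new > p_old, exon_length >= read_length,
            artifact_len5 + artifact_len3 < read_length / 2)
  if (is.null(fragment_length)) fragment_length <- round(1.6 * read_length)
  structure(list(
    n_genes = as.integer(n_genes), exons_per_gene = as.integer(exons_per_gene),
    exon_length = as.integer(exon_length),
    intron_length = as.integer(intron_length),
    intergenic = as.integer(intergenic),
    reads_per_gene = as.integer(reads_per_gene),
    read_length = as.integer(read_length),
    p_new = p_new, p_old = p_old, pi = pi,
    snp_n = as.integer(snp_n), snp_het_prop = snp_het_prop,
    artifact_len5 = as.integer(artifact_len5),
    artifact_len3 = as.integer(artifact_len3),
    artifact_rate = artifact_rate,
    base_error_rate = base_error_rate,
    paired = paired, fragment_length = as.integer(fragment_length),
    seed = as.integer(seed)), class = "sim_config")
}

#' Simulate the reference genome and annotation
#'
#' One chromosome carries all genes end to end, each gene a single transcript
#' of `exons_per_gene` exons with alternating strand (+, -, ...). Bases are
#' uniform over A/C/G/T so reference-T density is about 25% on either strand.
#'
#' @param cfg A [sim_config()].
#' @param dir Output directory for `genome.fa` and `genes.gtf` (created).
#' @return List: `fasta`, `gtf` (paths), `genome` (character string),
#'   `genes` (tibble with coordinates and strand), `exons` (tibble),
#'   `chrom` name.
#' @export
simulate_reference <- function(cfg, dir = tempfile("slamsim")) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(cfg$seed)
  chrom <- "chrT"
  gene_span <- cfg$exons_per_gene * cfg$exon_length +
    (cfg$exons_per_gene - 1L) * cfg$intron_length
  starts <- cfg$intergenic +
    (seq_len(cfg$n_genes) - 1L) * (gene_span + cfg$intergenic)
  glen <- utils::tail(starts, 1) + gene_span + cfg$intergenic
  genome <- paste(sample(c("A", "C", "G", "T"), glen, replace = TRUE),
                  collapse = "")
  genes <- tibble(
    gene_id = sprintf("G%03d", seq_len(cfg$n_genes)),
    chrom = chrom,
    strand = rep_len(c("+", "-"), cfg$n_genes),
    start = starts, end = starts + gene_span
  )
  exons <- purrr::pmap_dfr(genes, function(gene_id, chrom, strand, start, end) {
    es <- start + (seq_len(cfg$exons_per_gene) - 1L) *
      (cfg$exon_length + cfg$intron_length)
    tibble(gene_id = gene_id, chrom = chrom, strand = strand,
           start = es, end = es + cfg$exon_length,
           exon_number = seq_along(es))
  })

  fasta <- file.path(dir, "genome.fa")
  writeLines(c(paste0(">", chrom), genome), fasta)
  gtf <- file.path(dir, "genes.gtf")
  gtf_lines <- sprintf(
    '%s\tslamkit_sim\texon\t%d\t%d\t.\t%s\t.\tgene_id "%s"; transcript_id "%s.t1"; gene_name "%s"; exon_number "%d";',
    exons$chrom, exons$start + 1L, exons$end, exons$strand,
    exons$gene_id, exons$gene_id, exons$gene_id, exons$exon_number)
  writeLines(gtf_lines, gtf)
  list(fasta = fasta, gtf = gtf, genome = genome, genes = genes,
       exons = exons, chrom = chrom)
}

#' Simulate SLAM-seq reads with ground truth
#'
#' Each read draws its origin from Bernoulli(pi_gene): sense-strand
#' reference-T positions convert to C at `p_new` (new RNA) or `p_old` (old).
#' Planted SNP sites convert at their planted fraction regardless of origin
#' (combined independently with the origin rate). Inside artifact windows at
#' the read ends the conversion probability is `artifact_rate` for all reads.
#' Uniform base errors are applied afterwards at non-converted positions.
#' Alignments are emitted as simple full-match coordinate-sorted SAM records
#' (the generator emulates requantification of already-aligned data).
#'
#' @param cfg A [sim_config()].
#' @param ref Reference from [simulate_reference()].
#' @param dir Output directory for `reads.sam` and ground-truth TSVs.
#' @return List: `sam` (path), `truth` (list of tibbles `genes`, `snps`,
#'   `reads`), and `paths` of the written ground-truth files.
#' @export
simulate_reads <- function(cfg, ref, dir = dirname(ref$fasta)) {
  set.seed(cfg$seed + 1L)
  L <- cfg$read_length
  genome_chars <- strsplit(ref$genome, "", fixed = TRUE)[[1]]

  pi_gene <- if (is.null(cfg$pi)) runif(cfg$n_genes) else
    rep_len(cfg$pi, cfg$n_genes)
  genes <- ref$genes %>% mutate(true_pi = pi_gene)

  # plant SNPs at sense-T exonic positions
  exon_pos <- unlist(purrr::pmap(ref$exons, function(start, end, strand, ...) {
    p <- start:(end - 1L)
    sense_t <- if (strand == "+") genome_chars[p + 1L] == "T" else
      genome_chars[p + 1L] == "A"
    p[sense_t]
  }), use.names = FALSE)
  exon_pos <- unique(exon_pos)
  snp_n <- min(cfg$snp_n, length(exon_pos))
  snp_pos <- sort(sample(exon_pos, snp_n))
  n_het <- round(snp_n * cfg$snp_het_prop)
  snp_frac <- rep(1.0, snp_n)
  if (snp_n > 0L && n_het > 0L) snp_frac[seq_len(n_het)] <- 0.5
  snps <- tibble(chrom = ref$chrom, pos = snp_pos, fraction = snp_frac)
  snp_lookup <- setNames(snp_frac, as.character(snp_pos))

  # fragment layout: one row per read (or mate)
  n_frag <- cfg$n_genes * cfg$reads_per_gene
  gi <- rep(seq_len(cfg$n_genes), each = cfg$reads_per_gene)
  frag_len <- if (cfg$paired) cfg$fragment_length else L
  # a fragment sits inside one exon (simple unspliced model)
  ex_by_gene <- split(ref$exons, ref$exons$gene_id)
  exon_choice <- integer(n_frag); frag_start <- integer(n_frag)
  for (g in seq_len(cfg$n_genes)) {
    idx <- which(gi == g)
    ex <- ex_by_gene[[genes$gene_id[g]]]
    fit <- which(ex$end - ex$start >= frag_len)
    ec <- fit[sample.int(length(fit), length(idx), replace = TRUE)]
    exon_choice[idx] <- ec
    frag_start[idx] <- ex$start[ec] +
      floor(runif(length(idx)) * (ex$end[ec] - ex$start[ec] - frag_len + 1L))
  }
  origin_new <- runif(n_frag) < genes$true_pi[gi]
  gene_strand <- genes$strand[gi]

  # molecule-level conversions over the fragment footprint
  fl <- frag_len
  gpos <- rep(frag_start, each = fl) + rep(0:(fl - 1L), times = n_frag)
  fidx <- rep(seq_len(n_frag), each = fl)
  refb <- genome_chars[gpos + 1L]
  strand_m <- gene_strand[fidx]
  sense_t <- (strand_m == "+" & refb == "T") | (strand_m == "-" & refb == "A")
  p_origin <- if_else(origin_new[fidx], cfg$p_new, cfg$p_old)
  f_snp <- snp_lookup[as.character(gpos)]
  f_snp[is.na(f_snp)] <- 0
  p_mol <- 1 - (1 - p_origin) * (1 - f_snp)
  mol_conv <- sense_t & (runif(length(gpos)) < p_mol)

  # emit mates (single-end: one mate per fragment)
  mates <- if (cfg$paired) {
    bind_rows(
      tibble(fidx = seq_len(n_frag), mate = 1L,
             start = frag_start,
             aln_strand = if_else(gene_strand == "+", "+", "-")),
      tibble(fidx = seq_len(n_frag), mate = 2L,
             start = frag_start + fl - L,
             aln_strand = if_else(gene_strand == "+", "-", "+"))
    )
  } else {
    tibble(fidx = seq_len(n_frag), mate = 0L, start = frag_start,
           aln_strand = gene_strand)
  }
  # for paired mode on a minus-strand gene the first sequenced mate is the
  # rightmost one; swap so mate 1 is always the 5'-most in transcript terms
  if (cfg$paired) {
    minus <- gene_strand[mates$fidx] == "-"
    mates$mate[minus] <- 3L - mates$mate[minus]
  }

  n_reads <- nrow(mates)
  rg <- rep(mates$start, each = L) + rep(0:(L - 1L), times = n_reads)
  ridx <- rep(seq_len(n_reads), each = L)
  rref <- genome_chars[rg + 1L]
  r_strand <- gene_strand[mates$fidx[ridx]]
  r_sense_t <- (r_strand == "+" & rref == "T") | (r_strand == "-" & rref == "A")
  # read position from the mate's 5' end as sequenced
  aln_minus <- mates$aln_strand[ridx] == "-"
  off <- rg - rep(mates$start, each = L)
  rpos <- ifelse(aln_minus, L - 1L - off, off)

  # inherit molecule conversions
  key_m <- paste0(fidx, ":", gpos)
  conv_set <- key_m[mol_conv]
  key_r <- paste0(mates$fidx[ridx], ":", rg)
  conv <- key_r %in% conv_set

  # artifact windows override the conversion process at sense-T positions
  in_art <- (rpos < cfg$artifact_len5) | (rpos >= L - cfg$artifact_len3)
  art_zone <- r_sense_t & in_art
  conv[art_zone] <- runif(sum(art_zone)) < cfg$artifact_rate

  # emitted forward-strand base
  out_base <- rref
  plus_conv <- conv & r_strand == "+"
  minus_conv <- conv & r_strand == "-"
  out_base[plus_conv] <- "C"
  out_base[minus_conv] <- "G"

  # uniform base errors at non-converted positions
  err <- !conv & runif(length(out_base)) < cfg$base_error_rate
  if (any(err)) {
    alt <- matrix(c("C","G","T", "A","G","T", "A","C","T", "A","C","G"),
                  nrow = 3,
                  dimnames = list(NULL, c("A", "C", "G", "T")))
    pick <- sample.int(3L, sum(err), replace = TRUE)
    out_base[err] <- alt[cbind(pick, match(out_base[err], colnames(alt)))]
  }

  seqs <- vapply(split(out_base, ridx), paste, character(1), collapse = "")
  seqs <- seqs[order(as.integer(names(seqs)))]
  qual <- strrep("F", L)  # constant Phred 37

  read_id <- sprintf("r%06d", mates$fidx)
  if (cfg$paired) {
    fwd <- mates$aln_strand == "+"
    first <- mates$mate == 1L
    flag <- 1L + 2L +
      if_else(fwd, 0L, 16L) + if_else(fwd, 32L, 0L) +
      if_else(first, 64L, 128L)
    # the other mate of fragment f sits at the other end of the fragment
    both <- frag_start[mates$fidx]
    pnext <- if_else(mates$start == both, both + fl - L, both) + 1L
    rnext <- "="
  } else {
    flag <- if_else(mates$aln_strand == "+", 0L, 16L)
    pnext <- rep(0L, n_reads)
    rnext <- "*"
  }

  sam <- file.path(dir, "reads.sam")
  ord <- order(mates$start, read_id, mates$mate)
  hdr <- c("@HD\tVN:1.6\tSO:coordinate",
           paste0("@SQ\tSN:", ref$chrom, "\tLN:", nchar(ref$genome)))
  rec <- sprintf("%s\t%d\t%s\t%d\t255\t%dM\t%s\t%d\t%d\t%s\t%s\tNH:i:1",
                 read_id[ord], flag[ord], ref$chrom, mates$start[ord] + 1L,
                 L, rnext, pnext[ord], 0L, seqs[ord], qual)
  writeLines(c(hdr, rec), sam)

  # ground truth: per-read conversion positions (post-artifact, pre-error)
  conv_by_read <- split(rg[conv], ridx[conv])
  conv_str <- character(n_reads)
  conv_str[as.integer(names(conv_by_read))] <-
    vapply(conv_by_read, paste, character(1), collapse = ",")
  reads_truth <- tibble(
    read_id = read_id, mate = mates$mate,
    gene_id = genes$gene_id[gi[mates$fidx]],
    origin = if_else(origin_new[mates$fidx], "new", "old"),
    start = mates$start, aln_strand = mates$aln_strand,
    conv_pos = conv_str
  )
  # the NTR ground truth is the realized per-gene fraction of new reads:
  # the NTR is defined over the reads actually present, not the Bernoulli
  # parameter they were drawn from
  realized <- tibble(gene_id = genes$gene_id[gi],
                     new = origin_new) %>%
    group_by(.data$gene_id) %>%
    summarise(ntr_true = mean(.data$new), .groups = "drop")
  genes <- genes %>% left_join(realized, by = "gene_id") %>%
    mutate(ntr_true = dplyr::coalesce(.data$ntr_true, 0))

  paths <- list(
    genes = file.path(dir, "truth_genes.tsv"),
    snps = file.path(dir, "truth_snps.tsv"),
    reads = file.path(dir, "truth_reads.tsv")
  )
  readr::write_tsv(genes %>% select("gene_id", "strand", "true_pi",
                                    "ntr_true"),
                   paths$genes, progress = FALSE)
  readr::write_tsv(snps, paths$snps, progress = FALSE)
  readr::write_tsv(reads_truth, paths$reads, progress = FALSE)

  list(sam = sam, truth = list(genes = genes, snps = snps,
                               reads = reads_truth),
       paths = paths)
}

#' Run the full synthetic benchmark generator
#'
#' Writes FASTA, GTF, coordinate-sorted SAM, ground-truth TSVs and a JSON
#' echo of the configuration into one directory.
#'
#' @param cfg A [sim_config()].
#' @param out_dir Output directory (created).
#' @return List with all paths, the ground-truth tibbles and the reference.
#' @export
simulate_slam <- function(cfg, out_dir = tempfile("slamsim")) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  ref <- simulate_reference(cfg, dir = out_dir)
  reads <- simulate_reads(cfg, ref, dir = out_dir)
  cfg_path <- file.path(out_dir, "sim_config.json")
  jsonlite::write_json(unclass(cfg), cfg_path, auto_unbox = TRUE,
                       pretty = TRUE, null = "null")
  list(dir = out_dir, fasta = ref$fasta, gtf = ref$gtf, sam = reads$sam,
       config = cfg_path, truth = reads$truth, truth_paths = reads$paths,
       ref = ref)
}
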