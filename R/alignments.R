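#' Load aligned reads from a BAM/SAM file
#'
#' Reads mapped alignments into a tidy one-row-per-alignment table. Unmapped
#' records are skipped. The number of reported alignments per read
#' (`n_alignments`) is taken from the `NH` tag when present, else 1. Input
#' must be coordinate-sorted; sortedness is checked on the fly and every
#' alignment chromosome must be present in the reference FASTA.
#'
#' @param bam_path Path to a coordinate-sorted BAM (or SAM, converted on the
#'   fly) file.
#' @param fasta_path Path to the reference genome FASTA (indexed on demand).
#' @return A tibble with one row per mapped alignment: `read_id`, `chrom`,
#'   `strand`, `pos` (0-based leftmost reference position), `cigar`, `seq`,
#'   `qual` (Phred string), `flag`, `mate` (0 unpaired, 1/2 for mates),
#'   `is_paired`, `n_alignments`, `is_spliced`, `read_index` (input order).
#' @export
load_alignments <- function(bam_path, fasta_path) {
  if (!file.exists(bam_path)) abort(paste0("alignment file not found: ", bam_path))
  if (grepl("\\.sam$", bam_path, ignore.case = TRUE)) {
    dest <- tempfile(fileext = "")
    bam_path <- Rsamtools::asBam(bam_path, destination = dest,
                                 overwrite = TRUE, indexDestination = TRUE)
  }
  fa <- open_fasta(fasta_path)
  fa_chroms <- as.character(GenomeInfoDb::seqnames(Rsamtools::scanFaIndex(fa)))

  param <- Rsamtools::ScanBamParam(
    what = c("qname", "flag", "rname", "strand", "pos", "cigar", "seq", "qual"),
    tag = "NH",
    flag = Rsamtools::scanBamFlag(isUnmappedQuery = FALSE)
  )
  res <- Rsamtools::scanBam(bam_path, param = param)[[1]]
  n <- length(res$qname)
  if (n == 0L) {
    return(tibble(read_id = character(), chrom = character(),
                  strand = character(), pos = integer(), cigar = character(),
                  seq = character(), qual = character(), flag = integer(),
                  mate = integer(), is_paired = logical(),
                  n_alignments = integer(), is_spliced = logical(),
                  read_index = integer()))
  }
  chrom <- as.character(res$rname)
  missing_chrom <- setdiff(unique(chrom), fa_chroms)
  if (length(missing_chrom) > 0L) {
    abort(paste0("alignment chromosome not present in reference FASTA: ",
                 paste(missing_chrom, collapse = ", ")))
  }
  # sortedness check: positions nondecreasing within each chromosome block
  rle_ch <- rle(chrom)
  off <- 0L
  for (j in seq_along(rle_ch$lengths)) {
    p <- res$pos[(off + 1L):(off + rle_ch$lengths[j])]
    if (is.unsorted(p)) {
      abort(paste0("alignments are not coordinate-sorted (chromosome ",
                   rle_ch$values[j], "); sort the input first"))
    }
    off <- off + rle_ch$lengths[j]
  }
  if (anyDuplicated(rle_ch$values)) {
    abort("alignments are not coordinate-sorted (interleaved chromosomes)")
  }

  flag <- res$flag
  nh <- res$tag$NH %enull% rep(1L, n)
  nh[is.na(nh)] <- 1L
  tibble(
    read_id = res$qname,
    chrom = chrom,
    strand = as.character(res$strand),
    pos = res$pos - 1L,
    cigar = res$cigar,
    seq = as.character(res$seq),
    qual = as.character(res$qual),
    flag = flag,
    mate = if_else(bitwAnd(flag, 1L) == 0L, 0L,
                   if_else(bitwAnd(flag, 64L) != 0L, 1L, 2L)),
    is_paired = bitwAnd(flag, 1L) != 0L,
    n_alignments = as.integer(nh),
    is_spliced = grepl("N", res$cigar, fixed = TRUE),
    read_index = seq_len(n)
  )
}

open_fasta <- function(fasta_path) {
  if (!file.exists(fasta_path)) {
    abort(paste0("FASTA file not found: ", fasta_path))
  }
  if (!file.exists(paste0(fasta_path, ".fai"))) {
    Rsamtools::indexFa(fasta_path)
  }
  Rsamtools::FaFile(fasta_path)
}

# Matched-block decomposition of alignments: one row per M block with
# reference and query (read) coordinates. Soft clips, insertions and
# deletions are excluded from T accounting by construction.
alignment_blocks <- function(reads) {
  if (nrow(reads) == 0L) {
    return(tibble(row = integer(), ref_start = integer(), ref_end = integer(),
                  q_start = integer(), q_end = integer()))
  }
  rr <- GenomicAlignments::cigarRangesAlongReferenceSpace(
    reads$cigar, ops = "M", pos = reads$pos + 1L)
  qq <- GenomicAlignments::cigarRangesAlongQuerySpace(reads$cigar, ops = "M")
  nb <- S4Vectors::elementNROWS(rr)
  rrf <- unlist(rr, use.names = FALSE)
  qqf <- unlist(qq, use.names = FALSE)
  tibble(
    row = rep(seq_len(nrow(reads)), nb),
    ref_start = BiocGenerics::start(rrf) - 1L,     # 0-based half-open
    ref_end = BiocGenerics::end(rrf),
    q_start = BiocGenerics::start(qqf) - 1L,
    q_end = BiocGenerics::end(qqf)
  )
}

# splice junctions (N gaps) of each alignment, 0-based half-open intron spans
alignment_junctions <- function(reads) {
  if (nrow(reads) == 0L) {
    return(tibble(row = integer(), start = integer(), end = integer()))
  }
  jr <- GenomicAlignments::cigarRangesAlongReferenceSpace(
    reads$cigar, ops = "N", pos = reads$pos + 1L)
  nj <- S4Vectors::elementNROWS(jr)
  jf <- unlist(jr, use.names = FALSE)
  tibble(row = rep(seq_len(nrow(reads)), nj),
         start = BiocGenerics::start(jf) - 1L,
         end = BiocGenerics::end(jf))
}
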