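#' Build the per-base event table for assigned reads
#'
#' Expands every aligned matched base of every assigned read into one row,
#' annotated with its genomic position, read position, reference and read
#' base (alignment strand), base quality and gene context. This long table is
#' the single substrate for conversion counting, the SNP site table and the
#' per-read-position conversion profile, which guarantees that all three see
#' the same position universe.
#'
#' Read positions (`rpos`) are 0-based offsets from the read's 5' end *as
#' sequenced*: for alignments on the minus strand the stored sequence is
#' reference-oriented, so offsets are reversed.
#'
#' @param reads Alignment tibble from [load_alignments()].
#' @param assignments Assignment tibble from [assign_reads()]; only
#'   `exonic`/`intronic` rows with positive weight are expanded.
#' @param fasta_path Reference FASTA path.
#' @return A tibble with columns `read_id`, `row`, `read_index`, `mate`,
#'   `gene_id`, `gene_strand`, `weight`, `category`, `chrom`, `gpos`, `rpos`,
#'   `read_len`, `ref`, `obs`, `qual`, and the derived sense-strand columns
#'   `sense_ref`, `sense_obs`.
#' @export
build_base_table <- function(reads, assignments, fasta_path) {
  fa <- open_fasta(fasta_path)
  use <- assignments %>%
    filter(.data$category %in% c("exonic", "intronic"), .data$weight > 0)
  empty <- tibble(read_id = character(), row = integer(),
                  read_index = integer(), mate = integer(),
                  gene_id = character(), gene_strand = character(),
                  weight = double(), category = character(),
                  chrom = character(), gpos = integer(), rpos = integer(),
                  read_len = integer(), ref = character(), obs = character(),
                  qual = integer(), sense_ref = character(),
                  sense_obs = character())
  if (nrow(use) == 0L) return(empty)

  rows <- sort(unique(use$row))
  sub <- reads[rows, ]
  blocks <- alignment_blocks(sub)
  if (nrow(blocks) == 0L) return(empty)

  # reference bases under each block
  ref_gr <- GenomicRanges::GRanges(
    seqnames = sub$chrom[blocks$row],
    ranges = IRanges::IRanges(blocks$ref_start + 1L, blocks$ref_end))
  ref_seq <- as.character(Rsamtools::scanFa(fa, ref_gr))

  blen <- blocks$ref_end - blocks$ref_start
  idx <- rep(seq_len(nrow(blocks)), blen)
  off <- sequence(blen) - 1L
  orig_row <- rows[blocks$row[idx]]

  read_seq_full <- sub$seq[blocks$row]
  read_qual_full <- sub$qual[blocks$row]

  per_block_read <- substr(read_seq_full, blocks$q_start + 1L, blocks$q_end)
  per_block_qual <- substr(read_qual_full, blocks$q_start + 1L, blocks$q_end)

  obs <- substring(per_block_read[idx], off + 1L, off + 1L)
  qual <- as.integer(charToRaw(paste(per_block_qual, collapse = ""))) - 33L
  ref <- substring(ref_seq[idx], off + 1L, off + 1L)

  q_off_in_read <- blocks$q_start[idx] + off           # offset in stored seq
  read_len <- nchar(sub$seq)[blocks$row[idx]]
  strand_minus <- (sub$strand == "-")[blocks$row[idx]]
  rpos <- ifelse(strand_minus, read_len - 1L - q_off_in_read, q_off_in_read)

  base <- tibble(
    row = orig_row,
    read_index = sub$read_index[blocks$row[idx]],
    read_id = sub$read_id[blocks$row[idx]],
    mate = sub$mate[blocks$row[idx]],
    chrom = sub$chrom[blocks$row[idx]],
    gpos = blocks$ref_start[idx] + off,
    rpos = as.integer(rpos),
    read_len = read_len,
    ref = ref,
    obs = obs,
    qual = qual
  )

  out <- use %>%
    select("row", "gene_id", "weight", "category") %>%
    inner_join(base, by = "row", relationship = "many-to-many")

  gm_strand <- attr(assignments, "gene_strand")
  # gene strand travels with the assignment attr when present, else via join
  if (is.null(gm_strand)) {
    abort("assignments lack gene strand metadata; use assign_and_annotate()")
  }
  out$gene_strand <- unname(gm_strand[out$gene_id])
  out <- out %>%
    mutate(
      sense_ref = if_else(.data$gene_strand == "-",
                          unname(BASE_COMP[.data$ref]), .data$ref),
      sense_obs = if_else(.data$gene_strand == "-",
                          unname(BASE_COMP[.data$obs]), .data$obs)
    )
  out[, c("read_id", "row", "read_index", "mate", "gene_id", "gene_strand",
          "weight", "category", "chrom", "gpos", "rpos", "read_len",
          "ref", "obs", "qual", "sense_ref", "sense_obs")]
}

#' Assign reads and attach gene-strand metadata
#'
#' Thin wrapper around [assign_reads()] that records each gene's strand on the
#' result, as required by [build_base_table()].
#'
#' @inheritParams assign_reads
#' @param ... Passed to [assign_reads()].
#' @export
assign_and_annotate <- function(reads, gene_models, ...) {
  a <- assign_reads(reads, gene_models, ...)
  attr(a, "gene_strand") <- setNames(gene_models$genes$strand,
                                     gene_models$genes$gene_id)
  a
}

#' Filter the per-base table by mask, trim window and quality floor
#'
#' Applies, in order: removal of `N` bases (read or reference), the base
#' quality floor, the read-end trim window, the SNP mask, and paired-end
#' overlap resolution. Trimmed positions are excluded from *all* downstream
#' tables (site table included) so SNP detection and NTR estimation see the
#' same positions ("trim guards").
#'
#' @param base_table From [build_base_table()].
#' @param mask Optional SNP mask tibble (`chrom`, `pos`), 0-based.
#' @param trim5,trim3 Number of read positions trimmed from the 5'/3' read
#'   ends (as sequenced).
#' @param q_floor Minimum Phred base quality for a position to count.
#' @param pair_policy `"count_once"` (doubly covered positions counted once,
#'   higher-quality mate wins) or `"drop_discordant"` (positions where mates
#'   disagree are excluded entirely).
#' @return Filtered per-base tibble.
#' @export
filter_base_table <- function(base_table, mask = NULL, trim5 = 0L, trim3 = 0L,
                              q_floor = 20L,
                              pair_policy = c("count_once", "drop_discordant")) {
  pair_policy <- match.arg(pair_policy)
  bt <- base_table %>%
    filter(.data$ref != "N", .data$obs != "N",
           .data$qual >= q_floor,
           .data$rpos >= trim5,
           .data$rpos < .data$read_len - trim3)
  if (!is.null(mask) && nrow(mask) > 0L) {
    bt <- bt %>% anti_join(mask, by = c("chrom" = "chrom", "gpos" = "pos"))
  }
  resolve_pair_overlap(bt, policy = pair_policy)
}

#' Resolve paired-end overlap in the per-base table
#'
#' Reference positions covered by both mates of a fragment are counted once.
#' Under `count_once` the mate with the higher base quality wins (ties go to
#' mate 1); under `drop_discordant` a doubly covered position where the mates
#' disagree on the base is excluded from both numerator and denominator.
#'
#' @param base_table Per-base tibble.
#' @param policy `"count_once"` or `"drop_discordant"`.
#' @return Per-base tibble with at most one row per (fragment, gene, position).
#' @export
resolve_pair_overlap <- function(base_table,
                                 policy = c("count_once", "drop_discordant")) {
  policy <- match.arg(policy)
  paired <- base_table$mate > 0L
  if (!any(paired)) return(base_table)
  bp <- base_table[paired, ]
  dup_grp <- bp %>%
    dplyr::add_count(.data$read_id, .data$gene_id, .data$chrom, .data$gpos,
                     name = "n_cov")
  solo <- dup_grp %>% filter(.data$n_cov == 1L) %>% select(-"n_cov")
  dup <- dup_grp %>% filter(.data$n_cov > 1L) %>% select(-"n_cov")
  if (nrow(dup) > 0L) {
    if (policy == "drop_discordant") {
      dup <- dup %>%
        group_by(.data$read_id, .data$gene_id, .data$chrom, .data$gpos) %>%
        filter(dplyr::n_distinct(.data$obs) == 1L) %>%
        arrange(.data$mate, .by_group = TRUE) %>%
        slice(1L) %>%
        ungroup()
    } else {
      dup <- dup %>%
        group_by(.data$read_id, .data$gene_id, .data$chrom, .data$gpos) %>%
        arrange(dplyr::desc(.data$qual), .data$mate, .by_group = TRUE) %>%
        slice(1L) %>%
        ungroup()
    }
  }
  bind_rows(base_table[!paired, ], solo, dup)
}

#' Per-read conversion counts
#'
#' Summarises the filtered per-base table into per-read (n_T, k) pairs: `n_T`
#' usable sense-strand reference-T positions and `k` observed T>C conversions
#' (sense strand), with the read's assignment weight.
#'
#' @param base_table Filtered per-base tibble ([filter_base_table()]).
#' @return Tibble `read_id`, `gene_id`, `n_T`, `k`, `weight`.
#' @export
read_conversion_counts <- function(base_table) {
  base_table %>%
    filter(.data$sense_ref == "T") %>%
    group_by(.data$read_id, .data$gene_id) %>%
    summarise(n_T = dplyr::n(),
              k = sum(.data$sense_obs == "C"),
              weight = first(.data$weight), .groups = "drop")
}

#' Per-site coverage and mismatch table
#'
#' One row per genomic position whose sense-strand reference base is T, with
#' total T coverage, the T>C count and the other substitution-class counts.
#' This is the substrate for SNP knee detection.
#'
#' @param base_table Filtered per-base tibble.
#' @return Tibble `chrom`, `gpos`, `coverage`, `tc_count`, `ta_count`,
#'   `tg_count`.
#' @export
site_table <- function(base_table) {
  base_table %>%
    filter(.data$sense_ref == "T") %>%
    distinct(.data$read_id, .data$mate, .data$chrom, .data$gpos,
             .keep_all = TRUE) %>%
    group_by(.data$chrom, .data$gpos) %>%
    summarise(coverage = dplyr::n(),
              tc_count = sum(.data$sense_obs == "C"),
              ta_count = sum(.data$sense_obs == "A"),
              tg_count = sum(.data$sense_obs == "G"),
              .groups = "drop")
}

#' Per-read-position conversion profile, chunked
#'
#' T coverage and T>C counts per read position, split into `chunks` read
#' chunks (round-robin over input order) for variance estimation.
#'
#' @param base_table Filtered per-base tibble.
#' @param chunks Number of chunks (C >= 1; the variance curve needs >= 2).
#' @return Tibble `chunk` (0-based), `rpos`, `t_coverage`, `tc_count`.
#' @export
conversion_profile <- function(base_table, chunks = 10L) {
  stopifnot(chunks >= 1L)
  base_table %>%
    filter(.data$sense_ref == "T") %>%
    mutate(chunk = (match(.data$read_index,
                          sort(unique(base_table$read_index))) - 1L) %%
             as.integer(chunks)) %>%
    group_by(.data$chunk, .data$rpos) %>%
    summarise(t_coverage = dplyr::n(),
              tc_count = sum(.data$sense_obs == "C"),
              .groups = "drop")
}

#' Aggregate per-read counts into per-gene totals
#'
#' @param read_counts From [read_conversion_counts()].
#' @param gene_models Optional `gene_models`; when given, genes with no reads
#'   are included with zero counts and gene names are attached.
#' @param min_reads Weighted read-count threshold below which a gene is
#'   flagged low-coverage (still reported).
#' @return Tibble `gene_id`, `read_count` (weighted), `K` (weighted
#'   conversions), `N_T` (weighted T coverage), `low_coverage`, plus a
#'   `reads` list-column of the per-read (n_T, k, weight) records used for
#'   NTR estimation.
#' @export
aggregate_gene_counts <- function(read_counts, gene_models = NULL,
                                  min_reads = 20) {
  agg <- read_counts %>%
    group_by(.data$gene_id) %>%
    summarise(read_count = sum(.data$weight),
              K = sum(.data$weight * .data$k),
              N_T = sum(.data$weight * .data$n_T),
              reads = list(dplyr::pick("n_T", "k", "weight")),
              .groups = "drop")
  if (!is.null(gene_models)) {
    all_genes <- gene_models$genes %>% select("gene_id", "gene_name")
    agg <- all_genes %>%
      left_join(agg, by = "gene_id") %>%
      mutate(read_count = dplyr::coalesce(.data$read_count, 0),
             K = dplyr::coalesce(.data$K, 0),
             N_T = dplyr::coalesce(.data$N_T, 0),
             reads = purrr::map(.data$reads, function(r) {
               r %||% tibble(n_T = integer(), k = integer(), weight = double())
             }))
  }
  agg %>% mutate(low_coverage = .data$read_count < min_reads)
}
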