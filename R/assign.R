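#' Assign reads to genes
#'
#' Implements the two assignment rule sets used for conversion counting.
#'
#' In `default` mode a read is assigned to a gene iff *all* of its aligned
#' blocks fall within that gene's union exons on the sense strand, and that
#' gene is unique; reads matching several genes are `ambiguous` and excluded
#' from counting, everything else is `unassigned`. In `compat` (GEDI-style)
#' mode three additional behaviors apply: unspliced reads fully within
#' intronic regions are assigned as `intronic` and counted; a read is
#' accepted for a gene when at least half of its aligned bases overlap the
#' gene's exons and every splice junction in the read matches an annotated
#' junction of that gene (lenient acceptance); and multi-gene/multi-alignment
#' reads receive weight `1 / (n_alignments * geneCount)`. Each compat
#' behavior is an independent tri-state option (`inherit`/`on`/`off`);
#' `mode = "compat"` turns them all on unless individually overridden.
#'
#' @param reads Alignment tibble from [load_alignments()].
#' @param gene_models A `gene_models` object from [load_annotation()].
#' @param mode `"default"` or `"compat"`.
#' @param strandedness `"sense"` (reads report the transcript strand) or
#'   `"antisense"` (reverse-stranded protocol; alignment strand is flipped
#'   before matching gene strand).
#' @param compat_intronic,compat_lenient,compat_weighting Tri-state compat
#'   toggles: `"inherit"` (follow `mode`), `"on"`, or `"off"`.
#' @return A tibble `read_id`, `row` (alignment row in `reads`), `gene_id`,
#'   `category` (`exonic`, `intronic`, `ambiguous`, `unassigned`), `weight`.
#'   Only `exonic`/`intronic` rows carry a gene and a positive weight.
#' @export
assign_reads <- function(reads, gene_models,
                         mode = c("default", "compat"),
                         strandedness = c("sense", "antisense"),
                         compat_intronic = c("inherit", "on", "off"),
                         compat_lenient = c("inherit", "on", "off"),
                         compat_weighting = c("inherit", "on", "off")) {
  mode <- match.arg(mode)
  strandedness <- match.arg(strandedness)
  tri <- function(x) {
    x <- match.arg(x, c("inherit", "on", "off"))
    if (x == "inherit") mode == "compat" else x == "on"
  }
  use_intronic <- tri(compat_intronic)
  use_lenient <- tri(compat_lenient)
  use_weighting <- tri(compat_weighting)

  empty <- tibble(read_id = character(), row = integer(),
                  gene_id = character(), category = character(),
                  weight = double())
  if (nrow(reads) == 0L) return(empty)

  blocks <- alignment_blocks(reads)
  # fragment orientation: the second mate of an FR pair aligns antisense to
  # the fragment, so its strand is flipped before matching the gene strand
  frag_strand <- if_else(reads$mate == 2L,
                         if_else(reads$strand == "+", "-", "+"),
                         reads$strand)
  read_strand <- if (strandedness == "sense") frag_strand else
    if_else(frag_strand == "+", "-", "+")

  bl_gr <- GenomicRanges::GRanges(
    seqnames = reads$chrom[blocks$row],
    ranges = IRanges::IRanges(blocks$ref_start + 1L, blocks$ref_end))
  ue_gr <- union_exon_granges(gene_models)
  gene_strand <- setNames(gene_models$genes$strand, gene_models$genes$gene_id)

  hits <- GenomicRanges::findOverlaps(bl_gr, ue_gr, ignore.strand = TRUE)
  ov <- tibble(
    block = S4Vectors::queryHits(hits),
    gene_id = ue_gr$gene_id[S4Vectors::subjectHits(hits)]
  )
  ov$row <- blocks$row[ov$block]
  ov$ov_width <- IRanges::width(IRanges::pintersect(
    IRanges::ranges(bl_gr)[ov$block],
    IRanges::ranges(ue_gr)[S4Vectors::subjectHits(hits)]))
  within <- IRanges::`%within%`(
    IRanges::ranges(bl_gr)[ov$block],
    IRanges::ranges(ue_gr)[S4Vectors::subjectHits(hits)])
  ov$within <- within

  blocks$len <- blocks$ref_end - blocks$ref_start
  read_len <- blocks %>% group_by(.data$row) %>%
    summarise(aligned = sum(.data$len), n_blocks = dplyr::n(), .groups = "drop")

  per_gene <- ov %>%
    group_by(.data$row, .data$gene_id) %>%
    summarise(ov_bases = sum(.data$ov_width),
              blocks_within = sum(.data$within),
              .groups = "drop") %>%
    left_join(read_len, by = "row") %>%
    mutate(strand_ok = read_strand[.data$row] ==
             unname(gene_strand[.data$gene_id]),
           fully_exonic = .data$blocks_within == .data$n_blocks,
           frac = .data$ov_bases / .data$aligned) %>%
    filter(.data$strand_ok)

  # splice-junction concordance for lenient acceptance
  if (use_lenient && nrow(per_gene) > 0L) {
    jn <- alignment_junctions(reads)
    if (nrow(jn) > 0L) {
      gj <- gene_models$junctions
      jn_status <- per_gene %>%
        select("row", "gene_id") %>%
        inner_join(jn, by = "row", relationship = "many-to-many") %>%
        left_join(gj %>% mutate(known = TRUE),
                  by = c("gene_id", "start", "end")) %>%
        group_by(.data$row, .data$gene_id) %>%
        summarise(junctions_ok = all(!is.na(.data$known)), .groups = "drop")
      per_gene <- per_gene %>%
        left_join(jn_status, by = c("row", "gene_id")) %>%
        mutate(junctions_ok = if_else(is.na(.data$junctions_ok),
                                      TRUE, .data$junctions_ok))
    } else {
      per_gene$junctions_ok <- TRUE
    }
  }

  if (use_lenient) {
    per_gene$accepted <- per_gene$fully_exonic |
      (per_gene$frac >= 0.5 & per_gene$junctions_ok)
  } else {
    per_gene$accepted <- per_gene$fully_exonic
  }
  acc <- per_gene %>% filter(.data$accepted) %>%
    mutate(category = "exonic")

  # intronic classification of unspliced reads fully inside intron intervals
  if (use_intronic) {
    ig <- intron_granges(gene_models)
    if (length(ig) > 0L) {
      ih <- GenomicRanges::findOverlaps(bl_gr, ig, type = "within",
                                        ignore.strand = TRUE)
      iov <- tibble(block = S4Vectors::queryHits(ih),
                    gene_id = ig$gene_id[S4Vectors::subjectHits(ih)])
      iov$row <- blocks$row[iov$block]
      intr <- iov %>%
        distinct(.data$row, .data$gene_id, .data$block) %>%
        group_by(.data$row, .data$gene_id) %>%
        summarise(blocks_within = dplyr::n(), .groups = "drop") %>%
        left_join(read_len, by = "row") %>%
        filter(.data$blocks_within == .data$n_blocks,
               !reads$is_spliced[.data$row],
               read_strand[.data$row] == unname(gene_strand[.data$gene_id])) %>%
        # an exonically accepted read is not also intronic for the same gene
        anti_join(acc, by = c("row", "gene_id")) %>%
        mutate(category = "intronic")
      acc <- bind_rows(acc, intr)
    }
  }

  if (nrow(acc) == 0L) {
    return(tibble(read_id = reads$read_id, row = seq_len(nrow(reads)),
                  gene_id = NA_character_, category = "unassigned",
                  weight = 0))
  }

  gene_counts <- acc %>% count(.data$row, name = "gene_count")
  acc <- acc %>% left_join(gene_counts, by = "row")

  if (mode == "default" && !use_weighting) {
    out <- acc %>%
      mutate(category = if_else(.data$gene_count > 1L, "ambiguous",
                                .data$category),
             weight = if_else(.data$gene_count > 1L, 0, 1))
  } else if (use_weighting) {
    out <- acc %>%
      mutate(weight = 1 / (reads$n_alignments[.data$row] * .data$gene_count))
  } else {
    # compat rules but uniform weighting: multi-gene reads still ambiguous
    out <- acc %>%
      mutate(category = if_else(.data$gene_count > 1L, "ambiguous",
                                .data$category),
             weight = if_else(.data$gene_count > 1L, 0, 1))
  }

  out <- out %>%
    mutate(read_id = reads$read_id[.data$row]) %>%
    select("read_id", "row", "gene_id", "category", "weight")

  un_rows <- setdiff(seq_len(nrow(reads)), unique(out$row))
  if (length(un_rows) > 0L) {
    out <- bind_rows(out, tibble(read_id = reads$read_id[un_rows],
                                 row = un_rows, gene_id = NA_character_,
                                 category = "unassigned", weight = 0))
  }
  arrange(out, .data$row, .data$gene_id)
}
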