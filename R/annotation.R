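#' Load gene models from a GTF file
#'
#' Parses exon features from a GTF (Ensembl/GENCODE dialect) and builds the
#' gene models used for read assignment: per-gene merged ("union") exons,
#' per-transcript introns, and the set of splice junctions. GTF 1-based closed
#' coordinates are converted to the package-internal 0-based half-open
#' convention on load.
#'
#' @param gtf_path Path to a GTF file with `exon` features carrying `gene_id`
#'   and `transcript_id` attributes.
#' @return A `gene_models` object: a list with tibbles `genes`
#'   (`gene_id`, `gene_name`, `chrom`, `strand`, `start`, `end`),
#'   `union_exons` (`gene_id`, `chrom`, `start`, `end`), `introns`
#'   (`gene_id`, `transcript_id`, `chrom`, `start`, `end`) and `junctions`
#'   (`gene_id`, `chrom`, `start`, `end`) — all 0-based half-open.
#' @examples
#' gtf <- tempfile(fileext = ".gtf")
#' writeLines(paste("chr1", "src", "exon", 1, 100, ".", "+", ".",
#'   'gene_id "g1"; transcript_id "t1";', sep = "\t"), gtf)
#' gm <- load_annotation(gtf)
#' gm$genes
#' @export
load_annotation <- function(gtf_path) {
  if (!file.exists(gtf_path)) abort(paste0("GTF file not found: ", gtf_path))
  raw <- readLines(gtf_path)
  body <- raw[!startsWith(raw, "#") & nzchar(trimws(raw))]
  if (length(body) == 0L) {
    return(new_gene_models(
      genes = tibble(gene_id = character(), gene_name = character(),
                     chrom = character(), strand = character(),
                     start = integer(), end = integer()),
      union_exons = tibble(gene_id = character(), chrom = character(),
                           start = integer(), end = integer()),
      introns = tibble(gene_id = character(), transcript_id = character(),
                       chrom = character(), start = integer(), end = integer()),
      junctions = tibble(gene_id = character(), chrom = character(),
                         start = integer(), end = integer())
    ))
  }

  gr <- rtracklayer::import(gtf_path, format = "gtf")
  ex <- gr[gr$type == "exon"]
  if (length(ex) > 0L) {
    miss <- which(is.na(ex$gene_id) | is.na(ex$transcript_id))
    if (length(miss) > 0L) {
      ln <- gtf_exon_line_numbers(raw)[miss[1]]
      abort(paste0("GTF exon feature missing gene_id/transcript_id at line ",
                   ln))
    }
    bad <- which(BiocGenerics::width(ex) < 1L)
    if (length(bad) > 0L) {
      ln <- gtf_exon_line_numbers(raw)[bad[1]]
      abort(paste0("GTF exon with start >= end at line ", ln))
    }
  }

  exons <- tibble(
    gene_id = as.character(ex$gene_id),
    gene_name = as.character(ex$gene_name %enull% ex$gene_id),
    transcript_id = as.character(ex$transcript_id),
    chrom = as.character(GenomeInfoDb::seqnames(ex)),
    strand = as.character(BiocGenerics::strand(ex)),
    start = BiocGenerics::start(ex) - 1L,   # to 0-based half-open
    end = BiocGenerics::end(ex)
  )
  if (nrow(exons) > 0L && is.null(ex$gene_name)) exons$gene_name <- exons$gene_id
  exons$gene_name[is.na(exons$gene_name)] <-
    exons$gene_id[is.na(exons$gene_name)]

  genes <- exons %>%
    group_by(.data$gene_id) %>%
    summarise(gene_name = first(.data$gene_name),
              chrom = first(.data$chrom),
              strand = first(.data$strand),
              start = min(.data$start), end = max(.data$end),
              .groups = "drop")

  union_exons <- exons %>%
    group_by(.data$gene_id, .data$chrom) %>%
    dplyr::reframe(merge_intervals(.data$start, .data$end)) %>%
    ungroup()

  # an intron is the gap between consecutive exons of one transcript
  introns <- exons %>%
    arrange(.data$gene_id, .data$transcript_id, .data$start) %>%
    group_by(.data$gene_id, .data$transcript_id, .data$chrom) %>%
    dplyr::reframe(istart = utils::head(.data$end, -1L),
                   iend = utils::tail(.data$start, -1L)) %>%
    rename(start = "istart", end = "iend")
  introns <- introns[introns$start < introns$end,
                     c("gene_id", "transcript_id", "chrom", "start", "end")]

  junctions <- introns %>%
    distinct(.data$gene_id, .data$chrom, .data$start, .data$end)

  new_gene_models(genes = genes, union_exons = union_exons,
                  introns = introns, junctions = junctions)
}

# line numbers (1-based, in the original file) of exon features
gtf_exon_line_numbers <- function(raw_lines) {
  keep <- !startsWith(raw_lines, "#") & nzchar(trimws(raw_lines))
  idx <- which(keep)
  feat <- vapply(strsplit(raw_lines[idx], "\t", fixed = TRUE),
                 function(f) if (length(f) >= 3) f[3] else "", character(1))
  idx[feat == "exon"]
}

# merge sorted/unsorted 0-based half-open intervals into their union
merge_intervals <- function(start, end) {
  stopifnot(all(start < end))
  o <- order(start, end)
  start <- start[o]; end <- end[o]
  ms <- start[1]; me <- end[1]
  out_s <- integer(); out_e <- integer()
  if (length(start) > 1L) {
    for (i in 2:length(start)) {
      if (start[i] <= me) {
        me <- max(me, end[i])
      } else {
        out_s <- c(out_s, ms); out_e <- c(out_e, me)
        ms <- start[i]; me <- end[i]
      }
    }
  }
  tibble(start = c(out_s, ms), end = c(out_e, me))
}

new_gene_models <- function(genes, union_exons, introns, junctions) {
  structure(list(genes = genes, union_exons = union_exons,
                 introns = introns, junctions = junctions),
            class = "gene_models")
}

#' @export
print.gene_models <- function(x, ...) {
  cat("<gene_models> ", nrow(x$genes), " genes, ",
      nrow(x$union_exons), " union exons, ",
      nrow(x$junctions), " distinct junctions\n", sep = "")
  invisible(x)
}

# GRanges of union exons with gene_id metadata (1-based internally for IRanges)
union_exon_granges <- function(gm) {
  ue <- gm$union_exons
  gr <- GenomicRanges::GRanges(
    seqnames = ue$chrom,
    ranges = IRanges::IRanges(start = ue$start + 1L, end = ue$end),
    gene_id = ue$gene_id
  )
  gr
}

# per-gene intronic intervals = union over transcripts' introns minus exons
intron_granges <- function(gm) {
  if (nrow(gm$introns) == 0L) {
    return(GenomicRanges::GRanges(gene_id = character()))
  }
  intr <- gm$introns %>%
    group_by(.data$gene_id, .data$chrom) %>%
    dplyr::reframe(merge_intervals(.data$start, .data$end)) %>%
    ungroup()
  # remove any part covered by another transcript's exon of the same gene
  out <- purrr::map_dfr(split(intr, intr$gene_id), function(d) {
    ue <- gm$union_exons[gm$union_exons$gene_id == d$gene_id[1], ]
    ig <- IRanges::IRanges(d$start + 1L, d$end)
    eg <- IRanges::IRanges(ue$start + 1L, ue$end)
    kept <- BiocGenerics::setdiff(ig, eg)
    if (length(kept) == 0L) return(tibble())
    tibble(gene_id = d$gene_id[1], chrom = d$chrom[1],
           start = BiocGenerics::start(kept) - 1L,
           end = BiocGenerics::end(kept))
  })
  if (nrow(out) == 0L) return(GenomicRanges::GRanges(gene_id = character()))
  GenomicRanges::GRanges(
    seqnames = out$chrom,
    ranges = IRanges::IRanges(out$start + 1L, out$end),
    gene_id = out$gene_id
  )
}
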