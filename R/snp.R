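#' Load a SNP mask from BED or VCF
#'
#' BED intervals (0-based half-open) are expanded to one row per position.
#' VCF records contribute `POS - 1` for single-nucleotide variants; indel
#' records are skipped and counted in the `n_skipped_indels` attribute.
#' Loading the same file twice yields identical masks.
#'
#' @param path File path.
#' @param format `"auto"` (by extension), `"bed"` or `"vcf"`.
#' @return Tibble `chrom`, `pos` (0-based), distinct rows; attribute
#'   `n_skipped_indels` for VCF input.
#' @export
load_snp_mask <- function(path, format = c("auto", "bed", "vcf")) {
  format <- match.arg(format)
  if (!file.exists(path)) abort(paste0("SNP mask file not found: ", path))
  if (format == "auto") {
    format <- if (grepl("\\.vcf(\\.gz)?$", path, ignore.case = TRUE))
      "vcf" else "bed"
  }
  if (format == "bed") {
    lines <- readLines(path)
    lines <- lines[nzchar(trimws(lines)) & !startsWith(lines, "#") &
                     !startsWith(lines, "track") & !startsWith(lines, "browser")]
    if (length(lines) == 0L) {
      return(tibble(chrom = character(), pos = integer()))
    }
    gr <- rtracklayer::import(path, format = "BED")
    pos0 <- BiocGenerics::start(gr) - 1L  # back to 0-based
    widths <- BiocGenerics::width(gr)
    mask <- tibble(
      chrom = rep(as.character(GenomeInfoDb::seqnames(gr)), widths),
      pos = unlist(purrr::map2(pos0, widths, function(s, w) s + 0:(w - 1L)),
                   use.names = FALSE)
    )
    return(distinct(mask))
  }
  # VCF: SNV rows only
  if (!requireNamespace("VariantAnnotation", quietly = TRUE)) {
    abort("VCF mask support needs the VariantAnnotation package")
  }
  vcf <- VariantAnnotation::readVcf(path, genome = "unknown")
  rr <- SummarizedExperiment::rowRanges(vcf)
  ref <- as.character(VariantAnnotation::ref(vcf))
  alt_len <- S4Vectors::elementNROWS(VariantAnnotation::alt(vcf))
  alt_chr <- vapply(as.list(VariantAnnotation::alt(vcf)), function(a) {
    max(nchar(as.character(a)))
  }, numeric(1))
  is_snv <- nchar(ref) == 1L & alt_len >= 1L & alt_chr == 1
  n_skipped <- sum(!is_snv)
  if (n_skipped > 0L) {
    warn(paste0(n_skipped, " non-SNV VCF record(s) skipped from SNP mask"))
  }
  mask <- tibble(
    chrom = as.character(GenomeInfoDb::seqnames(rr))[is_snv],
    pos = BiocGenerics::start(rr)[is_snv] - 1L
  ) %>% distinct()
  attr(mask, "n_skipped_indels") <- n_skipped
  mask
}

#' Detect the SNP mismatch-fraction threshold by knee detection
#'
#' Kneedle-style knee detection on the mismatch-fraction histogram of
#' sense-strand T sites. Sites with coverage >= `min_cov` are eligible; their
#' T>C fractions are binned into `bins` equal-width bins over `[0, 1]`, bin
#' counts are `log1p`-transformed and min-max normalised, and the knee is the
#' bin maximising the distance `1 - x - y` from the descending diagonal (the
#' histogram decreases from its mass near zero, so the knee sits just past
#' the decay of the sequencing-error population — Kneedle geometry for a
#' decreasing curve). Guardrails: fewer than 1,000 eligible sites or knee strength
#' <= 0.02 trigger the fallback threshold 0.22; otherwise the raw knee is
#' clamped to `[0.10, 0.60]`.
#'
#' @param sites Site table from [site_table()].
#' @param min_cov Minimum coverage for a site to be eligible (default 10).
#' @param bins Number of histogram bins (default 100).
#' @return A `knee_result` object (list): `threshold`, `raw_knee`,
#'   `strength`, `eligible_sites`, `clamped`, `fallback_used`, `histogram`
#'   (tibble `bin_lower`, `count`).
#' @export
detect_snp_threshold <- function(sites, min_cov = 10L, bins = 100L) {
  elig <- sites %>% filter(.data$coverage >= min_cov)
  f <- elig$tc_count / elig$coverage
  edges <- seq(0, 1, length.out = bins + 1L)
  bin <- pmin(findInterval(f, edges, rightmost.closed = TRUE), bins)
  counts <- tabulate(bin, nbins = bins)
  hist_tbl <- tibble(bin_lower = edges[-length(edges)], count = counts)

  y <- log1p(counts)
  rng <- range(y)
  fallback <- FALSE
  raw_knee <- NA_real_
  strength <- 0
  if (rng[2] > rng[1]) {
    yn <- (y - rng[1]) / (rng[2] - rng[1])
    xn <- (seq_len(bins) - 1) / (bins - 1)
    d <- 1 - xn - yn
    b_star <- which.max(d)
    strength <- d[b_star]
    raw_knee <- edges[b_star]
  }
  if (nrow(elig) < 1000L || strength <= 0.02) {
    fallback <- TRUE
    threshold <- 0.22
    clamped <- FALSE
  } else {
    threshold <- clamp(raw_knee, 0.10, 0.60)
    clamped <- threshold != raw_knee
  }
  structure(list(threshold = threshold, raw_knee = raw_knee,
                 strength = strength, eligible_sites = nrow(elig),
                 clamped = clamped, fallback_used = fallback,
                 histogram = hist_tbl),
            class = "knee_result")
}

#' @export
print.knee_result <- function(x, ...) {
  cat("<knee_result> threshold = ", format(x$threshold),
      if (x$fallback_used) " (fallback)" else "",
      if (x$clamped) " (clamped)" else "",
      "; eligible sites = ", x$eligible_sites,
      "; strength = ", format(round(x$strength, 4)), "\n", sep = "")
  invisible(x)
}

#' @rdname detect_snp_threshold
#' @param x A `knee_result`.
#' @param ... Unused.
#' @method glance knee_result
#' @export
glance.knee_result <- function(x, ...) {
  tibble(threshold = x$threshold, raw_knee = x$raw_knee,
         strength = x$strength, eligible_sites = x$eligible_sites,
         clamped = x$clamped, fallback_used = x$fallback_used)
}

#' Build a SNP mask from the site table at a given threshold
#'
#' Masks every eligible site (coverage >= `min_cov`) whose T>C fraction is at
#' least `threshold`. Sites below the coverage floor are never masked by
#' auto-detection.
#'
#' @param sites Site table.
#' @param threshold Mismatch-fraction threshold in (0, 1].
#' @param min_cov Minimum coverage for eligibility.
#' @return Mask tibble `chrom`, `pos`.
#' @export
build_snp_mask <- function(sites, threshold, min_cov = 10L) {
  stopifnot(threshold > 0, threshold <= 1)
  sites %>%
    filter(.data$coverage >= min_cov,
           .data$tc_count / .data$coverage >= threshold) %>%
    select(chrom = "chrom", pos = "gpos")
}

#' Combine SNP masks (set union)
#'
#' @param ... Mask tibbles (`chrom`, `pos`); `NULL`s are ignored.
#' @return The distinct union.
#' @export
union_masks <- function(...) {
  ms <- purrr::compact(list(...))
  if (length(ms) == 0L) return(tibble(chrom = character(), pos = integer()))
  distinct(bind_rows(ms))
}
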