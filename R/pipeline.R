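#' Run the full SLAM-seq requantification pipeline
#'
#' Two-pass offline requantification of existing alignments: pass 1 builds
#' the site table and chunked conversion profile with zero trim, from which
#' the SNP threshold/mask and the auto-trim window are derived; pass 2
#' recounts under the final mask and trim, estimates global conversion rates
#' and per-gene NTRs, and writes the quantification table, a run manifest and
#' (optionally) the QC report. With several BAM inputs, `trim_scope =
#' "first"` computes the trim on the first file and applies it everywhere;
#' `"per-file"` computes it independently per file. Reads are pooled across
#' files for SNP detection and quantification.
#'
#' @param bam One or more BAM/SAM paths.
#' @param fasta Reference FASTA path.
#' @param gtf Gene annotation GTF path.
#' @param out_prefix Output path prefix; writes `<prefix>.ntr.tsv`,
#'   `<prefix>.manifest.json` and, with `qc_report`, `<prefix>.qc.json`
#'   (+ `.qc.html` if `qc_html`).
#' @param snp_bed,snp_vcf Optional SNP mask files.
#' @param snp_detect Run internal knee-based SNP detection (default TRUE
#'   when no mask file given). Combined with a file mask by set union.
#' @param snp_min_cov,snp_bins Knee-detection parameters.
#' @param snp_threshold Manual threshold override, bypassing guardrails.
#' @param auto_trim `"variance"` or `"none"`.
#' @param trim_scope `"first"` or `"per-file"`.
#' @param trim5,trim3 Manual trim override (disables auto-trim).
#' @param trim_chunks,trim_window Variance-curve parameters.
#' @param mode,strandedness,compat_intronic,compat_lenient,compat_weighting
#'   Assignment options, see [assign_reads()]; `mode = "compat"` is the
#'   GEDI-compatibility mode.
#' @param pair_policy Paired-end overlap policy, see [filter_base_table()].
#' @param q_floor Minimum base quality (default 20).
#' @param p_old,p_new Optional user-supplied global rates.
#' @param min_reads Weighted read count below which a gene is flagged
#'   low-coverage (default 20).
#' @param schema Output table schema, `"native"` or `"grandslam"`.
#' @param qc_report,qc_html Emit the QC JSON / single-file HTML report.
#' @param seed Recorded in the manifest (the pipeline itself is
#'   deterministic).
#' @return A `slam_run` list: `ntr` (the `ntr_fit` tibble), `rates`, `knee`,
#'   `trim` (per-file tibble), `gene_counts`, `site_pass1`, `site_pass2`,
#'   `mask`, `manifest`, `paths`.
#' @export
run_quant <- function(bam, fasta, gtf, out_prefix = NULL,
                      snp_bed = NULL, snp_vcf = NULL, snp_detect = NULL,
                      snp_min_cov = 10L, snp_bins = 100L,
                      snp_threshold = NULL,
                      auto_trim = c("variance", "none"),
                      trim_scope = c("first", "per-file"),
                      trim5 = NULL, trim3 = NULL,
                      trim_chunks = 10L, trim_window = 3L,
                      mode = c("default", "compat"),
                      strandedness = c("sense", "antisense"),
                      compat_intronic = "inherit", compat_lenient = "inherit",
                      compat_weighting = "inherit",
                      pair_policy = c("count_once", "drop_discordant"),
                      q_floor = 20L, p_old = NULL, p_new = NULL,
                      min_reads = 20, schema = c("native", "grandslam"),
                      qc_report = FALSE, qc_html = FALSE, seed = 1L) {
  auto_trim <- match.arg(auto_trim)
  trim_scope <- match.arg(trim_scope)
  mode <- match.arg(mode)
  strandedness <- match.arg(strandedness)
  pair_policy <- match.arg(pair_policy)
  schema <- match.arg(schema)
  if (is.null(snp_detect)) snp_detect <- is.null(snp_bed) && is.null(snp_vcf)
  manual_trim <- !is.null(trim5) || !is.null(trim3)

  stage <- function(...) inform(paste0("[slamkit] ", ...))
  stage("loading annotation: ", gtf)
  gm <- load_annotation(gtf)
  stage(nrow(gm$genes), " genes loaded")

  bams <- as.character(bam)
  base_tables <- purrr::imap(bams, function(b, i) {
    stage("pass 1, file ", i, ": ", b)
    reads <- load_alignments(b, fasta)
    asn <- assign_and_annotate(reads, gm, mode = mode,
                               strandedness = strandedness,
                               compat_intronic = compat_intronic,
                               compat_lenient = compat_lenient,
                               compat_weighting = compat_weighting)
    n_asn <- sum(asn$category %in% c("exonic", "intronic"))
    stage("  ", nrow(reads), " alignments, ", n_asn, " assigned")
    build_base_table(reads, asn, fasta)
  })

  # pass 1: no mask, no trim (quality floor and N handling always apply)
  pass1 <- purrr::map(base_tables, filter_base_table, mask = NULL,
                      trim5 = 0L, trim3 = 0L, q_floor = q_floor,
                      pair_policy = pair_policy)
  pooled1 <- bind_rows(pass1)
  sites1 <- site_table(pooled1)

  # SNP mask
  file_mask <- NULL
  if (!is.null(snp_bed)) file_mask <- union_masks(file_mask,
                                                  load_snp_mask(snp_bed, "bed"))
  if (!is.null(snp_vcf)) file_mask <- union_masks(file_mask,
                                                  load_snp_mask(snp_vcf, "vcf"))
  knee <- NULL
  auto_mask <- NULL
  if (isTRUE(snp_detect)) {
    if (!is.null(snp_threshold)) {
      knee <- structure(list(threshold = snp_threshold,
                             raw_knee = snp_threshold, strength = NA_real_,
                             eligible_sites = sum(sites1$coverage >= snp_min_cov),
                             clamped = FALSE, fallback_used = FALSE,
                             histogram = NULL), class = "knee_result")
    } else {
      knee <- detect_snp_threshold(sites1, min_cov = snp_min_cov,
                                   bins = snp_bins)
    }
    auto_mask <- build_snp_mask(sites1, knee$threshold, min_cov = snp_min_cov)
    stage("SNP threshold ", signif(knee$threshold, 3),
          if (knee$fallback_used) " (fallback)" else "",
          "; ", nrow(auto_mask), " sites auto-masked")
  }
  mask <- union_masks(file_mask, auto_mask)
  stage("mask size: ", nrow(mask), " positions")

  # auto-trim
  trim_tbl <- purrr::imap_dfr(pass1, function(bt, i) {
    if (manual_trim) {
      return(tibble(file = bams[i], trim5 = as.integer(trim5 %||% 0L),
                    trim3 = as.integer(trim3 %||% 0L), source = "manual"))
    }
    if (auto_trim == "none") {
      return(tibble(file = bams[i], trim5 = 0L, trim3 = 0L, source = "none"))
    }
    if (trim_scope == "first" && i > 1L) {
      return(tibble(file = bams[i], trim5 = NA_integer_, trim3 = NA_integer_,
                    source = "first"))
    }
    prof <- conversion_profile(bt, chunks = trim_chunks)
    spec <- auto_trim(prof, window = trim_window)
    tibble(file = bams[i], trim5 = spec$trim5, trim3 = spec$trim3,
           source = "variance", fit = list(attr(spec, "fit")),
           curve = list(attr(spec, "curve")))
  })
  if (trim_scope == "first") {
    trim_tbl$trim5[is.na(trim_tbl$trim5)] <- trim_tbl$trim5[1]
    trim_tbl$trim3[is.na(trim_tbl$trim3)] <- trim_tbl$trim3[1]
  }
  stage("trim: ", paste(sprintf("%s(5'=%d,3'=%d)", basename(trim_tbl$file),
                                trim_tbl$trim5, trim_tbl$trim3),
                        collapse = ", "))

  # pass 2: final counting
  pass2 <- purrr::imap(base_tables, function(bt, i) {
    filter_base_table(bt, mask = mask, trim5 = trim_tbl$trim5[i],
                      trim3 = trim_tbl$trim3[i], q_floor = q_floor,
                      pair_policy = pair_policy)
  })
  pooled2 <- bind_rows(pass2)
  sites2 <- site_table(pooled2)
  rcounts <- read_conversion_counts(pooled2)
  stage(nrow(rcounts), " read/gene conversion records")

  rates <- estimate_global_rates(rcounts, sites = sites2,
                                 p_old = p_old, p_new = p_new)
  gcounts <- aggregate_gene_counts(rcounts, gene_models = gm,
                                   min_reads = min_reads)
  if (rates$source == "estimated") {
    rates <- refine_global_rates(gcounts, rates)
  }
  stage("rates: p_old = ", signif(rates$p_old, 4), ", p_new = ",
        signif(rates$p_new, 4), " (", rates$source, ")")
  ntr <- estimate_ntr(gcounts, rates)
  stage(nrow(ntr), " genes quantified")

  manifest <- list(
    tool = "slamkit", version = as.character(packageVersion("slamkit")),
    seed = seed,
    inputs = list(bam = bams, fasta = fasta, gtf = gtf,
                  snp_bed = snp_bed, snp_vcf = snp_vcf),
    options = list(mode = mode, strandedness = strandedness,
                   compat_intronic = compat_intronic,
                   compat_lenient = compat_lenient,
                   compat_weighting = compat_weighting,
                   pair_policy = pair_policy, q_floor = q_floor,
                   snp_detect = snp_detect, snp_min_cov = snp_min_cov,
                   snp_bins = snp_bins, snp_threshold = snp_threshold,
                   auto_trim = auto_trim, trim_scope = trim_scope,
                   trim_chunks = trim_chunks, trim_window = trim_window,
                   min_reads = min_reads, schema = schema),
    mask_sources = c(if (!is.null(file_mask)) "file",
                     if (!is.null(auto_mask)) "auto"),
    rates = list(p_old = rates$p_old, p_new = rates$p_new,
                 source = rates$source),
    knee = if (!is.null(knee)) {
      list(threshold = knee$threshold, raw_knee = knee$raw_knee,
           strength = knee$strength, eligible_sites = knee$eligible_sites,
           clamped = knee$clamped, fallback_used = knee$fallback_used)
    },
    trim = purrr::pmap(trim_tbl[, c("file", "trim5", "trim3", "source")], list)
  )

  paths <- list()
  if (!is.null(out_prefix)) {
    dir.create(dirname(out_prefix), showWarnings = FALSE, recursive = TRUE)
    paths$table <- paste0(out_prefix, ".ntr.tsv")
    write_ntr_table(ntr, paths$table, schema = schema)
    paths$manifest <- paste0(out_prefix, ".manifest.json")
    jsonlite::write_json(manifest, paths$manifest, auto_unbox = TRUE,
                         pretty = TRUE, null = "null", digits = NA)
  }

  run <- list(ntr = ntr, rates = rates, knee = knee, trim = trim_tbl,
              gene_counts = gcounts, read_counts = rcounts,
              site_pass1 = sites1, site_pass2 = sites2, mask = mask,
              profile = conversion_profile(pooled2, chunks = trim_chunks),
              manifest = manifest, paths = paths)
  class(run) <- "slam_run"

  if (qc_report && !is.null(out_prefix)) {
    qc <- build_qc_report(run)
    paths$qc_json <- paste0(out_prefix, ".qc.json")
    if (qc_html) paths$qc_html <- paste0(out_prefix, ".qc.html")
    write_qc(qc, paths$qc_json, html = paths$qc_html)
    run$paths <- paths
    run$qc <- qc
  }
  run
}

#' @export
print.slam_run <- function(x, ...) {
  cat("<slam_run> ", nrow(x$ntr), " genes; p_old = ",
      signif(x$rates$p_old, 3), ", p_new = ", signif(x$rates$p_new, 3),
      "; mask = ", nrow(x$mask), " sites\n", sep = "")
  invisible(x)
}

#' Re-run a pipeline from a written manifest
#'
#' Reproduces a run from its `<prefix>.manifest.json`: identical inputs and
#' options give byte-identical outputs.
#'
#' @param manifest_path Path to a manifest JSON written by [run_quant()].
#' @param out_prefix Output prefix for the re-run.
#' @param qc_report,qc_html Passed through to [run_quant()].
#' @return A `slam_run`.
#' @export
rerun_manifest <- function(manifest_path, out_prefix,
                           qc_report = FALSE, qc_html = FALSE) {
  m <- jsonlite::fromJSON(manifest_path)
  o <- m$options
  run_quant(bam = m$inputs$bam, fasta = m$inputs$fasta, gtf = m$inputs$gtf,
            out_prefix = out_prefix,
            snp_bed = m$inputs$snp_bed, snp_vcf = m$inputs$snp_vcf,
            snp_detect = o$snp_detect, snp_min_cov = o$snp_min_cov,
            snp_bins = o$snp_bins, snp_threshold = o$snp_threshold,
            auto_trim = o$auto_trim, trim_scope = o$trim_scope,
            trim_chunks = o$trim_chunks, trim_window = o$trim_window,
            mode = o$mode, strandedness = o$strandedness,
            compat_intronic = o$compat_intronic,
            compat_lenient = o$compat_lenient,
            compat_weighting = o$compat_weighting,
            pair_policy = o$pair_policy, q_floor = o$q_floor,
            min_reads = o$min_reads, schema = o$schema,
            qc_report = qc_report, qc_html = qc_html, seed = m$seed)
}
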