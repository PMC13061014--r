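#' Build the QC report object from a pipeline run
#'
#' Collects the four QC sections: per-read-position conversion rates, the
#' auto-trim variance curve with fitted breakpoints, the SNP detection
#' histogram with threshold annotations, and the per-gene NTR distribution
#' summary, plus the guardrail flags of the run.
#'
#' @param run A `slam_run` from [run_quant()].
#' @return A `qc_report` list with elements `per_position_rates`,
#'   `variance_fit`, `snp_histogram`, `ntr_summary`, `guardrails`.
#' @export
build_qc_report <- function(run) {
  prof <- run$profile %>%
    group_by(.data$rpos) %>%
    summarise(t_coverage = sum(.data$t_coverage),
              tc_count = sum(.data$tc_count), .groups = "drop") %>%
    mutate(rate = .data$tc_count / .data$t_coverage)

  vf <- NULL
  if ("curve" %in% names(run$trim) && !is.null(run$trim$curve[[1]])) {
    curve <- run$trim$curve[[1]]
    fit <- run$trim$fit[[1]]
    vf <- list(rpos = curve$rpos, smoothed_sd = curve$smoothed_sd,
               sd = curve$sd,
               breakpoints = fit$breakpoints, n_segments = fit$n_segments,
               trim5 = run$trim$trim5[1], trim3 = run$trim$trim3[1])
  } else {
    vf <- list(rpos = integer(), smoothed_sd = numeric(), sd = numeric(),
               breakpoints = integer(), n_segments = NA_integer_,
               trim5 = run$trim$trim5[1], trim3 = run$trim$trim3[1])
  }

  sh <- if (!is.null(run$knee) && !is.null(run$knee$histogram)) {
    list(bin_lower = run$knee$histogram$bin_lower,
         count = run$knee$histogram$count,
         threshold = run$knee$threshold, raw_knee = run$knee$raw_knee,
         strength = run$knee$strength)
  } else {
    list(bin_lower = numeric(), count = integer(),
         threshold = run$knee$threshold %||% NA_real_,
         raw_knee = NA_real_, strength = NA_real_)
  }

  qn <- stats::quantile(run$ntr$ntr_mean, c(0, 0.25, 0.5, 0.75, 1),
                        na.rm = TRUE)
  ntr_summary <- list(
    n_genes = nrow(run$ntr),
    n_quantified = sum(!run$ntr$low_coverage),
    ntr_mean_quantiles = as.list(setNames(unname(qn),
                                          c("min", "q25", "median", "q75",
                                            "max"))),
    histogram = {
      h <- graphics::hist(run$ntr$ntr_mean, breaks = seq(0, 1, by = 0.05),
                          plot = FALSE)
      list(bin_lower = h$breaks[-length(h$breaks)], count = h$counts)
    }
  )

  guardrails <- list(
    snp_fallback_used = isTRUE(run$knee$fallback_used),
    snp_fallback_value = 0.22,
    snp_threshold_clamped = isTRUE(run$knee$clamped),
    snp_threshold = run$knee$threshold %||% NA_real_,
    trim_capped = FALSE,
    mask_sources = as.list(run$manifest$mask_sources),
    rate_source = run$rates$source
  )

  structure(list(per_position_rates = list(rpos = prof$rpos,
                                           t_coverage = prof$t_coverage,
                                           tc_count = prof$tc_count,
                                           rate = prof$rate),
                 variance_fit = vf,
                 snp_histogram = sh,
                 ntr_summary = ntr_summary,
                 guardrails = guardrails),
            class = "qc_report")
}

#' Write the QC report
#'
#' The JSON report is always written and is self-contained (all arrays
#' inline). The optional HTML report is a single file with inline styles,
#' data and SVG charts — it references no external resources and opens
#' without network access.
#'
#' @param qc A `qc_report`.
#' @param json_path Output JSON path.
#' @param html Optional output HTML path.
#' @return `json_path`, invisibly.
#' @export
write_qc <- function(qc, json_path, html = NULL) {
  jsonlite::write_json(unclass(qc), json_path, auto_unbox = TRUE,
                       pretty = TRUE, null = "null", na = "null", digits = NA)
  if (!is.null(html)) write_qc_html(qc, html)
  invisible(json_path)
}

# minimal dependency-free inline SVG line/bar chart builders
svg_chart <- function(xs, ys, width = 640, height = 200, pad = 30,
                      kind = c("line", "bar"), vlines = numeric(0),
                      title = "") {
  kind <- match.arg(kind)
  ok <- is.finite(xs) & is.finite(ys)
  xs <- xs[ok]; ys <- ys[ok]
  if (length(xs) == 0L) {
    return(paste0("<p><em>", title, ": no data</em></p>"))
  }
  xr <- range(xs); yr <- range(c(0, ys))
  if (diff(xr) == 0) xr <- xr + c(-0.5, 0.5)
  if (diff(yr) == 0) yr <- yr + c(0, 1)
  sx <- function(x) pad + (x - xr[1]) / diff(xr) * (width - 2 * pad)
  sy <- function(y) height - pad - (y - yr[1]) / diff(yr) * (height - 2 * pad)
  body <- if (kind == "line") {
    pts <- paste(sprintf("%.1f,%.1f", sx(xs), sy(ys)), collapse = " ")
    sprintf('<polyline fill="none" stroke="#2166ac" stroke-width="1.5" points="%s"/>', pts)
  } else {
    bw <- (width - 2 * pad) / max(length(xs), 1)
    paste(sprintf('<rect x="%.1f" y="%.1f" width="%.1f" height="%.1f" fill="#2166ac"/>',
                  sx(xs) - bw / 2, sy(ys), bw * 0.9, sy(yr[1]) - sy(ys)),
          collapse = "")
  }
  vl <- paste(sprintf('<line x1="%.1f" y1="%d" x2="%.1f" y2="%d" stroke="#b2182b" stroke-dasharray="4 3"/>',
                      sx(vlines), pad, sx(vlines), height - pad),
              collapse = "")
  sprintf(paste0('<h3>%s</h3><svg viewBox="0 0 %d %d" width="%d" height="%d">',
                 '<rect x="%d" y="%d" width="%d" height="%d" fill="none" stroke="#999"/>',
                 '%s%s</svg>'),
          title, width, height, width, height, pad, pad,
          width - 2 * pad, height - 2 * pad, body, vl)
}

write_qc_html <- function(qc, path) {
  pr <- qc$per_position_rates
  vf <- qc$variance_fit
  sh <- qc$snp_histogram
  nh <- qc$ntr_summary$histogram
  parts <- c(
    "<!DOCTYPE html><html><head><meta charset='utf-8'>",
    "<title>SLAM QC report</title>",
    "<style>body{font-family:sans-serif;max-width:720px;margin:2em auto}</style>",
    "</head><body><h1>SLAM QC report</h1>",
    svg_chart(pr$rpos, pr$rate, kind = "line",
              vlines = c(vf$trim5 - 0.5,
                         max(pr$rpos %enull% 0) - vf$trim3 + 0.5),
              title = "Per-position T&gt;C conversion rate"),
    svg_chart(vf$rpos, vf$smoothed_sd, kind = "line",
              vlines = vf$breakpoints,
              title = "Auto-trim variance curve (smoothed SD, fitted breakpoints)"),
    svg_chart(sh$bin_lower, log1p(sh$count), kind = "bar",
              vlines = sh$threshold,
              title = "SNP mismatch-fraction histogram (log1p counts, threshold)"),
    svg_chart(nh$bin_lower, nh$count, kind = "bar",
              title = "Per-gene NTR distribution"),
    "<h3>Guardrails</h3><pre>",
    jsonlite::toJSON(qc$guardrails, auto_unbox = TRUE, pretty = TRUE,
                     null = "null", na = "null"),
    "</pre></body></html>"
  )
  writeLines(paste(parts, collapse = "\n"), path)
  invisible(path)
}
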