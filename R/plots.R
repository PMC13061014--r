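#' @importFrom ggplot2 ggplot aes geom_line geom_col geom_point geom_vline
#'   geom_hline labs theme_minimal autoplot geom_abline geom_errorbar
NULL

#' Plot the per-position conversion-rate profile
#'
#' @param profile Chunked profile from [conversion_profile()] (chunks are
#'   pooled for display).
#' @param trim Optional `trim_spec` to annotate the trim window.
#' @return A ggplot.
#' @export
plot_conversion_profile <- function(profile, trim = NULL) {
  d <- profile %>%
    group_by(.data$rpos) %>%
    summarise(rate = sum(.data$tc_count) / sum(.data$t_coverage),
              .groups = "drop")
  p <- ggplot(d, aes(x = .data$rpos, y = .data$rate)) +
    geom_line(colour = "#2166ac") +
    labs(x = "read position (5' to 3')", y = "T>C conversion rate") +
    theme_minimal()
  if (!is.null(trim)) {
    L <- max(d$rpos) + 1L
    cuts <- c(if (trim$trim5 > 0) trim$trim5 - 0.5,
              if (trim$trim3 > 0) L - trim$trim3 - 0.5)
    if (length(cuts)) p <- p + geom_vline(xintercept = cuts,
                                          linetype = "dashed",
                                          colour = "#b2182b")
  }
  p
}

#' @rdname compute_variance_curve
#' @param object A `variance_curve`.
#' @param ... Optionally `fit =` a `trim_fit` whose breakpoints to annotate.
#' @method autoplot variance_curve
#' @export
autoplot.variance_curve <- function(object, ...) {
  dots <- list(...)
  p <- ggplot(as_tibble(object), aes(x = .data$rpos, y = .data$smoothed_sd)) +
    geom_line(colour = "#2166ac") +
    geom_point(aes(y = .data$sd), size = 0.5, alpha = 0.4) +
    labs(x = "read position", y = "SD of conversion rate across chunks") +
    theme_minimal()
  if (!is.null(dots$fit)) {
    p <- p + geom_vline(xintercept = dots$fit$breakpoints,
                        linetype = "dashed", colour = "#b2182b")
  }
  p
}

#' @rdname detect_snp_threshold
#' @param object A `knee_result`.
#' @method autoplot knee_result
#' @export
autoplot.knee_result <- function(object, ...) {
  h <- object$histogram
  ggplot(h, aes(x = .data$bin_lower, y = log1p(.data$count))) +
    geom_col(width = min(diff(h$bin_lower)), fill = "#2166ac") +
    geom_vline(xintercept = object$threshold, linetype = "dashed",
               colour = "#b2182b") +
    labs(x = "T>C mismatch fraction", y = "log1p(site count)",
         subtitle = sprintf("threshold %.3g%s%s", object$threshold,
                            if (object$fallback_used) " (fallback)" else "",
                            if (object$clamped) " (clamped)" else "")) +
    theme_minimal()
}

#' @rdname estimate_ntr
#' @param object An `ntr_fit`.
#' @method autoplot ntr_fit
#' @export
autoplot.ntr_fit <- function(object, ...) {
  d <- as_tibble(object)
  ggplot(d, aes(x = .data$ntr_mean)) +
    ggplot2::geom_histogram(breaks = seq(0, 1, by = 0.05), fill = "#2166ac") +
    labs(x = "NTR (posterior mean)", y = "genes") +
    theme_minimal()
}

#' Plot estimated against true NTR
#'
#' Convenience for simulated data: posterior mean with 5/95% credible bars
#' against the planted per-gene NTR.
#'
#' @param ntr An `ntr_fit`.
#' @param truth Tibble with `gene_id`, `true_pi`.
#' @return A ggplot.
#' @export
plot_ntr_recovery <- function(ntr, truth) {
  d <- as_tibble(ntr) %>% inner_join(truth, by = "gene_id")
  ggplot(d, aes(x = .data$true_pi, y = .data$ntr_mean)) +
    geom_abline(slope = 1, intercept = 0, colour = "grey60") +
    geom_errorbar(aes(ymin = .data$ntr_q05, ymax = .data$ntr_q95),
                  width = 0, colour = "#2166ac", alpha = 0.6) +
    geom_point(colour = "#2166ac") +
    labs(x = "true NTR", y = "estimated NTR (mean, 5-95% CrI)") +
    theme_minimal()
}
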