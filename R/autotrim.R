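#' Per-position conversion-rate variance curve
#'
#' Computes, for every read position, the sample standard deviation of the
#' T>C conversion rate across read chunks, then smooths it with a centred
#' moving average (truncated at the edges). The SD across round-robin chunks
#' estimates the sampling variability of the per-position rate; artifact-prone
#' read ends show elevated and unstable rates.
#'
#' The smoothing window defaults to 3: a centred average wide enough to damp
#' chunk noise while smearing a sharp artifact boundary by at most one
#' position, which keeps the fitted knee within the resolution the trim rule
#' needs.
#'
#' @param profile Chunked profile from [conversion_profile()] (needs >= 2
#'   chunks with data).
#' @param window Moving-average width (default 3).
#' @return A `variance_curve` tibble: `rpos`, `n_chunks` (chunks with T
#'   coverage), `rate_mean`, `sd`, `smoothed_sd`.
#' @export
compute_variance_curve <- function(profile, window = 3L) {
  n_chunks <- length(unique(profile$chunk))
  if (n_chunks < 2L) {
    abort(paste0("variance curve needs >= 2 read chunks (got ", n_chunks,
                 "); lower the chunk size or supply more reads"))
  }
  curve <- profile %>%
    mutate(rate = .data$tc_count / .data$t_coverage) %>%
    group_by(.data$rpos) %>%
    summarise(n_chunks = dplyr::n(),
              rate_mean = mean(.data$rate),
              sd = if (dplyr::n() >= 2L) stats::sd(.data$rate) else NA_real_,
              .groups = "drop") %>%
    arrange(.data$rpos)
  curve$smoothed_sd <- moving_average(curve$sd, window)
  attr(curve, "window") <- as.integer(window)
  class(curve) <- c("variance_curve", class(curve))
  curve
}

# centred moving average with truncated windows at the edges; NAs excluded
moving_average <- function(x, window) {
  n <- length(x)
  half <- (window - 1L) %/% 2L
  vapply(seq_len(n), function(i) {
    lo <- max(1L, i - half); hi <- min(n, i + half)
    mean(x[lo:hi], na.rm = TRUE)
  }, numeric(1))
}

#' Fit a BIC-selected continuous piecewise-linear model to the variance curve
#'
#' For each candidate segment count m in `segment_counts`, fits a continuous
#' piecewise-linear function with m segments by exhaustive search over
#' integer breakpoints minimising the residual sum of squares on
#' `smoothed_sd`, then selects m by BIC with parameter count `k_m = 2m`
#' (m + 1 node values plus m - 1 breakpoints):
#' `BIC_m = n log(RSS_m / n) + k_m log(n)`.
#'
#' For long curves the breakpoint grid is thinned to at most `max_candidates`
#' positions and the best placement refined locally, so the search stays
#' exhaustive for curves up to `max_candidates` positions.
#'
#' @param curve A `variance_curve` (or any tibble with `rpos`,
#'   `smoothed_sd`).
#' @param segment_counts Candidate numbers of segments (subset of 2:4).
#' @param max_candidates Breakpoint-grid cap before local refinement.
#' @return A `trim_fit` object: `breakpoints` (integer read positions),
#'   `n_segments`, `bic` (named per m), `rss`, `fitted` tibble, `n`.
#' @export
fit_piecewise <- function(curve, segment_counts = 2:4, max_candidates = 60L) {
  ok <- !is.na(curve$smoothed_sd)
  x <- curve$rpos[ok]
  y <- curve$smoothed_sd[ok]
  n <- length(x)
  if (n < 10L) {
    warn("variance curve shorter than 10 positions; returning zero-trim fit")
    return(structure(list(breakpoints = integer(), n_segments = 1L,
                          bic = setNames(numeric(0), character(0)),
                          rss = NA_real_,
                          fitted = tibble(rpos = x, fitted = y), n = n,
                          degenerate = TRUE),
                     class = "trim_fit"))
  }
  segment_counts <- sort(intersect(segment_counts, 2:4))
  stopifnot(length(segment_counts) > 0L)

  fits <- purrr::map(segment_counts, function(m) {
    best_piecewise_m(x, y, m, max_candidates)
  })
  bic <- vapply(seq_along(fits), function(i) {
    m <- segment_counts[i]
    k_m <- 2 * m
    rss <- max(fits[[i]]$rss, 1e-300)
    n * log(rss / n) + k_m * log(n)
  }, numeric(1))
  names(bic) <- paste0("m", segment_counts)
  sel <- which.min(bic)
  best <- fits[[sel]]
  structure(list(breakpoints = best$breakpoints,
                 n_segments = segment_counts[sel],
                 bic = bic, rss = best$rss,
                 fitted = tibble(rpos = x, fitted = best$fitted),
                 n = n, degenerate = FALSE),
            class = "trim_fit")
}

# RSS of a continuous piecewise-linear fit with given interior breakpoints,
# via a linear basis {1, x, (x - b)+}
pwl_fit <- function(x, y, bps) {
  X <- cbind(1, x)
  for (b in bps) X <- cbind(X, pmax(x - b, 0))
  f <- lm.fit(X, y)
  list(rss = sum(f$residuals^2), fitted = as.numeric(X %*% f$coefficients))
}

# exhaustive search over breakpoint placements for m segments (m - 1
# breakpoints), with optional grid thinning + local refinement for long curves
best_piecewise_m <- function(x, y, m, max_candidates = 60L) {
  n <- length(x)
  # interior candidate breakpoints: at least 2 positions on each flank
  cand_all <- x[seq(3L, n - 2L)]
  if (m == 2L && length(cand_all) == 0L) cand_all <- x[2L]
  thin <- length(cand_all) > max_candidates
  cand <- if (thin) {
    unique(round(seq(min(cand_all), max(cand_all), length.out = max_candidates)))
  } else cand_all
  best <- search_breakpoints(x, y, m, cand)
  if (thin && length(best$breakpoints) > 0L) {
    stride <- max(1L, ceiling(length(cand_all) / max_candidates))
    refined <- unique(sort(unlist(lapply(best$breakpoints, function(b) {
      cand_all[abs(cand_all - b) <= stride]
    }))))
    best2 <- search_breakpoints(x, y, m, refined)
    if (best2$rss < best$rss) best <- best2
  }
  best
}

search_breakpoints <- function(x, y, m, cand) {
  n_bp <- m - 1L
  if (length(cand) < n_bp) {
    f <- pwl_fit(x, y, integer(0))
    return(list(breakpoints = integer(), rss = f$rss, fitted = f$fitted))
  }
  combos <- utils::combn(cand, n_bp)
  # drop placements with segments shorter than 2 positions
  if (n_bp > 1L) {
    keep <- apply(combos, 2, function(b) all(diff(b) >= 2))
    combos <- combos[, keep, drop = FALSE]
  }
  best_rss <- Inf; best_bp <- integer(); best_fit <- NULL
  for (j in seq_len(ncol(combos))) {
    bp <- combos[, j]
    f <- pwl_fit(x, y, bp)
    if (f$rss < best_rss - 1e-15) {
      best_rss <- f$rss; best_bp <- bp; best_fit <- f$fitted
    }
  }
  list(breakpoints = as.integer(best_bp), rss = best_rss, fitted = best_fit)
}

#' @export
print.trim_fit <- function(x, ...) {
  cat("<trim_fit> ", x$n_segments, " segments, breakpoints at [",
      paste(x$breakpoints, collapse = ", "), "], RSS = ",
      format(x$rss), "\n", sep = "")
  invisible(x)
}

#' @rdname fit_piecewise
#' @param x A `trim_fit`.
#' @param ... Unused.
#' @method glance trim_fit
#' @export
glance.trim_fit <- function(x, ...) {
  tibble(n_segments = x$n_segments, rss = x$rss, n = x$n,
         breakpoints = paste(x$breakpoints, collapse = ","),
         bic_selected = unname(x$bic[paste0("m", x$n_segments)]))
}

#' Derive 5'/3' trim lengths from a piecewise fit
#'
#' The fitted piecewise-linear curve defines the artifact boundaries: the
#' baseline is the median fitted value over the middle half of the read, and
#' `trim5` is the number of leading positions whose fitted value exceeds
#' `elevation_factor` times that baseline (the point where the fitted curve
#' descends through the elevation threshold); symmetrically for `trim3` at
#' the 3' end. A non-zero trim is then padded by the smoothing half-window,
#' since the moving average spreads an artifact boundary into its
#' neighbours: an under-trim leaks artifact conversions into every
#' downstream estimate, while an extra clean position costs almost nothing.
#' Neither trim can pass the curve midpoint, and a flat fit yields zero
#' trim. A safety cap rejects trims with `trim5 + trim3 > L / 2` (zero-trim
#' returned, warning flag set).
#'
#' @param fit A `trim_fit`.
#' @param curve The `variance_curve` the fit was computed on.
#' @param elevation_factor Relative elevation needed to trim (default 1.5).
#' @return A `trim_spec` tibble row: `trim5`, `trim3`, `n_segments`,
#'   `breakpoints` (list-col), `capped` (safety-cap warning flag).
#' @export
derive_trim <- function(fit, curve, elevation_factor = 1.5) {
  L <- max(curve$rpos) + 1L
  halfwin <- (attr(curve, "window") %||% 1L) %/% 2L
  zero <- tibble(trim5 = 0L, trim3 = 0L, n_segments = fit$n_segments,
                 breakpoints = list(fit$breakpoints), capped = FALSE)
  if (nrow(fit$fitted) == 0L) return(new_trim_spec(zero))
  x <- fit$fitted$rpos
  yf <- fit$fitted$fitted
  mid_lo <- stats::quantile(x, 0.25); mid_hi <- stats::quantile(x, 0.75)
  baseline <- stats::median(yf[x >= mid_lo & x <= mid_hi])
  thr <- elevation_factor * baseline
  elevated <- yf > thr
  half <- length(x) %/% 2L

  lead5 <- 0L
  for (i in seq_len(half)) {
    if (elevated[i]) lead5 <- i else break
  }
  trim5 <- if (lead5 > 0L) x[lead5] + 1L + halfwin else 0L

  lead3 <- 0L
  nx <- length(x)
  for (i in seq_len(half)) {
    if (elevated[nx - i + 1L]) lead3 <- i else break
  }
  trim3 <- if (lead3 > 0L) L - x[nx - lead3 + 1L] + halfwin else 0L

  if (trim5 + trim3 > L / 2) {
    warn("derived trim exceeds half the read length; returning zero-trim")
    zero$capped <- TRUE
    return(new_trim_spec(zero))
  }
  new_trim_spec(tibble(trim5 = as.integer(trim5), trim3 = as.integer(trim3),
                       n_segments = fit$n_segments,
                       breakpoints = list(fit$breakpoints), capped = FALSE))
}

new_trim_spec <- function(tbl) {
  class(tbl) <- c("trim_spec", class(tbl))
  tbl
}

#' One-call variance-based auto-trim
#'
#' Convenience wrapper: variance curve, BIC piecewise fit, trim derivation.
#'
#' @param profile Chunked conversion profile.
#' @param window Smoothing window.
#' @param segment_counts Candidate segment counts.
#' @param elevation_factor Elevation factor for [derive_trim()].
#' @return A `trim_spec` with the fit and curve attached as attributes
#'   `fit` and `curve`.
#' @export
auto_trim <- function(profile, window = 3L, segment_counts = 2:4,
                      elevation_factor = 1.5) {
  curve <- compute_variance_curve(profile, window = window)
  fit <- fit_piecewise(curve, segment_counts = segment_counts)
  spec <- derive_trim(fit, curve, elevation_factor = elevation_factor)
  attr(spec, "fit") <- fit
  attr(spec, "curve") <- curve
  spec
}
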