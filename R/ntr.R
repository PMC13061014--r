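#' Estimate the global conversion rates
#'
#' Background modeling for the binomial mixture. The background rate `p_old`
#' (T>C observed in pre-existing RNA) and the labeled-RNA conversion rate
#' `p_new` are estimated jointly by EM on the pooled per-read (n, k) pairs
#' under a two-component binomial mixture, with a free global mixing weight
#' as a nuisance parameter. The pooled rate of a control substitution class
#' at sense-strand T sites (T>G by default, or the mean of both non-T>C
#' classes) initialises `p_old` and serves as its lower floor: the T>C
#' background can exceed the control class (chemistry-specific effects) but
#' not undercut it. `p_old_mode = "control"` instead holds `p_old` fixed at
#' the control-class rate. User overrides short-circuit estimation.
#'
#' @param read_counts Per-read counts from [read_conversion_counts()].
#' @param sites Site table from [site_table()] (needed unless `p_old` given).
#' @param p_old,p_new Optional user overrides.
#' @param control_class `"tg"` (default) or `"mean_non_tc"`.
#' @param p_old_mode `"em"` (default: control class initialises and floors a
#'   free background rate) or `"control"` (background fixed at the
#'   control-class rate).
#' @param tol,max_iter EM convergence controls.
#' @return A `global_rates` object (list): `p_old`, `p_new`, `pi_global`,
#'   `source` (`"estimated"` or `"user"`), `iterations`, `converged`.
#' @export
estimate_global_rates <- function(read_counts, sites = NULL,
                                  p_old = NULL, p_new = NULL,
                                  control_class = c("tg", "mean_non_tc"),
                                  p_old_mode = c("em", "control"),
                                  tol = 1e-8, max_iter = 500L) {
  control_class <- match.arg(control_class)
  p_old_mode <- match.arg(p_old_mode)
  if (!is.null(p_old) && !is.null(p_new)) {
    if (p_new <= p_old) abort("p_new must exceed p_old")
    return(structure(list(p_old = p_old, p_new = p_new,
                          pi_global = NA_real_, source = "user",
                          iterations = 0L, converged = TRUE),
                     class = "global_rates"))
  }
  p_old_free <- FALSE
  p_old_control <- NA_real_
  if (is.null(p_old)) {
    if (is.null(sites)) abort("site table needed to estimate p_old")
    cov_tot <- sum(sites$coverage)
    if (cov_tot == 0) abort("empty site table; cannot estimate p_old")
    p_old <- if (control_class == "tg") {
      sum(sites$tg_count) / cov_tot
    } else {
      (sum(sites$tg_count) + sum(sites$ta_count)) / (2 * cov_tot)
    }
    # a zero control-class rate gives dbinom mass 0 for any k > 0; floor at
    # one pseudo-event over the pooled coverage
    p_old <- max(p_old, 1 / (2 * cov_tot))
    p_old_control <- p_old
    p_old_free <- p_old_mode == "em"
  }

  rc <- read_counts %>% filter(.data$n_T > 0)
  if (nrow(rc) == 0L) abort("no informative reads for rate estimation")
  k <- rc$k; n <- rc$n_T; w <- rc$weight

  if (is.null(p_new)) {
    # EM with free (pi, p_new) and, in "em" background mode, free p_old
    # floored at the control-class rate
    p_old_floor <- p_old
    pi_g <- 0.1
    p_new_hat <- max(5 * p_old, min(0.5, sum(w * k) / sum(w * n) * 2))
    converged <- FALSE
    it <- 0L
    for (it in seq_len(max_iter)) {
      lf0 <- dbinom(k, n, p_old, log = TRUE)
      lf1 <- dbinom(k, n, p_new_hat, log = TRUE)
      la <- log(pi_g) + lf1
      lb <- log1p(-pi_g) + lf0
      g <- 1 / (1 + exp(lb - la))
      pi_new <- sum(w * g) / sum(w)
      denom <- sum(w * g * n)
      p_cand <- if (denom > 0) sum(w * g * k) / denom else p_new_hat
      delta <- max(abs(pi_new - pi_g), abs(p_cand - p_new_hat))
      if (p_old_free) {
        denom0 <- sum(w * (1 - g) * n)
        p0_cand <- if (denom0 > 0) sum(w * (1 - g) * k) / denom0 else p_old
        p0_cand <- min(max(p0_cand, p_old_floor), 1 - 1e-12)
        delta <- max(delta, abs(p0_cand - p_old))
        p_old <- p0_cand
      }
      pi_g <- min(max(pi_new, 1e-12), 1 - 1e-12)
      p_new_hat <- min(max(p_cand, 1e-12), 1 - 1e-12)
      if (delta < tol) { converged <- TRUE; break }
    }
    if (p_new_hat <= p_old) {
      abort(paste0("estimated p_new (", signif(p_new_hat, 4),
                   ") does not exceed p_old (", signif(p_old, 4),
                   "); no labeling signal detected - supply --p-old/--p-new"))
    }
    return(structure(list(p_old = p_old, p_new = p_new_hat, pi_global = pi_g,
                          p_old_floor = p_old_control,
                          source = "estimated", iterations = it,
                          converged = converged),
                     class = "global_rates"))
  }
  if (p_new <= p_old) abort("p_new must exceed p_old")
  structure(list(p_old = p_old, p_new = p_new, pi_global = NA_real_,
                 source = "user", iterations = 0L, converged = TRUE),
            class = "global_rates")
}

#' Refine global rates jointly with per-gene mixing weights
#'
#' One shared (p_old, p_new) pair with an independent mixing weight per gene
#' is the generative model for pooled multi-gene data; estimating the rates
#' under a single pooled mixing weight (as [estimate_global_rates()] does)
#' leaves a small bias when NTRs vary across genes. This EM alternates
#' per-gene E-steps with pooled rate M-steps, starting from `rates`.
#' `p_old` stays floored at its initial value when that came from the
#' control substitution class.
#'
#' @param gene_counts Per-gene counts from [aggregate_gene_counts()].
#' @param rates Initial `global_rates` (its `p_old` is used as the floor).
#' @param tol Convergence tolerance on the rate updates.
#' @param max_outer Maximum outer iterations.
#' @return A refined `global_rates` object (source `"estimated"`).
#' @export
refine_global_rates <- function(gene_counts, rates, tol = 1e-7,
                                max_outer = 50L) {
  stopifnot(inherits(rates, "global_rates"))
  reads <- gene_counts %>%
    select("gene_id", "reads") %>%
    tidyr::unnest("reads") %>%
    filter(.data$n_T > 0)
  if (nrow(reads) == 0L) return(rates)
  gidx <- match(reads$gene_id, unique(reads$gene_id))
  k <- reads$k; n <- reads$n_T; w <- reads$weight
  ng <- max(gidx)
  pi_g <- rep(0.1, ng)
  p_old <- rates$p_old; p_new <- rates$p_new
  floor0 <- rates$p_old_floor %||% rates$p_old
  if (!is.finite(floor0)) floor0 <- rates$p_old
  converged <- FALSE
  for (it in seq_len(max_outer)) {
    lf1 <- dbinom(k, n, p_new, log = TRUE)
    lf0 <- dbinom(k, n, p_old, log = TRUE)
    # several inner E/M cycles on the per-gene weights at fixed rates
    for (j in 1:25) {
      la <- log(pi_g[gidx]) + lf1
      lb <- log1p(-pi_g[gidx]) + lf0
      g <- 1 / (1 + exp(lb - la))
      pi_new_g <- vapply(seq_len(ng), function(gi) {
        sel <- gidx == gi
        sum(w[sel] * g[sel]) / sum(w[sel])
      }, numeric(1))
      if (max(abs(pi_new_g - pi_g)) < 1e-8) { pi_g <- pi_new_g; break }
      pi_g <- clamp(pi_new_g, 1e-12, 1 - 1e-12)
    }
    p_new_next <- sum(w * g * k) / max(sum(w * g * n), 1e-300)
    p_old_next <- sum(w * (1 - g) * k) / max(sum(w * (1 - g) * n), 1e-300)
    p_old_next <- min(max(p_old_next, floor0), 1 - 1e-12)
    p_new_next <- min(max(p_new_next, 1e-12), 1 - 1e-12)
    delta <- max(abs(p_new_next - p_new), abs(p_old_next - p_old))
    p_new <- p_new_next; p_old <- p_old_next
    if (delta < tol) { converged <- TRUE; break }
  }
  if (p_new <= p_old) return(rates)
  structure(list(p_old = p_old, p_new = p_new,
                 pi_global = sum(w * g) / sum(w), p_old_floor = floor0,
                 source = "estimated",
                 iterations = it, converged = converged),
            class = "global_rates")
}

#' @export
print.global_rates <- function(x, ...) {
  cat("<global_rates> p_old = ", signif(x$p_old, 4), ", p_new = ",
      signif(x$p_new, 4), " (", x$source, ")\n", sep = "")
  invisible(x)
}

# EM for one gene: returns list(pi, gamma_sum, w_sum, iterations, converged,
# loglik_trace)
gene_em <- function(k, n, w, p_new, p_old, tol = 1e-8, max_iter = 1000L,
                    pi_init = 0.1, trace = FALSE) {
  lf1 <- dbinom(k, n, p_new, log = TRUE)
  lf0 <- dbinom(k, n, p_old, log = TRUE)
  pi_hat <- pi_init
  converged <- FALSE
  ll_trace <- if (trace) numeric(max_iter) else NULL
  g <- rep(pi_hat, length(k))
  it <- 0L
  for (it in seq_len(max_iter)) {
    la <- log(pi_hat) + lf1
    lb <- log1p(-pi_hat) + lf0
    g <- 1 / (1 + exp(lb - la))
    if (trace) ll_trace[it] <- sum(w * log_add(la, lb))
    pi_new <- sum(w * g) / sum(w)
    if (abs(pi_new - pi_hat) < tol) {
      pi_hat <- pi_new
      converged <- TRUE
      if (trace) ll_trace <- ll_trace[seq_len(it)]
      break
    }
    pi_hat <- min(max(pi_new, 1e-12), 1 - 1e-12)
  }
  if (!converged && trace) ll_trace <- ll_trace[seq_len(it)]
  # final responsibilities at the converged pi
  la <- log(pi_hat) + lf1
  lb <- log1p(-pi_hat) + lf0
  g <- 1 / (1 + exp(lb - la))
  list(pi = pi_hat, gamma = g, gamma_sum = sum(w * g), w_sum = sum(w),
       iterations = it, converged = converged, loglik = ll_trace)
}

# Beta(alpha, beta) fitted by moment matching to the exact posterior of pi
# on a uniform grid (uniform prior); falls back to supplied effective-count
# parameters if the posterior is numerically degenerate
beta_posterior <- function(k, n, w, p_new, p_old, grid_n = 1001L,
                           fallback_alpha = 1, fallback_beta = 1) {
  grid <- seq(0, 1, length.out = grid_n)
  f1 <- dbinom(k, n, p_new)
  f0 <- dbinom(k, n, p_old)
  # log posterior at each grid point (uniform prior)
  ll <- vapply(grid, function(p) {
    sum(w * log(p * f1 + (1 - p) * f0))
  }, numeric(1))
  ll[!is.finite(ll)] <- -Inf
  if (all(ll == -Inf)) {
    return(list(alpha = fallback_alpha, beta = fallback_beta))
  }
  pw <- exp(ll - max(ll))
  pw <- pw / sum(pw)
  m1 <- sum(pw * grid)
  v <- sum(pw * grid^2) - m1^2
  # moment matching needs 0 < v < m1(1 - m1)
  if (!is.finite(v) || v <= 0 || v >= m1 * (1 - m1)) {
    return(list(alpha = fallback_alpha, beta = fallback_beta))
  }
  nu <- m1 * (1 - m1) / v - 1
  list(alpha = m1 * nu, beta = (1 - m1) * nu)
}

beta_map <- function(alpha, beta) {
  if (alpha > 1 && beta > 1) (alpha - 1) / (alpha + beta - 2)
  else if (alpha <= 1 && beta > 1) 0
  else if (alpha > 1 && beta <= 1) 1
  else alpha / (alpha + beta)  # alpha = beta = 1 (or both <= 1): use mean
}

#' Estimate per-gene new-to-total RNA ratios
#'
#' Fits, for each gene, the two-component binomial mixture
#' \deqn{L(\pi) = \prod_i [\pi B(k_i; n_i, p_{new}) +
#'   (1-\pi) B(k_i; n_i, p_{old})]^{w_i}}
#' by EM on the mixing weight \eqn{\pi} (the NTR), then summarises
#' uncertainty with a Beta posterior under a uniform Beta(1, 1) prior: the
#' exact one-dimensional posterior over \eqn{\pi} is evaluated on a dense
#' grid and a Beta(\eqn{\alpha}, \eqn{\beta}) distribution is fitted to it
#' by moment matching, so `ntr_mean` equals the exact posterior mean and the
#' reported 0.05/0.95 quantiles carry the full origin uncertainty of the
#' reads (a Beta built from the EM's soft counts would understate it). The
#' posterior mode under the uniform prior is the EM estimate itself, and
#' `ntr_map` is the Beta mode \eqn{(\alpha-1)/(\alpha+\beta-2)}. Genes
#' with no informative reads (all \eqn{n_i = 0}) get the uniform posterior
#' Beta(1, 1) and `converged = FALSE`.
#'
#' @param gene_counts Per-gene counts from [aggregate_gene_counts()].
#' @param rates A `global_rates` object.
#' @param tol EM convergence tolerance on \eqn{|\Delta\pi|} (default 1e-8).
#' @param max_iter Maximum EM iterations (default 1000).
#' @param pi_init Initial mixing weight (default 0.1).
#' @return An `ntr_fit` tibble, one row per gene: `gene_id`, `gene_name`
#'   (when present), `read_count`, `K`, `N_T`, `alpha`, `beta`, `ntr_map`,
#'   `ntr_mean`, `ntr_q05`, `ntr_q95`, `em_iterations`, `converged`,
#'   `low_coverage`. The `global_rates` used are attached as attribute
#'   `rates`.
#' @export
estimate_ntr <- function(gene_counts, rates, tol = 1e-8, max_iter = 1000L,
                         pi_init = 0.1) {
  stopifnot(inherits(rates, "global_rates"))
  res <- purrr::pmap_dfr(
    list(gene_counts$gene_id, gene_counts$reads),
    function(gid, reads) {
      reads <- reads %>% filter(.data$n_T > 0)
      if (nrow(reads) == 0L) {
        alpha <- 1; beta <- 1
        return(tibble(gene_id = gid, alpha = alpha, beta = beta,
                      ntr_map = beta_map(alpha, beta),
                      ntr_mean = alpha / (alpha + beta),
                      ntr_q05 = qbeta(0.05, alpha, beta),
                      ntr_q95 = qbeta(0.95, alpha, beta),
                      em_iterations = 0L, converged = FALSE))
      }
      em <- gene_em(reads$k, reads$n_T, reads$weight,
                    p_new = rates$p_new, p_old = rates$p_old,
                    tol = tol, max_iter = max_iter, pi_init = pi_init)
      post <- beta_posterior(reads$k, reads$n_T, reads$weight,
                             p_new = rates$p_new, p_old = rates$p_old,
                             fallback_alpha = 1 + em$gamma_sum,
                             fallback_beta = 1 + em$w_sum - em$gamma_sum)
      tibble(gene_id = gid, alpha = post$alpha, beta = post$beta,
             ntr_map = beta_map(post$alpha, post$beta),
             ntr_mean = post$alpha / (post$alpha + post$beta),
             ntr_q05 = qbeta(0.05, post$alpha, post$beta),
             ntr_q95 = qbeta(0.95, post$alpha, post$beta),
             em_iterations = em$iterations, converged = em$converged)
    })
  keep <- intersect(c("gene_id", "gene_name", "read_count", "K", "N_T",
                      "low_coverage"), names(gene_counts))
  out <- gene_counts[, keep] %>% left_join(res, by = "gene_id")
  out <- out[, c(setdiff(names(out), "low_coverage"), "low_coverage")]
  attr(out, "rates") <- rates
  class(out) <- c("ntr_fit", class(out))
  out
}

#' @rdname estimate_ntr
#' @param x An `ntr_fit`.
#' @param ... Unused.
#' @method tidy ntr_fit
#' @export
tidy.ntr_fit <- function(x, ...) {
  out <- as_tibble(x)
  class(out) <- setdiff(class(out), "ntr_fit")
  out
}

#' @rdname estimate_ntr
#' @method glance ntr_fit
#' @export
glance.ntr_fit <- function(x, ...) {
  r <- attr(x, "rates")
  tibble(n_genes = nrow(x),
         n_quantified = sum(!x$low_coverage),
         p_old = r$p_old, p_new = r$p_new, rate_source = r$source,
         median_ntr = stats::median(x$ntr_mean[!x$low_coverage]))
}

grandslam_default_headers <- function() {
  p <- system.file("extdata", "grandslam_schema.json", package = "slamkit")
  jsonlite::fromJSON(p)
}

#' Write the NTR table
#'
#' Writes a tab-separated quantification table. The `native` schema uses the
#' package's own column names; the `grandslam` schema renames them to
#' GrandSLAM-style headers read from a JSON config (default shipped in
#' `inst/extdata/grandslam_schema.json`), so parity with a given GrandSLAM
#' version is adjustable without code changes.
#'
#' @param estimates An `ntr_fit`.
#' @param path Output path.
#' @param schema `"native"` or `"grandslam"`.
#' @param schema_config Optional path to a JSON mapping of native column ->
#'   output header for the grandslam schema.
#' @return The path, invisibly.
#' @export
write_ntr_table <- function(estimates, path,
                            schema = c("native", "grandslam"),
                            schema_config = NULL) {
  schema <- match.arg(schema)
  tbl <- tidy.ntr_fit(estimates)
  if (!"gene_name" %in% names(tbl)) tbl$gene_name <- tbl$gene_id
  native_cols <- c("gene_id", "gene_name", "read_count", "conversions",
                   "t_coverage", "ntr_map", "ntr_mean", "ntr_q05", "ntr_q95",
                   "alpha", "beta", "converged")
  tbl <- tbl %>%
    rename(conversions = "K", t_coverage = "N_T") %>%
    select(dplyr::all_of(native_cols))
  if (schema == "grandslam") {
    hdr <- if (is.null(schema_config)) grandslam_default_headers() else
      jsonlite::fromJSON(schema_config)
    tbl <- tbl[, names(hdr)]
    names(tbl) <- unname(unlist(hdr))
  }
  readr::write_tsv(tbl, path, progress = FALSE)
  invisible(path)
}
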