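# model-level gene_counts builder: R reads with n_T positions each, origins
# drawn Bernoulli(pi), conversions binomial at the origin's rate
sim_gene_counts <- function(pi, R = 500L, nT = 20L, p_new = 0.05,
                            p_old = 0.001, gene_id = "g") {
  z <- runif(R) < pi
  reads <- tibble::tibble(n_T = rep(nT, R),
                          k = rbinom(R, nT, ifelse(z, p_new, p_old)),
                          weight = 1)
  tibble::tibble(gene_id = gene_id, read_count = R,
                 K = sum(reads$k), N_T = sum(reads$n_T),
                 reads = list(reads), low_coverage = FALSE)
}

user_rates <- function(p_old = 0.001, p_new = 0.05) {
  estimate_global_rates(tibble::tibble(read_id = "r", gene_id = "g",
                                       n_T = 1L, k = 0L, weight = 1),
                        p_old = p_old, p_new = p_new)
}

test_that("global rates: user overrides pass through; pooled EM recovers the conversion rate", {
  r <- user_rates(0.001, 0.05)
  expect_equal(r$p_old, 0.001)
  expect_equal(r$p_new, 0.05)
  expect_equal(r$source, "user")
  expect_error(user_rates(0.05, 0.001), "exceed")

  set.seed(11)
  pool <- dplyr::bind_rows(lapply(1:40, function(g) {
    sim_gene_counts(runif(1), R = 500L)$reads[[1]]
  }))
  pool$read_id <- as.character(seq_len(nrow(pool)))
  pool$gene_id <- "pool"
  est <- estimate_global_rates(pool, p_old = 0.001)
  expect_gte(est$p_new, 0.045)
  expect_lte(est$p_new, 0.055)
  expect_equal(est$source, "estimated")

  # no conversions anywhere: estimation must refuse rather than invent a rate
  zero <- tibble::tibble(read_id = as.character(1:100), gene_id = "g",
                         n_T = 20L, k = 0L, weight = 1)
  expect_error(estimate_global_rates(zero, p_old = 0.001), "labeling")
})

test_that("a gene with no informative reads gets the uniform posterior", {
  gc <- tibble::tibble(gene_id = "g", read_count = 0, K = 0, N_T = 0,
                       reads = list(tibble::tibble(n_T = integer(),
                                                   k = integer(),
                                                   weight = double())),
                       low_coverage = TRUE)
  est <- estimate_ntr(gc, user_rates())
  expect_equal(est$alpha, 1)
  expect_equal(est$beta, 1)
  expect_equal(est$ntr_mean, 0.5)
  expect_equal(est$ntr_q05, 0.05)
  expect_equal(est$ntr_q95, 0.95)
  expect_false(est$converged)
})

test_that("posterior summaries obey the Beta identities and bracket the EM estimate", {
  set.seed(21)
  gc <- dplyr::bind_rows(lapply(c(0.1, 0.4, 0.8), function(p) {
    sim_gene_counts(p, gene_id = sprintf("g%.1f", p))
  }))
  est <- estimate_ntr(gc, user_rates())
  expect_equal(est$ntr_mean, est$alpha / (est$alpha + est$beta))
  expect_equal(est$ntr_map,
               (est$alpha - 1) / (est$alpha + est$beta - 2))
  expect_true(all(est$ntr_q05 <= est$ntr_q95))
  expect_true(all(est$ntr_q05 >= 0 & est$ntr_q95 <= 1))
  # the posterior mode tracks the EM/MLE point estimate
  for (i in seq_len(nrow(gc))) {
    em <- slamkit:::gene_em(gc$reads[[i]]$k, gc$reads[[i]]$n_T,
                            gc$reads[[i]]$weight, 0.05, 0.001)
    expect_lt(abs(est$ntr_map[i] - em$pi), 0.01)
  }
})

test_that("EM agrees with an exhaustive likelihood grid search on every simulated gene", {
  set.seed(13)
  for (pi in c(0.05, 0.4, 0.7, 0.95)) {
    gc <- sim_gene_counts(pi)
    r <- gc$reads[[1]]
    em <- slamkit:::gene_em(r$k, r$n_T, r$weight, 0.05, 0.001)
    grid <- oracle_grid_pi(r$k, r$n_T, r$weight, 0.05, 0.001)
    expect_lte(abs(em$pi - grid), 1e-3)
  }
})

test_that("the EM log-likelihood is non-decreasing at every iteration", {
  set.seed(17)
  for (pi in c(0.1, 0.5, 0.9)) {
    r <- sim_gene_counts(pi, R = 200L)$reads[[1]]
    em <- slamkit:::gene_em(r$k, r$n_T, r$weight, 0.05, 0.001, trace = TRUE)
    expect_true(all(diff(em$loglik) >= -1e-9))
  }
})

test_that("boundary NTRs and label symmetry behave as the mixture implies", {
  set.seed(29)
  for (s in 1:10) {
    lo <- estimate_ntr(sim_gene_counts(0), user_rates())
    hi <- estimate_ntr(sim_gene_counts(1), user_rates())
    expect_lt(lo$ntr_mean, 0.02)
    # the upper boundary is softer than the lower one: a third of fully
    # labeled reads carry zero conversions at these rates, so estimates sit
    # just below 1 with ~0.01-0.02 spread
    expect_gt(hi$ntr_map, 0.95)
    expect_gt(hi$ntr_mean, 0.95)
  }
  # swapping component labels mirrors the estimate
  r <- sim_gene_counts(0.3)$reads[[1]]
  a <- slamkit:::gene_em(r$k, r$n_T, r$weight, 0.05, 0.001)
  b <- slamkit:::gene_em(r$k, r$n_T, r$weight, 0.001, 0.05, pi_init = 0.9)
  expect_equal(a$pi, 1 - b$pi, tolerance = 1e-6)
})

test_that("credible intervals are calibrated over genes with uniform NTRs", {
  set.seed(31)
  truth <- runif(200)
  gc <- dplyr::bind_rows(lapply(1:200, function(i) {
    sim_gene_counts(truth[i], gene_id = paste0("g", i))
  }))
  est <- estimate_ntr(gc, user_rates())
  covered <- mean(truth >= est$ntr_q05 & truth <= est$ntr_q95)
  expect_gte(covered, 0.84)
  expect_lte(covered, 0.96)
})

test_that("the output table round-trips and the GrandSLAM schema renames headers in order", {
  set.seed(37)
  gc <- dplyr::bind_rows(lapply(1:3, function(i) {
    sim_gene_counts(runif(1), R = 50L, gene_id = paste0("g", i))
  }))
  est <- estimate_ntr(gc, user_rates())
  dir <- withr::local_tempdir()
  p1 <- file.path(dir, "native.tsv")
  write_ntr_table(est, p1)
  back <- readr::read_tsv(p1, show_col_types = FALSE)
  expect_equal(nrow(back), 3L)
  expect_equal(back$ntr_mean, est$ntr_mean, tolerance = 1e-10)
  expect_equal(back$alpha, est$alpha, tolerance = 1e-10)

  p2 <- file.path(dir, "gs.tsv")
  write_ntr_table(est, p2, schema = "grandslam")
  hdr <- strsplit(readLines(p2, n = 1L), "\t")[[1]]
  expect_equal(hdr, c("Gene", "Symbol", "Readcount", "Conversions",
                      "Coverage", "MAP", "Mean", "lower", "upper"))
})
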