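# Small shared helpers. All genomic coordinates inside the package are
# 0-based half-open; file formats are converted on load/write.

BASE_COMP <- c(A = "T", C = "G", G = "C", T = "A", N = "N")

comp_base <- function(b) unname(BASE_COMP[b])

revcomp <- function(s) {
  chartr("ACGTN", "TGCAN", vapply(s, function(x) {
    paste(rev(strsplit(x, "", fixed = TRUE)[[1]]), collapse = "")
  }, character(1), USE.NAMES = FALSE))
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# log(exp(a) + exp(b)) element-wise, stable
log_add <- function(a, b) {
  m <- pmax(a, b)
  out <- m + log1p(exp(pmin(a, b) - m))
  out[is.infinite(m) & m < 0] <- -Inf
  out
}

# Phred string -> integer vector (offset 33)
phred_to_int <- function(q) as.integer(charToRaw(q)) - 33L

int_to_phred <- function(q) rawToChar(as.raw(q + 33L))

is_scalar_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

`%enull%` <- function(x, y) if (is.null(x) || length(x) == 0L) y else x
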