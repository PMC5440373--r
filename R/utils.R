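# shared internal helpers

# median of chi-square with 1 df; divisor in the genomic-control lambda
CHISQ1_MEDIAN <- qchisq(0.5, df = 1)

`%||%` <- function(a, b) if (is.null(a)) b else a

# strand complement for A/C/G/T allele vectors
comp_allele <- function(a) {
  c(A = "T", C = "G", G = "C", T = "A")[a]
}

is_palindromic <- function(a1, a2) {
  !is.na(a1) & !is.na(a2) & comp_allele(a1) == a2
}

stop2 <- function(...) stop(..., call. = FALSE)
warn2 <- function(...) warning(..., call. = FALSE)

# Run code under a fixed RNG seed without disturbing the caller's stream.
with_seed2 <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  withr::with_seed(as.integer(seed), code)
}

# -log10(p), guarded against p = 0
neg_log10 <- function(p) -log10(pmax(p, .Machine$double.xmin))
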