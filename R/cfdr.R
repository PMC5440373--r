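#' Build a conditional-FDR lookup grid
#'
#' Estimates the conditional FDR of the primary trait given the secondary,
#' `cfdr(p1 | p2 <= t) = min(1, p1 / Fhat(p1 | p2 <= t))`, on a 2D grid of
#' significance levels, where `Fhat(p1 | p2 <= t) =
#' #(p1_i <= p1 & p2_i <= t) / #(p2_i <= t)` is the empirical conditional
#' CDF. This is the conservative empirical-Bayes estimator with the null
#' proportion bounded at 1, so values upper-bound the posterior null
#' probability. The grid is fitted on an LD-pruned, region-excluded SNP
#' subset (complex long-range LD otherwise biases the empirical CDFs) but
#' can score any SNP via [lookup_cfdr()].
#'
#' Numerical conventions: axes are equally spaced in `-log10 p` from 0 to
#' the observed maximum (capped at `cap`); beyond the smallest observed
#' `p1` of a conditioning column the surface carries the boundary value
#' forward (the monotone-conservative extension — an empirical CDF gives
#' no license to extrapolate enrichment into its own tail);
#' the surface is then monotonized, first non-decreasing in `p1` (running
#' maximum toward larger `p1`), then non-increasing in conditioning
#' stringency (running minimum toward smaller `t`); columns whose
#' conditioning stratum is empty inherit the nearest less-stringent
#' column.
#'
#' @param pairs harmonized, inflation-corrected pair table
#'   ([intersect_traits()]).
#' @param ld optional [ld_reference()]; when given, the grid is fitted on
#'   one random SNP per LD block.
#' @param exclude optional region table ([default_exclusion_regions()]);
#'   SNPs inside (plus their r-squared partners) are dropped before
#'   fitting.
#' @param seed RNG seed for the pruning draw.
#' @param direction `"1|2"` (primary = trait 1, conditioning = trait 2) or
#'   `"2|1"`.
#' @param grid_size nodes per axis (default 201).
#' @param cap maximum `-log10 p` represented (default 300).
#' @param monotone apply the monotonization passes (default `TRUE`;
#'   disable only for estimator diagnostics).
#' @return object of class `cfdr_grid`: list with `axis1`, `axis2`
#'   (ascending `-log10 p` nodes), `cfdr` and `cond_cdf` (matrices, rows =
#'   axis1), `direction`, `n_fit`.
#' @export
build_cfdr_grid <- function(pairs, ld = NULL, exclude = NULL, seed = NULL,
                            direction = c("1|2", "2|1"), grid_size = 201,
                            cap = 300, monotone = TRUE) {
  direction <- match.arg(direction)
  dt <- as.data.table(pairs)
  ids <- dt$snp_id
  if (!is.null(exclude) && !is.null(ld)) {
    ids <- exclude_regions(ids, ld, exclude,
                           dt[, .(snp_id, chrom, pos)])
  }
  if (!is.null(ld)) ids <- random_prune(ids, ld, seed = seed)
  fit <- dt[snp_id %chin% ids]
  if (direction == "1|2") {
    x1 <- neg_log10(fit$p1); x2 <- neg_log10(fit$p2)
  } else {
    x1 <- neg_log10(fit$p2); x2 <- neg_log10(fit$p1)
  }
  x1 <- pmin(x1, cap); x2 <- pmin(x2, cap)
  G <- as.integer(grid_size)
  axis1 <- seq(0, max(x1), length.out = G)
  axis2 <- seq(0, max(x2), length.out = G)

  # joint suffix counts N[i,j] = #(x1 >= axis1[i] & x2 >= axis2[j])
  bi <- findInterval(x1, axis1)
  bj <- findInterval(x2, axis2)
  M <- matrix(tabulate(bi + (bj - 1L) * G, nbins = G * G), nrow = G)
  N <- apply(M, 2L, function(cl) rev(cumsum(rev(cl))))
  N <- t(apply(N, 1L, function(rw) rev(cumsum(rev(rw)))))
  D <- N[1L, ]  # conditioning counts #(x2 >= axis2[j])

  p1_nodes <- 10^(-axis1)
  cond_cdf <- sweep(N, 2L, pmax(D, 1), "/")
  cfdr <- pmin(outer(p1_nodes, pmax(D, 1)) / pmax(N, 1), 1)
  # beyond the observed support of a conditioning column the empirical CDF
  # is unknown; extend with the boundary value (the monotone-conservative
  # choice) instead of extrapolating the ratio
  empty <- D == 0
  for (j in which(!empty)) {
    i_star <- max(which(N[, j] > 0L))   # N[1, j] = D[j] > 0
    if (i_star < G) cfdr[(i_star + 1L):G, j] <- cfdr[i_star, j]
  }
  cfdr[, empty] <- NA_real_
  cond_cdf[, empty] <- NA_real_

  if (monotone) {
    # non-decreasing in p1: running max from small p1 (large i) to large
    for (i in seq(G - 1L, 1L)) {
      cfdr[i, ] <- pmax(cfdr[i, ], cfdr[i + 1L, ])
    }
    # empty conditioning columns inherit the nearest less-stringent one
    for (j in seq(2L, G)) {
      if (empty[j]) cfdr[, j] <- cfdr[, j - 1L]
    }
    # non-increasing in conditioning stringency: running min along axis2
    for (j in seq(2L, G)) {
      cfdr[, j] <- pmin(cfdr[, j], cfdr[, j - 1L])
    }
  }
  structure(list(axis1 = axis1, axis2 = axis2, cfdr = cfdr,
                 cond_cdf = cond_cdf, direction = direction,
                 n_fit = nrow(fit)),
            class = "cfdr_grid")
}

#' @export
print.cfdr_grid <- function(x, ...) {
  cat("cfdr_grid (", x$direction, "): ", length(x$axis1), "x",
      length(x$axis2), " nodes, fitted on ", x$n_fit, " SNPs\n", sep = "")
  invisible(x)
}

#' Interpolated conditional-FDR lookup
#'
#' Bilinear interpolation of a [build_cfdr_grid()] surface in
#' `(-log10 p1, -log10 p2)`; queries outside the grid are clamped to its
#' boundary, and values at grid nodes are returned exactly.
#'
#' @param grid a `cfdr_grid`.
#' @param p1 primary-trait p-values (the grid's `direction` decides which
#'   trait that is).
#' @param p2 conditioning-trait p-values.
#' @return numeric vector of conditional FDR values in `(0, 1]`.
#' @export
lookup_cfdr <- function(grid, p1, p2) {
  if (any(!is.finite(p1) | p1 <= 0 | p1 > 1) ||
      any(!is.finite(p2) | p2 <= 0 | p2 > 1)) {
    stop2("p-values must lie in (0, 1]")
  }
  a1 <- grid$axis1; a2 <- grid$axis2
  x <- pmin(pmax(neg_log10(p1), a1[1]), a1[length(a1)])
  y <- pmin(pmax(neg_log10(p2), a2[1]), a2[length(a2)])
  i <- findInterval(x, a1, all.inside = TRUE)
  j <- findInterval(y, a2, all.inside = TRUE)
  tx <- (x - a1[i]) / (a1[i + 1L] - a1[i])
  ty <- (y - a2[j]) / (a2[j + 1L] - a2[j])
  C <- grid$cfdr
  G <- nrow(C)
  v00 <- C[cbind(i, j)]
  v10 <- C[cbind(i + 1L, j)]
  v01 <- C[cbind(i, j + 1L)]
  v11 <- C[cbind(i + 1L, j + 1L)]
  (1 - tx) * (1 - ty) * v00 + tx * (1 - ty) * v10 +
    (1 - tx) * ty * v01 + tx * ty * v11
}

#' Conjunction FDR and significant-SNP selection
#'
#' The conjunction FDR of a SNP — an upper bound on the posterior
#' probability that it is null for either trait — is the maximum of the
#' two conditional FDRs, `max(cfdr(p1|p2), cfdr(p2|p1))`. SNPs are called
#' significant when the conjunction FDR falls strictly below the overall
#' threshold (default 0.05).
#'
#' @param grid12 `cfdr_grid` with direction `"1|2"`.
#' @param grid21 `cfdr_grid` with direction `"2|1"`.
#' @param pairs harmonized pair table whose SNPs are to be scored (need
#'   not equal the grid-fitting subset).
#' @param threshold overall FDR threshold (default 0.05, strict `<`).
#' @return `data.table` extending `pairs` with `cfdr_1g2`, `cfdr_2g1`,
#'   `conj_fdr` and `significant`; class `conjunction_result`, attribute
#'   `"threshold"`, attribute `"n_excluded"` (SNPs lacking a p-value in
#'   either trait).
#' @export
conjunction_fdr <- function(grid12, grid21, pairs, threshold = 0.05) {
  if (grid12$direction != "1|2" || grid21$direction != "2|1") {
    stop2("grid12/grid21 must have directions 1|2 and 2|1")
  }
  dt <- as.data.table(pairs)
  ok <- is.finite(dt$p1) & is.finite(dt$p2)
  n_excluded <- sum(!ok)
  dt <- dt[ok]
  dt[, cfdr_1g2 := lookup_cfdr(grid12, p1, p2)]
  dt[, cfdr_2g1 := lookup_cfdr(grid21, p2, p1)]
  dt[, conj_fdr := pmax(cfdr_1g2, cfdr_2g1)]
  dt[, significant := conj_fdr < threshold]
  setattr(dt, "threshold", threshold)
  setattr(dt, "n_excluded", n_excluded)
  setattr(dt, "class", c("conjunction_result", class(dt)))
  dt[]
}
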