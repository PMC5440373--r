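#' Stratify SNPs by secondary-trait significance
#'
#' Builds the nested SNP strata used by conditional Q-Q, fold-enrichment,
#' TDR and replication curves: stratum *k* holds the SNPs with secondary
#' p-value strictly below threshold *k*. A threshold of 1 denotes the
#' all-SNP stratum (`p2 <= 1`), so records with `p2 = 1` are kept there.
#'
#' @param pairs harmonized pair table ([intersect_traits()]) with a `p2`
#'   column (or a `p2`-like column named by `p_col`).
#' @param thresholds strictly descending secondary p cutoffs in `(0, 1]`
#'   (default `c(1, 0.1, 0.01, 0.001)`).
#' @param p_col column of `pairs` holding the conditioning p-values.
#' @return named list of SNP-id character vectors, nested by construction;
#'   names are the threshold values.
#' @export
make_strata <- function(pairs, thresholds = c(1, 0.1, 0.01, 0.001),
                        p_col = "p2") {
  if (is.unsorted(rev(thresholds), strictly = TRUE)) {
    stop2("thresholds must be strictly descending")
  }
  if (any(thresholds <= 0 | thresholds > 1)) {
    stop2("thresholds must lie in (0, 1]")
  }
  dt <- as.data.table(pairs)
  p <- dt[[p_col]]
  out <- lapply(thresholds, function(t) {
    if (t >= 1) dt$snp_id[p <= 1] else dt$snp_id[p < t]
  })
  names(out) <- format(thresholds, trim = TRUE, scientific = FALSE)
  empty <- vapply(out, length, integer(1)) == 0
  if (any(empty)) {
    warn2("empty stratum at threshold(s): ",
          paste(names(out)[empty], collapse = ", "))
  }
  out
}

# shared grid in -log10(p) units
enrichment_grid <- function(xmax, grid_size) {
  seq(0, xmax, length.out = grid_size)
}

#' Conditional Q-Q curves
#'
#' For each secondary-significance stratum, the empirical quantiles of the
#' primary trait's `-log10(p)` are evaluated against nominal uniform
#' quantiles. Under the null the curve sits on the diagonal; polygenic
#' overlap shows as increasing deflection across nested strata. Following
#' standard practice the display is restricted to sub-genome-wide SNPs
#' (`-log10 p < log10p_cap`, default 7.3, i.e. `p > 5e-8`), and curves are
#' averaged over repeated random prunings of the LD reference.
#'
#' @param pairs harmonized, inflation-corrected pair table.
#' @param ld optional [ld_reference()]; when supplied, curves are averaged
#'   over `prune_iters` random prunings (one SNP per block).
#' @param thresholds secondary strata cutoffs, see [make_strata()].
#' @param seed RNG seed for the prunings.
#' @param prune_iters number of random prunings averaged (default 100;
#'   ignored without `ld`).
#' @param grid_size number of nominal grid points (default 1000).
#' @param log10p_cap display cap on `-log10(p1)` (default 7.3).
#' @param min_stratum strata smaller than this are flagged low-confidence
#'   (default 50).
#' @return `data.table(stratum, threshold, nominal, empirical, n,
#'   low_confidence)`: `nominal` is the expected `-log10` quantile,
#'   `empirical` the observed one (averaged over prunings), `n` the mean
#'   stratum size after pruning.
#' @export
conditional_qq <- function(pairs, ld = NULL,
                           thresholds = c(1, 0.1, 0.01, 0.001),
                           seed = NULL, prune_iters = 100, grid_size = 1000,
                           log10p_cap = 7.3, min_stratum = 50) {
  dt <- as.data.table(pairs)
  strata <- make_strata(dt, thresholds)
  grid <- enrichment_grid(log10p_cap, grid_size)
  iters <- if (is.null(ld)) 1L else as.integer(prune_iters)
  p1 <- stats::setNames(dt$p1, dt$snp_id)

  acc <- lapply(strata, function(s) list(sum = numeric(length(grid)),
                                         cnt = numeric(length(grid)),
                                         n = 0))
  with_seed2(seed, {
    for (it in seq_len(iters)) {
      keep <- if (is.null(ld)) dt$snp_id else {
        random_prune(dt$snp_id, ld, seed = NULL)
      }
      for (k in seq_along(strata)) {
        ids <- intersect(strata[[k]], keep)
        pk <- p1[ids]
        pk <- pk[pk > 10^(-log10p_cap)]  # display restriction
        if (!length(pk)) next
        emp <- neg_log10(quantile(pk, probs = 10^(-grid), type = 1,
                                  names = FALSE))
        acc[[k]]$sum <- acc[[k]]$sum + emp
        acc[[k]]$cnt <- acc[[k]]$cnt + 1
        acc[[k]]$n <- acc[[k]]$n + length(pk)
      }
    }
  })
  out <- rbindlist(lapply(seq_along(strata), function(k) {
    a <- acc[[k]]
    n_mean <- if (any(a$cnt > 0)) a$n / max(a$cnt) else 0
    data.table(stratum = names(strata)[k],
               threshold = thresholds[k],
               nominal = grid,
               empirical = ifelse(a$cnt > 0, a$sum / pmax(a$cnt, 1),
                                  NA_real_),
               n = n_mean,
               low_confidence = n_mean < min_stratum)
  }))
  out[]
}

#' Fold-enrichment curves
#'
#' The enrichment of a secondary-significance stratum at primary
#' significance level `x` (in `-log10 p` units):
#' `fold_k(x) = [#(stratum SNPs with -log10 p1 >= x) / |stratum|] /
#' [#(all SNPs with -log10 p1 >= x) / N]`. The all-SNP stratum is
#' identically 1; the curve is `NA` where the all-SNP count vanishes.
#'
#' @inheritParams conditional_qq
#' @param grid ascending `-log10 p1` evaluation points; default 1000
#'   equally spaced points from 0 to the observed maximum, capped at
#'   `log10p_cap`.
#' @return `data.table(stratum, threshold, x, fold, n_stratum, n_tail)`.
#' @export
fold_enrichment <- function(pairs, thresholds = c(1, 0.1, 0.01, 0.001),
                            grid = NULL, grid_size = 1000,
                            log10p_cap = 7.3, min_stratum = 50) {
  dt <- as.data.table(pairs)
  strata <- make_strata(dt, thresholds)
  x1 <- stats::setNames(neg_log10(dt$p1), dt$snp_id)
  x1 <- x1[x1 < log10p_cap]  # display restriction
  if (is.null(grid)) {
    grid <- enrichment_grid(min(log10p_cap, max(x1)), grid_size)
  }
  n_all <- length(x1)
  sorted_all <- sort(x1)
  tail_ge <- function(v, g) length(v) - findInterval(g, v, left.open = TRUE)
  den_cnt <- tail_ge(sorted_all, grid)
  out <- rbindlist(lapply(seq_along(strata), function(k) {
    xk <- sort(unname(x1[intersect(strata[[k]], names(x1))]))
    nk <- length(xk)
    num_cnt <- if (nk) tail_ge(xk, grid) else rep(NA_real_, length(grid))
    fold <- ifelse(den_cnt > 0 & nk > 0,
                   (num_cnt / nk) / (den_cnt / n_all), NA_real_)
    data.table(stratum = names(strata)[k], threshold = thresholds[k],
               x = grid, fold = fold, n_stratum = nk, n_tail = num_cnt)
  }))
  if (any(out$n_stratum < min_stratum)) {
    warn2("stratum below ", min_stratum, " SNPs; fold estimates noisy")
  }
  out[]
}

#' Conditional true-discovery-rate curves
#'
#' Per stratum, `TDR(p) = 1 - min(1, p / Fhat(p))` where `Fhat` is the
#' stratum's empirical CDF of the primary p-values — the conservative
#' empirical-Bayes estimate with the null proportion bounded at 1. The FDR
#' component is monotonized with the standard running minimum toward less
#' significant p (q-value construction), so TDR is non-increasing in p.
#'
#' @inheritParams fold_enrichment
#' @param grid ascending `-log10 p1` evaluation points; default 1000 points
#'   over the observed range.
#' @return `data.table(stratum, threshold, x, tdr, n)`; `tdr` is `NA`
#'   where the stratum's empirical CDF is zero.
#' @export
conditional_tdr <- function(pairs, thresholds = c(1, 0.1, 0.01, 0.001),
                            grid = NULL, grid_size = 1000) {
  dt <- as.data.table(pairs)
  strata <- make_strata(dt, thresholds)
  x1 <- stats::setNames(neg_log10(dt$p1), dt$snp_id)
  if (is.null(grid)) grid <- enrichment_grid(max(x1), grid_size)
  pgrid <- 10^(-grid)
  out <- rbindlist(lapply(seq_along(strata), function(k) {
    xk <- sort(unname(x1[intersect(strata[[k]], names(x1))]))
    nk <- length(xk)
    if (!nk) {
      return(data.table(stratum = names(strata)[k],
                        threshold = thresholds[k], x = grid,
                        tdr = NA_real_, n = 0L))
    }
    # Fhat(p) = #( -log10 p1 >= -log10 p ) / n
    cdf <- (nk - findInterval(grid, xk, left.open = TRUE)) / nk
    fdr <- ifelse(cdf > 0, pmin(1, pgrid / cdf), NA_real_)
    fdr <- cummin(ifelse(is.na(fdr), Inf, fdr))  # running min toward small p
    fdr[cdf == 0] <- NA_real_  # empirical CDF exhausted: undefined
    data.table(stratum = names(strata)[k], threshold = thresholds[k],
               x = grid, tdr = 1 - fdr, n = nk)
  }))
  out[]
}
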