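#' Bundle per-substudy z-scores into a panel
#'
#' @param z numeric matrix, SNPs in rows (rownames = SNP ids), substudies
#'   in columns; z-scores aligned to one common effect allele.
#' @param n per-substudy sample sizes (positive, length = ncol(z)).
#' @param labels substudy labels (default column names or `S1..SK`).
#' @return object of class `substudy_panel`.
#' @export
substudy_panel <- function(z, n, labels = NULL) {
  z <- as.matrix(z)
  if (is.null(rownames(z))) stop2("z must have SNP ids as rownames")
  if (length(n) != ncol(z) || any(n <= 0)) {
    stop2("n must be positive with one entry per substudy")
  }
  labels <- labels %||% colnames(z) %||% paste0("S", seq_len(ncol(z)))
  colnames(z) <- labels
  structure(list(z = z, n = as.numeric(n), labels = labels,
                 snp_id = rownames(z)),
            class = "substudy_panel")
}

#' @export
print.substudy_panel <- function(x, ...) {
  cat("substudy_panel:", ncol(x$z), "substudies x", nrow(x$z), "SNPs\n")
  invisible(x)
}

#' Random half-partitions of substudies
#'
#' Each partition splits the K substudies into a discovery half and its
#' complement; with odd K the discovery set gets `floor(K/2)` members.
#' Seeded and reproducible.
#'
#' @param panel a [substudy_panel()] (or an integer K).
#' @param n_partitions number of random partitions (default 500).
#' @param seed RNG seed.
#' @return list of `list(discovery, replication)` index vectors.
#' @export
partition_substudies <- function(panel, n_partitions = 500, seed = NULL) {
  K <- if (inherits(panel, "substudy_panel")) ncol(panel$z)
       else as.integer(panel)
  if (K < 2) stop2("need at least 2 substudies")
  nd <- K %/% 2L
  with_seed2(seed, {
    lapply(seq_len(n_partitions), function(i) {
      perm <- sample.int(K)
      list(discovery = sort(perm[seq_len(nd)]),
           replication = sort(perm[(nd + 1L):K]))
    })
  })
}

#' Combine substudy z-scores (weighted Stouffer)
#'
#' `z_comb = sum(w_k z_k) / sqrt(sum(w_k^2))` with `w_k = sqrt(n_k)`
#' (sample-size weighting, the default) or `w_k = 1`. Null-preserving:
#' standard-normal inputs give a standard-normal combination. SNPs with
#' missing z in some members are combined over the available members.
#'
#' @param panel a [substudy_panel()].
#' @param subset substudy indices (or labels) to combine.
#' @param weights `"sqrt_n"` or `"equal"`.
#' @return named numeric vector of combined z-scores (one per SNP).
#' @export
combine_z <- function(panel, subset = NULL, weights = c("sqrt_n", "equal")) {
  weights <- match.arg(weights)
  idx <- subset %||% seq_len(ncol(panel$z))
  if (is.character(idx)) idx <- match(idx, panel$labels)
  Z <- panel$z[, idx, drop = FALSE]
  w <- if (weights == "sqrt_n") sqrt(panel$n[idx]) else rep(1, length(idx))
  if (!anyNA(Z)) {
    num <- as.vector(Z %*% w)
    den <- sqrt(sum(w^2))
    stats::setNames(num / den, panel$snp_id)
  } else {
    obs <- !is.na(Z)
    num <- rowSums(sweep(Z, 2L, w, "*"), na.rm = TRUE)
    den <- sqrt(obs %*% (w^2))
    stats::setNames(num / as.vector(den), panel$snp_id)
  }
}

#' Stratified cumulative replication-rate curves
#'
#' Over repeated random half-partitions of the substudies, SNPs are binned
#' by combined discovery significance and the cumulative replication rate
#' — the proportion of SNPs at or beyond each bin whose replication-half
#' p-value is below `alpha` (and, by default, whose effect sign agrees) —
#' is computed within each secondary-trait enrichment stratum and averaged
#' over partitions. Bins are equal-width in `-log10 p` over each
#' partition's observed discovery range.
#'
#' @param panel a [substudy_panel()].
#' @param p2 secondary-trait p-values named by (or aligned with) the
#'   panel's SNPs, defining the enrichment strata.
#' @param thresholds stratum cutoffs, see [make_strata()] (default
#'   `c(1, 0.1, 0.01, 0.001)`).
#' @param n_partitions number of random partitions (default 500).
#' @param bins number of equally spaced discovery `-log10 p` bins
#'   (default 1000).
#' @param seed RNG seed.
#' @param sign_rule require sign agreement between discovery and
#'   replication z in addition to `p < alpha` (default `TRUE`).
#' @param alpha replication significance level (default 0.05).
#' @param weights passed to [combine_z()].
#' @return `data.table(stratum, threshold, bin, x, rate, n)`: `x` is the
#'   bin's lower `-log10 p` edge averaged over partitions, `rate` the mean
#'   cumulative replication rate (`NA` where no SNP reached the bin), `n`
#'   the mean SNP count at or beyond the bin.
#' @export
replication_curves <- function(panel, p2,
                               thresholds = c(1, 0.1, 0.01, 0.001),
                               n_partitions = 500, bins = 1000,
                               seed = NULL, sign_rule = TRUE, alpha = 0.05,
                               weights = "sqrt_n") {
  if (!is.null(names(p2))) p2 <- p2[panel$snp_id]
  if (length(p2) != nrow(panel$z)) stop2("p2 must align with the panel")
  strata <- make_strata(data.table(snp_id = panel$snp_id, p2 = p2),
                        thresholds)
  memb <- lapply(strata, function(s) panel$snp_id %chin% s)
  parts <- partition_substudies(panel, n_partitions, seed = seed)

  nb <- as.integer(bins)
  S <- length(strata)
  rate_sum <- matrix(0, nb, S); rate_cnt <- matrix(0L, nb, S)
  n_sum <- matrix(0, nb, S); x_sum <- numeric(nb)
  for (pt in parts) {
    zd <- combine_z(panel, pt$discovery, weights = weights)
    zr <- combine_z(panel, pt$replication, weights = weights)
    ld10 <- neg_log10(z_to_p(zd))
    success <- (z_to_p(zr) < alpha) & (!sign_rule | zd * zr > 0)
    rng <- range(ld10)
    edges <- seq(rng[1], rng[2], length.out = nb + 1L)[seq_len(nb)]
    x_sum <- x_sum + edges
    for (s in seq_len(S)) {
      sel <- memb[[s]]
      v <- ld10[sel]; sc <- success[sel]
      if (!length(v)) next
      o <- order(v)
      v <- v[o]; sc <- sc[o]
      total_n <- length(v); total_s <- sum(sc)
      below <- findInterval(edges, v, left.open = TRUE)
      cs <- cumsum(sc)
      n_ge <- total_n - below
      s_ge <- total_s - ifelse(below > 0L, cs[pmax(below, 1L)], 0)
      ok <- n_ge > 0L
      rate_sum[ok, s] <- rate_sum[ok, s] + s_ge[ok] / n_ge[ok]
      rate_cnt[ok, s] <- rate_cnt[ok, s] + 1L
      n_sum[, s] <- n_sum[, s] + n_ge
    }
  }
  np <- length(parts)
  rbindlist(lapply(seq_len(S), function(s) {
    data.table(stratum = names(strata)[s], threshold = thresholds[s],
               bin = seq_len(nb), x = x_sum / np,
               rate = ifelse(rate_cnt[, s] > 0,
                             rate_sum[, s] / rate_cnt[, s], NA_real_),
               n = n_sum[, s] / np)
  }))[]
}

#' Discovery/replication effect-size agreement per stratum
#'
#' Per enrichment stratum, the through-origin regression slope of the
#' combined replication z on the combined discovery z, averaged over
#' random half-partitions, with its Monte-Carlo standard error. Under the
#' pure null the slope is ~0 (winner's curse); it rises toward 1 as true
#' effects dominate, and enriched strata are expected to replicate with
#' larger slopes.
#'
#' @inheritParams replication_curves
#' @return `data.table(stratum, threshold, slope, se, n_snps)`.
#' @export
effect_size_agreement <- function(panel, p2,
                                  thresholds = c(1, 0.1, 0.01, 0.001),
                                  n_partitions = 500, seed = NULL,
                                  weights = "sqrt_n") {
  if (!is.null(names(p2))) p2 <- p2[panel$snp_id]
  strata <- make_strata(data.table(snp_id = panel$snp_id, p2 = p2),
                        thresholds)
  memb <- lapply(strata, function(s) panel$snp_id %chin% s)
  parts <- partition_substudies(panel, n_partitions, seed = seed)
  slopes <- matrix(NA_real_, length(parts), length(strata))
  for (k in seq_along(parts)) {
    zd <- combine_z(panel, parts[[k]]$discovery, weights = weights)
    zr <- combine_z(panel, parts[[k]]$replication, weights = weights)
    for (s in seq_along(strata)) {
      sel <- memb[[s]]
      den <- sum(zd[sel]^2)
      if (is.finite(den) && den > 0) {
        slopes[k, s] <- sum(zd[sel] * zr[sel]) / den
      }
    }
  }
  rbindlist(lapply(seq_along(strata), function(s) {
    v <- slopes[, s]
    data.table(stratum = names(strata)[s], threshold = thresholds[s],
               slope = mean(v, na.rm = TRUE),
               se = stats::sd(v, na.rm = TRUE) / sqrt(sum(!is.na(v))),
               n_snps = sum(memb[[s]]))
  }))[]
}
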