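library(data.table)

# small valid summary-statistics table (non-palindromic alleles)
toy_sumstats <- function(n = 10, seed = 1, chrom = "1") {
  withr::with_seed(seed, {
    z <- rnorm(n)
    data.table(snp_id = sprintf("t%03d", seq_len(n)), chrom = chrom,
               pos = seq_len(n) * 1000L,
               a1 = rep(c("A", "C"), length.out = n),
               a2 = rep(c("G", "T"), length.out = n),
               z = z, p = z_to_p(z), n = 1000)
  })
}

# harmonized-pair table straight from p/z vectors (all direction-defined)
toy_pairs <- function(p1, p2, z1 = NULL, z2 = NULL, chrom = "1") {
  n <- length(p1)
  z1 <- if (is.null(z1)) p_to_z(p1) else z1
  z2 <- if (is.null(z2)) p_to_z(p2) else z2
  data.table(snp_id = sprintf("p%05d", seq_len(n)), chrom = chrom,
             pos = seq_len(n) * 1000L, a1 = "A", a2 = "G",
             z1 = z1, p1 = p1, n1 = 1000,
             z2 = z2, p2 = p2, n2 = 1000,
             direction_defined = TRUE)
}

# ---- independent oracles -------------------------------------------------

# connected components by explicit breadth-first search on an edge list
oracle_components <- function(ids, edges) {
  comp <- stats::setNames(rep(NA_integer_, length(ids)), ids)
  nb <- stats::setNames(vector("list", length(ids)), ids)
  for (k in seq_len(nrow(edges))) {
    a <- edges$a[k]; b <- edges$b[k]
    nb[[a]] <- c(nb[[a]], b); nb[[b]] <- c(nb[[b]], a)
  }
  cid <- 0L
  for (s in ids) {
    if (!is.na(comp[s])) next
    cid <- cid + 1L
    queue <- s
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      if (!is.na(comp[v])) next
      comp[v] <- cid
      queue <- c(queue, setdiff(nb[[v]], names(comp)[!is.na(comp)]))
    }
  }
  comp
}

# naive O(n^2) rank-greedy independent set on an r2 adjacency matrix
oracle_clump <- function(scores, p, adj_matrix) {
  ids <- names(scores)
  ord <- order(scores, p, ids)
  kept <- character(0)
  for (s in ids[ord]) {
    if (!length(kept) || all(adj_matrix[s, kept] == 0)) kept <- c(kept, s)
  }
  kept
}

# random r2 graph over n SNPs: returns edges + adjacency matrix
random_ld_graph <- function(n, p_edge = 0.08, seed = 1) {
  withr::with_seed(seed, {
    ids <- sprintf("g%03d", seq_len(n))
    A <- matrix(0, n, n, dimnames = list(ids, ids))
    el <- list()
    for (i in seq_len(n - 1)) {
      for (j in seq(i + 1, n)) {
        if (runif(1) < p_edge) {
          r2 <- runif(1, 0.11, 1)
          A[i, j] <- A[j, i] <- r2
          el[[length(el) + 1L]] <- data.table(a = ids[i], b = ids[j],
                                              r2 = r2)
        }
      }
    }
    list(ids = ids, edges = rbindlist(el), adj = A)
  })
}
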