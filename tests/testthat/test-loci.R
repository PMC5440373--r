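# wrap a p/score table as a minimal conjunction result
fake_result <- function(snp_id, chrom, pos, conj_fdr, z1 = 1, z2 = 1,
                        p1 = conj_fdr, p2 = conj_fdr,
                        direction_defined = TRUE, significant = NULL) {
  dt <- data.table(snp_id = snp_id, chrom = chrom, pos = pos,
                   a1 = "A", a2 = "G", z1 = z1, p1 = p1,
                   z2 = z2, p2 = p2,
                   direction_defined = direction_defined,
                   cfdr_1g2 = conj_fdr, cfdr_2g1 = conj_fdr,
                   conj_fdr = conj_fdr,
                   significant = significant %||% (conj_fdr < 0.05))
  dt
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("significant SNPs cluster into LD-block loci with correct leads", {
  # two linked significant SNPs plus one isolated: 2 loci of sizes 2 and 1
  res <- fake_result(c("a", "b", "c"), chrom = "1",
                     pos = c(100L, 200L, 9000L),
                     conj_fdr = c(0.0148, 0.0058, 0.03))
  ld <- ld_reference(edges = data.table(a = "a", b = "b", r2 = 0.4),
                     snps = c("a", "b", "c"))
  loci <- define_loci(res, ld)
  expect_equal(nrow(loci), 2)
  expect_equal(sort(loci$n_snps), c(1, 2))
  # within the linked pair the smaller conjunction FDR leads
  expect_equal(loci[n_snps == 2, lead_snp], "b")
  expect_equal(loci[n_snps == 2, conj_fdr], 0.0058)
  expect_equal(loci[n_snps == 2, members], "a,b")
  # numbering follows genomic order of the leads
  expect_equal(loci$pos, sort(loci$pos))

  # nothing significant: empty table, not an error
  res0 <- copy(res)[, significant := FALSE]
  expect_equal(nrow(define_loci(res0, ld)), 0)
})

test_that("locus components and leads match a brute-force oracle", {
  for (s in 1:50) {
    g <- random_ld_graph(n = 12, p_edge = 0.15, seed = 100 + s)
    withr::with_seed(200 + s, {
      fdr <- stats::setNames(runif(12, 0, 0.04), g$ids)
    })
    res <- fake_result(g$ids, chrom = "1",
                       pos = seq_along(g$ids) * 100L,
                       conj_fdr = unname(fdr[g$ids]))
    ld <- if (nrow(g$edges)) ld_reference(edges = g$edges, snps = g$ids)
          else ld_reference(snps = g$ids)
    loci <- define_loci(res, ld)
    # oracle: BFS components + component-minimum search
    edges <- if (nrow(g$edges)) g$edges[r2 > 0.1] else
      data.table(a = character(0), b = character(0))
    comp <- oracle_components(g$ids, edges)
    want_leads <- vapply(split(names(comp), comp), function(mem) {
      mem[order(fdr[mem], mem)][1]
    }, character(1))
    expect_setequal(loci$lead_snp, unname(want_leads))
    # partition property
    expect_equal(sum(loci$n_snps), 12)
    expect_setequal(unlist(strsplit(loci$members, ",")), g$ids)
    # leads are pairwise unlinked
    if (nrow(loci) > 1) {
      A <- g$adj[loci$lead_snp, loci$lead_snp]
      expect_true(all(A[upper.tri(A)] <= 0.1))
    }
    # cross-module agreement: every lead survives greedy clumping (equality
    # holds only when components are cliques, tested below)
    clumped <- greedy_clump(fdr, ld, p = fdr)
    expect_true(all(loci$lead_snp %in% clumped))
  }

  # with block-defined LD (complete graphs) leads and clump coincide
  withr::with_seed(300, {
    blocks <- data.table(snp_id = sprintf("q%02d", 1:20),
                         block = sample(1:6, 20, TRUE))
    fdr <- stats::setNames(runif(20, 0, 0.04), blocks$snp_id)
  })
  ldb <- ld_reference(blocks = blocks)
  resb <- fake_result(blocks$snp_id, chrom = "1",
                      pos = seq_len(20) * 50L,
                      conj_fdr = unname(fdr))
  lb <- define_loci(resb, ldb)
  expect_setequal(lb$lead_snp, greedy_clump(fdr, ldb, p = fdr))
})

test_that("direction concordance mirrors the shared-locus table rows", {
  # concordant: both z negative (EP300-style row)
  expect_true(direction_concordance(-4.49, -4.95))
  # discordant: inverse association (8p23.1-style row)
  expect_false(direction_concordance(-4.46, 5.47))
  # palindromic lead: undefined, the printed NaN
  expect_true(is.na(direction_concordance(-4.0, 4.0, FALSE)))
  expect_true(is.na(direction_concordance(NA_real_, 2)))
  expect_warning(out <- direction_concordance(0, 2), "zero")
  expect_true(is.na(out))
})

test_that("concordance is invariant to the effect-allele labeling", {
  withr::with_seed(41, {
    z1 <- rnorm(20); z2 <- rnorm(20)
    base <- direction_concordance(z1, z2)
    # flip which allele is 'effect' on either trait: both z change sign
    expect_equal(direction_concordance(-z1, -z2), base)
  })
})

test_that("nearest-gene annotation picks minimal distance with tie rules", {
  genes <- data.table(chrom = c("1", "1", "2"),
                      start = c(1000L, 5000L, 100L),
                      end = c(2000L, 6000L, 200L),
                      name = c("GA", "GB", "GC"))
  mk_locus <- function(pos, chrom = "1") {
    data.table(locus = 1L, lead_snp = "x", n_snps = 1L, members = "x",
               chrom = chrom, pos = pos, a1 = "A", a2 = "G",
               conj_fdr = 0.01, z1 = 1, z2 = 1, p1 = 0.01, p2 = 0.01,
               direction_defined = TRUE, concordant = TRUE)
  }
  # inside a span: distance 0
  a <- annotate_nearest_gene(mk_locus(1500L), genes)
  expect_equal(a$nearest_gene, "GA")
  expect_equal(a$gene_distance, 0L)
  # equidistant (1 kb from GA end and GB start): smaller start wins
  b <- annotate_nearest_gene(mk_locus(3500L), genes)
  expect_equal(b$nearest_gene, "GA")
  expect_equal(b$gene_distance, 1500L)
  eq <- annotate_nearest_gene(mk_locus(3000L), genes)
  expect_equal(eq$nearest_gene, "GA")  # ties at 1000 bp -> smaller start
  # chromosome without genes
  c2 <- annotate_nearest_gene(mk_locus(100L, chrom = "9"), genes)
  expect_equal(c2$nearest_gene, "intergenic-unassigned")

  # random positions vs linear-scan oracle
  withr::with_seed(42, {
    for (k in 1:10) {
      pos <- sample.int(10000L, 1)
      got <- annotate_nearest_gene(mk_locus(pos), genes)
      g1 <- genes[chrom == "1"]
      d <- pmax(0L, pmax(g1$start - pos, pos - g1$end))
      want <- g1$name[order(d, g1$start, g1$name)[1]]
      expect_equal(got$nearest_gene, want)
      expect_equal(got$gene_distance, min(d))
    }
  })
})

test_that("gene files round-trip with coordinate conventions", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("chrom\tstart\tend\tname", "1\t999\t2000\tGA"), f)
  g0 <- read_genes(f)
  expect_equal(g0$start, 999L)
  g1 <- read_genes(f, zero_based = TRUE)
  expect_equal(g1$start, 1000L)
})

test_that("Manhattan export covers all SNPs with consistent flags", {
  withr::with_seed(43, {
    n <- 200
    res <- fake_result(sprintf("m%03d", 1:n),
                       chrom = sample(c("1", "2", "10"), n, TRUE),
                       pos = sample.int(1e6, n),
                       conj_fdr = runif(n, 0, 0.2))
  })
  ld <- ld_reference(snps = res$snp_id)
  loci <- define_loci(res, ld)
  man <- manhattan_export(res, loci)
  expect_equal(nrow(man), n)
  expect_equal(anyDuplicated(man$snp_id), 0)
  expect_equal(sum(man$lead), nrow(loci))
  expect_equal(man[order(snp_id), significant],
               res[order(snp_id), significant])
  # genome order: chromosomes in numeric order, positions ascending within
  expect_true(all(diff(order(as.numeric(man$chrom), man$pos)) == 1))
})
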