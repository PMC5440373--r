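#' Configuration for the paired-GWAS simulator
#'
#' Defines the generative model for two polygenic traits measured on
#' GWAS summary statistics: each SNP is null, causal for trait 1 only,
#' causal for trait 2 only, or shared, with mixture weights `pi`. Causal
#' standardized effects are Gaussian with scale `sigma_beta`; shared SNPs
#' draw correlated effects (`rho_shared`). z-scores have mean
#' `sqrt(n) * beta` and are mixed within exchangeable-correlation LD
#' blocks. Defaults mirror the scale class of a large psychiatric GWAS
#' pair: 2e5 SNPs, n1 = 82,315, n2 = 59,225, 52 substudies for trait 1,
#' MHC-like and 8p23.1-like extended-LD regions.
#'
#' @param n_snps SNP count (default 2e5).
#' @param pi mixture proportions `(null, trait1, trait2, shared)`, summing
#'   to 1 (default `c(0.90, 0.04, 0.04, 0.02)`).
#' @param rho_shared correlation of standardized effects within the shared
#'   component, in `[-1, 1]` (default 0.9).
#' @param sigma_beta1,sigma_beta2 per-allele standardized effect scales;
#'   default derived from `target_median_abs_z` so that causal SNPs have
#'   the stated median `|z|`.
#' @param target_median_abs_z median `|z|` of causal SNPs implied by the
#'   default effect scales (default 4).
#' @param n1,n2 GWAS sample sizes (defaults 82315 and 59225).
#' @param ld_block_mean mean LD-block size in SNPs (default 10).
#' @param r2_within representative within-block squared correlation
#'   (default 0.6); blocks degenerate to singletons in the LD reference if
#'   this does not exceed `r2_threshold`.
#' @param r2_threshold partner cutoff for the emitted LD reference
#'   (default 0.1).
#' @param palindromic_fraction fraction of A/T or C/G SNPs (default 0.1).
#' @param n_chrom chromosomes the SNPs are laid out on (default 22).
#' @param chrom_length base-pair length per chromosome; SNP spacing is
#'   `chrom_length / SNPs per chromosome` (default 1.35e8).
#' @param special_regions `data.table(chrom, start, end, label,
#'   multiplier)`: blocks starting inside these regions have their size
#'   multiplied, mimicking extended-LD regions; default MHC-like and
#'   8p23.1-like regions with multiplier 5.
#' @param n_substudies substudy count for [simulate_substudies()]
#'   (default 52).
#' @param substudy_n per-substudy sizes, summing to `n1` (default: equal
#'   split).
#' @param seed default RNG seed carried by the config.
#' @return validated list of class `sim_config`.
#' @export
sim_config <- function(n_snps = 2e5,
                       pi = c(null = 0.90, trait1 = 0.04,
                              trait2 = 0.04, shared = 0.02),
                       rho_shared = 0.9,
                       sigma_beta1 = NULL, sigma_beta2 = NULL,
                       target_median_abs_z = 4,
                       n1 = 82315, n2 = 59225,
                       ld_block_mean = 10, r2_within = 0.6,
                       r2_threshold = 0.1,
                       palindromic_fraction = 0.1,
                       n_chrom = 22, chrom_length = 1.35e8,
                       special_regions = NULL,
                       n_substudies = 52, substudy_n = NULL,
                       seed = NULL) {
  if (length(pi) != 4 || abs(sum(pi) - 1) > 1e-12 || any(pi < 0)) {
    stop2("pi must be 4 non-negative proportions summing to 1")
  }
  if (abs(rho_shared) > 1) stop2("rho_shared must lie in [-1, 1]")
  sigma_from_target <- function(n) {
    sqrt(((target_median_abs_z / qnorm(0.75))^2 - 1) / n)
  }
  sigma_beta1 <- sigma_beta1 %||% sigma_from_target(n1)
  sigma_beta2 <- sigma_beta2 %||% sigma_from_target(n2)
  if (sigma_beta1 <= 0 || sigma_beta2 <= 0) stop2("effect scales must be > 0")
  if (ld_block_mean < 1) stop2("ld_block_mean must be >= 1")
  if (ld_block_mean > n_snps) stop2("mean block size exceeds n_snps")
  if (r2_within < 0 || r2_within > 1) stop2("r2_within must lie in [0, 1]")
  if (is.null(special_regions)) {
    special_regions <- cbind(default_exclusion_regions(), multiplier = 5)
  }
  if (is.null(substudy_n)) {
    base <- n1 %/% n_substudies
    substudy_n <- rep(base, n_substudies)
    substudy_n[seq_len(n1 - base * n_substudies)] <- base + 1
  }
  if (abs(sum(substudy_n) - n1) > 1e-9) {
    stop2("substudy sizes must sum to n1")
  }
  structure(list(n_snps = as.integer(n_snps), pi = pi,
                 rho_shared = rho_shared, sigma_beta1 = sigma_beta1,
                 sigma_beta2 = sigma_beta2, n1 = n1, n2 = n2,
                 ld_block_mean = ld_block_mean, r2_within = r2_within,
                 r2_threshold = r2_threshold,
                 palindromic_fraction = palindromic_fraction,
                 n_chrom = as.integer(n_chrom),
                 chrom_length = chrom_length,
                 special_regions = as.data.table(special_regions),
                 n_substudies = as.integer(n_substudies),
                 substudy_n = substudy_n, seed = seed),
            class = "sim_config")
}

# genome layout: chrom labels, positions, LD-block assignment
sim_layout <- function(config) {
  n <- config$n_snps
  per_chrom <- rep(n %/% config$n_chrom, config$n_chrom)
  extra <- n - sum(per_chrom)
  if (extra > 0) per_chrom[seq_len(extra)] <- per_chrom[seq_len(extra)] + 1L
  chrom <- rep(as.character(seq_len(config$n_chrom)), per_chrom)
  spacing <- ceiling(config$chrom_length / max(per_chrom))
  pos <- unlist(lapply(per_chrom, function(m) seq_len(m) * spacing),
                use.names = FALSE)

  # blocks: sequential runs, never crossing a chromosome boundary;
  # runs starting inside a special region are stretched by its multiplier
  sr <- config$special_regions
  mult <- rep(1, n)
  for (k in seq_len(nrow(sr))) {
    hit <- chrom == sr$chrom[k] & pos >= sr$start[k] & pos <= sr$end[k]
    mult[hit] <- pmax(mult[hit], sr$multiplier[k])
  }
  chrom_end <- cumsum(per_chrom)
  chrom_code <- rep(seq_len(config$n_chrom), per_chrom)
  sizes <- 1L + rpois(n, max(config$ld_block_mean - 1, 0))
  block <- integer(n)
  bid <- 0L
  i <- 1L
  while (i <= n) {
    size <- as.integer(ceiling(sizes[i] * mult[i]))
    j <- min(i + size - 1L, n, chrom_end[chrom_code[i]])
    bid <- bid + 1L
    block[i:j] <- bid
    i <- j + 1L
  }
  data.table(snp_id = sprintf("s%07d", seq_len(n)), chrom = chrom,
             pos = as.integer(pos), block = block)
}

# draw effect-allele pairs; a fraction strand-ambiguous (A/T or C/G)
sim_alleles <- function(n, palindromic_fraction) {
  pal_pairs <- matrix(c("A", "T", "T", "A", "C", "G", "G", "C"),
                      ncol = 2, byrow = TRUE)
  npal_pairs <- matrix(c("A", "C", "A", "G", "C", "A", "C", "T",
                         "G", "A", "G", "T", "T", "C", "T", "G"),
                       ncol = 2, byrow = TRUE)
  pal <- runif(n) < palindromic_fraction
  pick_p <- sample.int(4, n, replace = TRUE)
  pick_n <- sample.int(8, n, replace = TRUE)
  a1 <- ifelse(pal, pal_pairs[pick_p, 1], npal_pairs[pick_n, 1])
  a2 <- ifelse(pal, pal_pairs[pick_p, 2], npal_pairs[pick_n, 2])
  data.table(a1 = a1, a2 = a2, palindromic = pal)
}

#' Simulate a pair of GWAS summary-statistics panels with ground truth
#'
#' Generates the full inputs of the cross-trait pipeline: two
#' summary-statistics tables, the per-SNP ground truth, an LD reference,
#' and the extended-LD region table. Per SNP a causal component is drawn
#' from `pi`; shared SNPs draw correlated standardized effects; z-scores
#' are `R mu + eps`, with `mu = sqrt(n) beta`, `R` the exchangeable
#' within-block correlation matrix with off-diagonal
#' `r = sqrt(r2_within)`, and `eps ~ N(0, R)` — so LD both spreads signal
#' across block-mates and correlates their noise. Trait-2 records are
#' written in a randomly re-oriented allele representation (swaps and
#' strand complements) to exercise harmonization; the underlying effects
#' are generated on trait-1's effect allele.
#'
#' @param config a [sim_config()].
#' @param seed RNG seed (default `config$seed`).
#' @return list with `trait1`, `trait2` (canonical summary-statistics
#'   `data.table`s), `truth` (`snp_id, component, beta1, beta2, block`),
#'   `ld` ([ld_reference()]), `regions`, and `config`.
#' @export
simulate_pair <- function(config = sim_config(), seed = config$seed) {
  with_seed2(seed, {
    lay <- sim_layout(config)
    n <- config$n_snps
    comp <- sample.int(4L, n, replace = TRUE, prob = config$pi)
    beta1 <- numeric(n); beta2 <- numeric(n)
    beta1[comp == 2L] <- rnorm(sum(comp == 2L), 0, config$sigma_beta1)
    beta2[comp == 3L] <- rnorm(sum(comp == 3L), 0, config$sigma_beta2)
    ns <- sum(comp == 4L)
    if (ns) {
      x <- rnorm(ns); y <- rnorm(ns)
      rho <- config$rho_shared
      beta1[comp == 4L] <- config$sigma_beta1 * x
      beta2[comp == 4L] <- config$sigma_beta2 *
        (rho * x + sqrt(1 - rho^2) * y)
    }
    r <- sqrt(config$r2_within)
    mix <- function(mu) {
      s <- rowsum(mu, lay$block)[lay$block]
      m <- (1 - r) * mu + r * s
      g <- rnorm(max(lay$block))
      m + sqrt(1 - r) * rnorm(n) + sqrt(r) * g[lay$block]
    }
    z1 <- mix(sqrt(config$n1) * beta1)
    z2 <- mix(sqrt(config$n2) * beta2)
    al <- sim_alleles(n, config$palindromic_fraction)

    trait1 <- data.table(snp_id = lay$snp_id, chrom = lay$chrom,
                         pos = lay$pos, a1 = al$a1, a2 = al$a2,
                         z = z1, p = z_to_p(z1), n = config$n1)
    # re-orient trait 2's file representation at random
    swap <- runif(n) < 0.3
    flip_strand <- runif(n) < 0.3
    a1_2 <- ifelse(swap, al$a2, al$a1)
    a2_2 <- ifelse(swap, al$a1, al$a2)
    a1_2 <- ifelse(flip_strand, comp_allele(a1_2), a1_2)
    a2_2 <- ifelse(flip_strand, comp_allele(a2_2), a2_2)
    z2_file <- ifelse(swap, -z2, z2)
    trait2 <- data.table(snp_id = lay$snp_id, chrom = lay$chrom,
                         pos = lay$pos, a1 = a1_2, a2 = a2_2,
                         z = z2_file, p = z_to_p(z2_file), n = config$n2)

    truth <- data.table(snp_id = lay$snp_id,
                        component = c("null", "trait1", "trait2",
                                      "shared")[comp],
                        beta1 = beta1, beta2 = beta2, block = lay$block)
    ld <- if (config$r2_within > config$r2_threshold) {
      ld_reference(blocks = lay[, .(snp_id, block)],
                   r2_threshold = config$r2_threshold)
    } else {
      ld_reference(snps = lay$snp_id, r2_threshold = config$r2_threshold)
    }
    list(trait1 = trait1, trait2 = trait2, truth = truth, ld = ld,
         regions = config$special_regions[, .(chrom, start, end, label)],
         config = config)
  })
}

#' Simulate a substudy panel consistent with trait 1
#'
#' Substudy `k`'s z-score for SNP `i` is `N(sqrt(n_k) beta1_i, 1)`,
#' independent across substudies, so the sample-size-weighted Stouffer
#' combination over all substudies reproduces trait-1's full-sample mean
#' structure `sqrt(n1) beta1`.
#'
#' @param config a [sim_config()].
#' @param truth `truth` table from [simulate_pair()].
#' @param seed RNG seed.
#' @return a [substudy_panel()].
#' @export
simulate_substudies <- function(config, truth, seed = NULL) {
  truth <- as.data.table(truth)
  with_seed2(seed, {
    n <- nrow(truth)
    K <- config$n_substudies
    Z <- matrix(rnorm(n * K), n, K)
    Z <- Z + outer(truth$beta1, sqrt(config$substudy_n))
    rownames(Z) <- truth$snp_id
    substudy_panel(Z, n = config$substudy_n,
                   labels = sprintf("sub%02d", seq_len(K)))
  })
}

#' Simulate a gene-annotation table
#'
#' Random non-overlapping-ish gene intervals laid across the simulated
#' genome, for exercising nearest-gene annotation. Synthetic labels
#' (`GENE00001`, ...).
#'
#' @param config a [sim_config()].
#' @param n_genes total gene count (default 500).
#' @param seed RNG seed.
#' @return `data.table(chrom, start, end, name)`.
#' @export
simulate_genes <- function(config, n_genes = 500, seed = NULL) {
  with_seed2(seed, {
    chrom <- sample(as.character(seq_len(config$n_chrom)), n_genes,
                    replace = TRUE)
    start <- as.integer(runif(n_genes, 1, config$chrom_length * 0.98))
    width <- as.integer(runif(n_genes, 5e3, 2e5))
    dt <- data.table(chrom = chrom, start = start,
                     end = start + width,
                     name = sprintf("GENE%05d", seq_len(n_genes)))
    setorder(dt, chrom, start)
    dt[]
  })
}

#' Write a simulated dataset in the file dialects the readers consume
#'
#' @param sim output of [simulate_pair()].
#' @param dir output directory (created if needed).
#' @return named character vector of the file paths written.
#' @export
write_dataset <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(trait1 = file.path(dir, "trait1.tsv"),
             trait2 = file.path(dir, "trait2.tsv"),
             ld = file.path(dir, "ld_blocks.tsv"),
             regions = file.path(dir, "regions.tsv"),
             truth = file.path(dir, "truth.tsv"))
  write_sumstats(sim$trait1, paths[["trait1"]])
  write_sumstats(sim$trait2, paths[["trait2"]])
  write_ld(sim$ld, paths[["ld"]])
  fwrite(sim$regions, paths[["regions"]], sep = "\t")
  fwrite(sim$truth, paths[["truth"]], sep = "\t")
  paths
}
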