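#' Convert a signed z-score to a two-sided p-value
#'
#' `p = 2 * pnorm(-|z|)`, floored at `p_floor` so that downstream log-scale
#' grids never see an exact zero.
#'
#' @param z numeric vector of signed z-scores (finite).
#' @param p_floor smallest p-value returned (default `1e-300`).
#' @return numeric vector of two-sided p-values in `(0, 1]`.
#' @seealso [p_to_z()] for the inverse (magnitude only).
#' @export
#' @examples
#' z_to_p(0)        # 1
#' z_to_p(-4.49)    # ~7.0e-6
z_to_p <- function(z, p_floor = 1e-300) {
  if (any(!is.finite(z))) stop2("z must be finite")
  pmax(2 * pnorm(-abs(z)), p_floor)
}

#' Convert a two-sided p-value to a z-score magnitude
#'
#' @param p numeric vector of p-values in `(0, 1]`.
#' @return `|z|` such that `2 * pnorm(-|z|) = p`.
#' @export
p_to_z <- function(p) {
  if (any(!is.finite(p)) || any(p <= 0) || any(p > 1)) {
    stop2("p must lie in (0, 1]")
  }
  qnorm(p / 2, lower.tail = FALSE)
}

default_column_map <- function() {
  c(snp_id = "SNP", chrom = "CHR", pos = "BP", a1 = "A1", a2 = "A2",
    z = "Z", p = "P", n = "N")
}

#' Validate an in-memory summary-statistics table
#'
#' Applies the per-row invariants of a GWAS summary-statistics record:
#' p in (0, 1], alleles in A/C/G/T with a1 != a2, and (when both are
#' present) z/p consistency `|2 * pnorm(-|z|) - p| / p <= tol`. Rows failing
#' any check are removed and reported; duplicated `snp_id` or duplicated
#' (chrom, pos) is fatal.
#'
#' @param x data.frame with columns `snp_id, chrom, pos, a1, a2, z, p` and
#'   optionally `n`; `z` may be `NA` (magnitude-only record).
#' @param zp_tol relative tolerance for z/p consistency (default 0.05,
#'   tolerating z printed to two decimals).
#' @param p_floor clip applied to p before the consistency check.
#' @return validated `data.table`; attribute `"rejections"` holds a table
#'   of the removed rows with a `reason` column.
#' @export
as_sumstats <- function(x, zp_tol = 0.05, p_floor = 1e-300) {
  need <- c("snp_id", "chrom", "pos", "a1", "a2", "p")
  miss <- setdiff(need, names(x))
  if (length(miss)) stop2("missing columns: ", paste(miss, collapse = ", "))
  dt <- as.data.table(x)
  if (!"z" %in% names(dt)) dt[, z := NA_real_]
  if (!"n" %in% names(dt)) dt[, n := NA_real_]
  dt[, `:=`(snp_id = as.character(snp_id), chrom = as.character(chrom),
            pos = as.integer(pos), a1 = toupper(a1), a2 = toupper(a2),
            z = as.numeric(z), p = as.numeric(p), n = as.numeric(n))]

  if (anyDuplicated(dt$snp_id)) stop2("duplicate snp_id in summary statistics")
  if (anyDuplicated(dt[, .(chrom, pos)])) {
    stop2("duplicate (chrom, pos) in summary statistics")
  }

  reason <- rep(NA_character_, nrow(dt))
  bad_p <- !is.finite(dt$p) | dt$p <= 0 | dt$p > 1
  reason[bad_p] <- "p outside (0,1]"
  ok_allele <- dt$a1 %in% c("A", "C", "G", "T") &
    dt$a2 %in% c("A", "C", "G", "T") & dt$a1 != dt$a2
  reason[is.na(reason) & !ok_allele] <- "invalid alleles"
  has_z <- !is.na(dt$z)
  pz <- ifelse(has_z, pmax(2 * pnorm(-abs(dt$z)), p_floor), NA_real_)
  inconsistent <- has_z & is.na(reason) &
    abs(pz - pmax(dt$p, p_floor)) / pmax(dt$p, p_floor) > zp_tol
  reason[inconsistent] <- "z/p inconsistent"

  keep <- is.na(reason)
  rejected <- dt[!keep]
  set(rejected, j = "reason", value = reason[!keep])
  out <- dt[keep]
  setattr(out, "rejections", rejected)
  out[]
}

#' Read a GWAS summary-statistics file
#'
#' Reads a tab- or whitespace-delimited file with a header, maps columns to
#' the canonical names, and validates every row (see [as_sumstats()]).
#'
#' @param path file path.
#' @param column_map named character vector mapping canonical field names
#'   (`snp_id, chrom, pos, a1, a2, z, p, n`) to header names in the file;
#'   defaults to `SNP/CHR/BP/A1/A2/Z/P/N`. Extra columns are ignored; `z`
#'   and `n` are optional.
#' @param report_path optional path for a tab-delimited rejection report.
#' @inheritParams as_sumstats
#' @return validated `data.table` of records (attribute `"rejections"` as
#'   in [as_sumstats()]).
#' @export
read_sumstats <- function(path, column_map = NULL, zp_tol = 0.05,
                          report_path = NULL) {
  if (!file.exists(path)) stop2("cannot read file: ", path)
  cm <- default_column_map()
  if (!is.null(column_map)) cm[names(column_map)] <- unlist(column_map)
  raw <- fread(path, header = TRUE)
  required <- cm[c("snp_id", "chrom", "pos", "a1", "a2", "p")]
  miss <- setdiff(required, names(raw))
  if (length(miss)) stop2("mapped column(s) absent from file: ",
                          paste(miss, collapse = ", "))
  present <- cm[cm %in% names(raw)]
  dt <- raw[, unname(present), with = FALSE]
  setnames(dt, unname(present), names(present))
  out <- as_sumstats(dt, zp_tol = zp_tol)
  rej <- attr(out, "rejections")
  if (nrow(rej) && !is.null(report_path)) {
    fwrite(rej, report_path, sep = "\t")
  }
  if (nrow(rej)) {
    message(nrow(rej), " row(s) rejected while reading ", basename(path))
  }
  out
}

#' Write summary statistics in the canonical dialect
#'
#' @param x validated summary-statistics table.
#' @param path output path (tab-delimited, header `SNP CHR BP A1 A2 Z P N`).
#' @return `path`, invisibly.
#' @export
write_sumstats <- function(x, path) {
  out <- as.data.table(x)[, .(SNP = snp_id, CHR = chrom, BP = pos,
                              A1 = a1, A2 = a2, Z = z, P = p, N = n)]
  fwrite(out, path, sep = "\t", na = "NA", quote = FALSE)
  invisible(path)
}

#' Re-orient one trait's alleles and z-scores onto another's effect allele
#'
#' Vectorized allele harmonization between two studies of the same SNPs.
#' Trait-2 statistics are expressed in trait-1's (a1, a2) orientation:
#' matching alleles (directly or as strand complements) keep `z2`; swapped
#' alleles (trait-2 effect allele equals trait-1 other allele, directly or
#' as complements) flip the sign of `z2`. Palindromic SNPs (A/T or C/G)
#' cannot be strand-resolved, so their direction is undefined: `z2` is
#' returned `NA` with `direction_defined = FALSE` (their p-values remain
#' valid). Incompatible allele sets are flagged for dropping.
#'
#' @param a1_1,a2_1 trait-1 effect and other alleles.
#' @param a1_2,a2_2 trait-2 effect and other alleles.
#' @param z2 trait-2 signed z-scores (may be `NA`).
#' @return `data.table` with columns `z2` (re-oriented), `direction_defined`
#'   and `drop` (incompatible alleles).
#' @export
#' @examples
#' harmonize_alleles("A", "G", "G", "A", -2)  # swap: z2 becomes +2
harmonize_alleles <- function(a1_1, a2_1, a1_2, a2_2, z2) {
  n <- length(a1_1)
  pal <- is_palindromic(a1_1, a2_1) | is_palindromic(a1_2, a2_2)
  same <- (a1_2 == a1_1 & a2_2 == a2_1) |
    (a1_2 == comp_allele(a1_1) & a2_2 == comp_allele(a2_1))
  swap <- (a1_2 == a2_1 & a2_2 == a1_1) |
    (a1_2 == comp_allele(a2_1) & a2_2 == comp_allele(a1_1))
  drop <- !pal & !same & !swap
  z_out <- rep(NA_real_, n)
  keepz <- !pal & same
  flipz <- !pal & !same & swap
  z_out[keepz] <- z2[keepz]
  z_out[flipz] <- -z2[flipz]
  data.table(z2 = z_out, direction_defined = !pal & !drop, drop = drop)
}

#' Join two traits' summary statistics into harmonized pairs
#'
#' Inner join on `snp_id` followed by allele harmonization
#' ([harmonize_alleles()]). Pairs with incompatible allele sets are dropped
#' and counted; palindromic SNPs are retained with
#' `direction_defined = FALSE` and `z2 = NA` (p-values untouched).
#'
#' @param records1,records2 validated summary-statistics tables
#'   ([as_sumstats()]).
#' @return `data.table` with columns `snp_id, chrom, pos, a1, a2, z1, p1,
#'   n1, z2, p2, n2, direction_defined` (alleles in trait-1 orientation).
#'   Attribute `"counts"`: named vector of `shared`, `trait1_only`,
#'   `trait2_only`, `dropped`.
#' @export
intersect_traits <- function(records1, records2) {
  r1 <- as.data.table(records1)
  r2 <- as.data.table(records2)
  shared_ids <- intersect(r1$snp_id, r2$snp_id)
  if (!length(shared_ids)) stop2("no SNPs shared between the two traits")
  m1 <- r1[snp_id %chin% shared_ids]
  m2 <- r2[m1, on = "snp_id"][, .(snp_id, a1_2 = a1, a2_2 = a2,
                                  z2 = z, p2 = p, n2 = n)]
  h <- harmonize_alleles(m1$a1, m1$a2, m2$a1_2, m2$a2_2, m2$z2)
  pairs <- data.table(
    snp_id = m1$snp_id, chrom = m1$chrom, pos = m1$pos,
    a1 = m1$a1, a2 = m1$a2,
    z1 = m1$z, p1 = m1$p, n1 = m1$n,
    z2 = h$z2, p2 = m2$p2, n2 = m2$n2,
    direction_defined = h$direction_defined
  )
  dropped <- sum(h$drop)
  pairs <- pairs[!h$drop]
  counts <- c(shared = nrow(pairs),
              trait1_only = nrow(r1) - length(shared_ids),
              trait2_only = nrow(r2) - length(shared_ids),
              dropped = dropped)
  setattr(pairs, "counts", counts)
  pairs[]
}

#' Genomic-control inflation correction
#'
#' Estimates the genomic inflation factor
#' `lambda = median(z^2) / qchisq(0.5, 1)` on a null-representative SNP
#' subset and deflates all z-scores by `sqrt(lambda)`, recomputing p-values.
#' The default subset is one random SNP per LD block ([random_prune()]);
#' without an LD reference (or below `min_subset` SNPs) all SNPs are used.
#'
#' @param records summary-statistics table with `z` (and `p`) columns;
#'   rows with missing `z` get `|z|` derived from `p` for the estimate and
#'   are corrected on the p-scale.
#' @param ld optional [ld_reference()] used to prune the estimation subset.
#' @param null_snps optional explicit character vector of SNP ids defining
#'   the estimation subset (overrides `ld`).
#' @param seed RNG seed for the random pruning.
#' @param min_subset smallest admissible subset; below it the subset falls
#'   back to all SNPs with a warning (default 100).
#' @return list with `records` (corrected table: `z`, `p` updated),
#'   `lambda`, and `subset` (label of the subset used).
#' @export
genomic_control <- function(records, ld = NULL, null_snps = NULL,
                            seed = NULL, min_subset = 100) {
  dt <- copy(as.data.table(records))
  zabs <- ifelse(is.na(dt$z), p_to_z(dt$p), abs(dt$z))
  subset_label <- "all SNPs"
  idx <- rep(TRUE, nrow(dt))
  if (!is.null(null_snps)) {
    idx <- dt$snp_id %chin% null_snps
    subset_label <- "user-supplied subset"
  } else if (!is.null(ld)) {
    kept <- random_prune(dt$snp_id, ld, seed = seed)
    idx <- dt$snp_id %chin% kept
    subset_label <- "random-pruned (one SNP per LD block)"
  }
  if (sum(idx) < min_subset) {
    if (subset_label != "all SNPs") {
      warn2("inflation subset has ", sum(idx), " SNPs (< ", min_subset,
            "); falling back to all SNPs")
    }
    idx <- rep(TRUE, nrow(dt))
    subset_label <- "all SNPs"
  }
  lambda <- median(zabs[idx]^2) / CHISQ1_MEDIAN
  zc <- zabs / sqrt(lambda)
  dt[, p := z_to_p(zc)]
  dt[, z := ifelse(is.na(z), NA_real_, z / sqrt(lambda))]
  list(records = dt[],
       lambda = lambda,
       subset = subset_label)
}

#' Genomic-control correction of a harmonized pair table
#'
#' Applies [genomic_control()] separately to the two traits of a
#' harmonized pair table, each with its own inflation factor.
#'
#' @param pairs output of [intersect_traits()].
#' @inheritParams genomic_control
#' @return list with `pairs` (corrected), `lambda1`, `lambda2`.
#' @export
genomic_control_pairs <- function(pairs, ld = NULL, null_snps = NULL,
                                  seed = NULL, min_subset = 100) {
  dt <- as.data.table(pairs)
  t1 <- genomic_control(dt[, .(snp_id, z = z1, p = p1)], ld = ld,
                        null_snps = null_snps, seed = seed,
                        min_subset = min_subset)
  t2 <- genomic_control(dt[, .(snp_id, z = z2, p = p2)], ld = ld,
                        null_snps = null_snps, seed = seed,
                        min_subset = min_subset)
  out <- copy(dt)
  out[, `:=`(z1 = t1$records$z, p1 = t1$records$p,
             z2 = t2$records$z, p2 = t2$records$p)]
  list(pairs = out[], lambda1 = t1$lambda, lambda2 = t2$lambda)
}
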