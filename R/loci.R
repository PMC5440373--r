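#' Cluster significant SNPs into shared loci
#'
#' Significant SNPs (conjunction FDR below threshold) are clustered into
#' LD blocks — connected components of the `r^2 > threshold` graph
#' restricted to the significant set; a block may contain more than one
#' SNP. The lead SNP of each locus minimizes the conjunction FDR
#' (tie-break: smaller `p1`, then lexicographic id), and loci are numbered
#' by genomic order of their leads.
#'
#' @param result a `conjunction_result` ([conjunction_fdr()]).
#' @param ld an [ld_reference()].
#' @return `data.table` with one row per locus: `locus, lead_snp, n_snps,
#'   members` (comma-joined ids), lead `chrom, pos, a1, a2, conj_fdr, z1,
#'   z2, p1, p2, direction_defined, concordant`. Empty (zero-row) when
#'   nothing is significant.
#' @export
define_loci <- function(result, ld) {
  dt <- as.data.table(result)
  sig <- dt[significant == TRUE]
  if (!nrow(sig)) {
    return(data.table(locus = integer(0), lead_snp = character(0),
                      n_snps = integer(0), members = character(0),
                      chrom = character(0), pos = integer(0),
                      a1 = character(0), a2 = character(0),
                      conj_fdr = numeric(0), z1 = numeric(0),
                      z2 = numeric(0), p1 = numeric(0), p2 = numeric(0),
                      direction_defined = logical(0),
                      concordant = logical(0)))
  }
  ids <- sig$snp_id
  adj <- adjacency_within(ld, ids)
  edges <- rbindlist(lapply(ids, function(s) {
    if (length(adj[[s]])) data.table(a = s, b = adj[[s]]) else NULL
  }))
  comp <- if (!is.null(edges) && nrow(edges)) {
    g <- igraph::graph_from_data_frame(edges, directed = FALSE,
                                       vertices = ids)
    igraph::components(g)$membership[ids]
  } else {
    stats::setNames(seq_along(ids), ids)
  }
  sig[, component := comp[snp_id]]
  setorder(sig, conj_fdr, p1, snp_id)
  leads <- sig[, .SD[1L], by = component]
  members <- sig[, .(members = paste(sort(snp_id), collapse = ","),
                     n_snps = .N), by = component]
  loci <- leads[members, on = "component"]
  chrom_rank <- suppressWarnings(as.numeric(loci$chrom))
  ord <- order(is.na(chrom_rank), chrom_rank, loci$chrom, loci$pos)
  loci <- loci[ord]
  loci[, locus := seq_len(.N)]
  loci[, concordant := direction_concordance(z1, z2, direction_defined)]
  loci[, .(locus, lead_snp = snp_id, n_snps, members, chrom, pos, a1, a2,
           conj_fdr, z1, z2, p1, p2, direction_defined, concordant)]
}

#' Allelic effect-direction concordance
#'
#' A locus is direction-concordant when its lead SNP's z-scores, expressed
#' on the same effect allele, agree in sign: `sign(z1) * sign(z2) > 0`.
#' Undefined (`NA`) for strand-ambiguous (palindromic) leads — the case
#' printed as NaN in shared-locus tables — and when a z-score is zero or
#' missing.
#'
#' @param z1,z2 lead z-scores in a common allele orientation.
#' @param direction_defined logical; `FALSE` for palindromic SNPs.
#' @return logical vector (`NA` = undefined).
#' @export
direction_concordance <- function(z1, z2, direction_defined = TRUE) {
  out <- sign(z1) * sign(z2) > 0
  zero <- !is.na(z1) & !is.na(z2) & (z1 == 0 | z2 == 0)
  if (any(zero)) warn2("zero z-score(s): concordance undefined")
  out[zero | !direction_defined | is.na(z1) | is.na(z2)] <- NA
  out
}

#' Read a BED-like gene annotation table
#'
#' @param path file with columns chrom, start, end, name (header).
#' @param zero_based is the file BED-convention (0-based half-open)?
#' @return `data.table(chrom, start, end, name)` (1-based inclusive).
#' @export
read_genes <- function(path, zero_based = FALSE) {
  dt <- fread(path, header = TRUE)
  setnames(dt, names(dt)[1:4], c("chrom", "start", "end", "name"))
  dt[, `:=`(chrom = as.character(chrom), start = as.integer(start),
            end = as.integer(end), name = as.character(name))]
  if (zero_based) dt[, start := start + 1L]
  dt[]
}

#' Annotate loci with the nearest gene
#'
#' Labels each locus with the gene interval closest to its lead SNP
#' (distance 0 when the lead lies inside the gene span; ties broken by
#' smaller gene start, then lexicographic name). Loci on chromosomes
#' without any annotated gene get `"intergenic-unassigned"`.
#'
#' @param loci output of [define_loci()].
#' @param genes annotation `data.table(chrom, start, end, name)`
#'   (see [read_genes()]); same coordinate convention as the SNPs.
#' @return `loci` with added `nearest_gene` and `gene_distance` columns.
#' @export
annotate_nearest_gene <- function(loci, genes) {
  genes <- as.data.table(genes)
  loci <- copy(as.data.table(loci))
  nearest <- character(nrow(loci))
  dist_out <- rep(NA_integer_, nrow(loci))
  for (k in seq_len(nrow(loci))) {
    g <- genes[chrom == loci$chrom[k]]
    if (!nrow(g)) {
      nearest[k] <- "intergenic-unassigned"
      next
    }
    pos <- loci$pos[k]
    d <- pmax(0L, pmax(g$start - pos, pos - g$end))
    best <- order(d, g$start, g$name)[1L]
    nearest[k] <- g$name[best]
    dist_out[k] <- d[best]
  }
  loci[, `:=`(nearest_gene = nearest, gene_distance = dist_out)]
  loci[]
}

#' Export Manhattan-plot data
#'
#' One row per scored SNP with its `-log10` FDR value, significance flag
#' and lead-SNP flag, in genome order — the data content of a conjunction
#' (or conditional) FDR Manhattan plot in which significant SNPs are
#' enlarged and the strongest SNP per LD block is encircled.
#'
#' @param result a `conjunction_result`.
#' @param loci output of [define_loci()] on the same result.
#' @param kind `"conjunction"` (plots `conj_fdr`) or `"conditional"`
#'   (plots `cfdr_1g2` or `cfdr_2g1` per `direction`).
#' @param direction for `kind = "conditional"`: `"1|2"` or `"2|1"`.
#' @return `data.table(snp_id, chrom, pos, neg_log10_fdr, significant,
#'   lead)` sorted by genome order.
#' @export
manhattan_export <- function(result, loci,
                             kind = c("conjunction", "conditional"),
                             direction = "1|2") {
  kind <- match.arg(kind)
  dt <- as.data.table(result)
  val <- switch(kind,
                conjunction = dt$conj_fdr,
                conditional = if (direction == "1|2") dt$cfdr_1g2
                              else dt$cfdr_2g1)
  out <- data.table(snp_id = dt$snp_id, chrom = dt$chrom, pos = dt$pos,
                    neg_log10_fdr = neg_log10(val),
                    significant = dt$significant,
                    lead = dt$snp_id %chin% loci$lead_snp)
  chrom_rank <- suppressWarnings(as.numeric(out$chrom))
  out[order(is.na(chrom_rank), chrom_rank, chrom, pos)]
}
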