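#' LD reference: r-squared partner graph and LD blocks
#'
#' Represents linkage disequilibrium among SNPs as the graph whose edges
#' connect pairs with pairwise `r^2 > r2_threshold` (strict). LD blocks are
#' the connected components of that graph; SNPs without any partner form
#' singleton blocks. The reference can be built from an explicit pairwise
#' edge list or from a precomputed block assignment; in the latter case
#' every pair of SNPs sharing a block is treated as an r-squared partner
#' (complete graph within the block).
#'
#' @param edges data.frame with columns `a, b, r2` (SNP-id pair and their
#'   squared correlation). Edges with `r2 <= r2_threshold` are discarded;
#'   self-pairs are dropped with a warning; the symmetric closure is
#'   implied.
#' @param blocks block assignment instead of `edges`: a data.frame with
#'   columns `snp_id, block`, or a named vector of block labels.
#' @param snps optional SNP universe; ids absent from `edges`/`blocks`
#'   become singleton blocks.
#' @param r2_threshold squared-correlation cutoff (default 0.1, strict
#'   `>`).
#' @return object of class `ld_reference` with elements `edges`
#'   (`data.table(a, b)` or `NULL`), `block_of` (named integer vector) and
#'   `r2_threshold`.
#' @export
ld_reference <- function(edges = NULL, blocks = NULL, snps = NULL,
                         r2_threshold = 0.1) {
  if (!is.null(edges) && !is.null(blocks)) {
    stop2("supply either edges or blocks, not both")
  }
  edge_dt <- NULL
  block_of <- integer(0)
  if (!is.null(edges)) {
    e <- as.data.table(edges)
    setnames(e, names(e)[1:3], c("a", "b", "r2"))
    e[, `:=`(a = as.character(a), b = as.character(b), r2 = as.numeric(r2))]
    if (any(!is.finite(e$r2) | e$r2 < 0 | e$r2 > 1)) {
      stop2("r2 values must lie in [0, 1]")
    }
    selfp <- e$a == e$b
    if (any(selfp)) {
      warn2(sum(selfp), " self-pair(s) ignored in LD input")
      e <- e[!selfp]
    }
    e <- e[r2 > r2_threshold]
    # canonical undirected representation
    edge_dt <- unique(data.table(a = pmin(e$a, e$b), b = pmax(e$a, e$b)))
    ids <- unique(c(edge_dt$a, edge_dt$b, as.character(snps)))
    if (nrow(edge_dt)) {
      g <- igraph::graph_from_data_frame(edge_dt, directed = FALSE,
                                         vertices = ids)
      block_of <- igraph::components(g)$membership
      storage.mode(block_of) <- "integer"
    } else {
      block_of <- stats::setNames(seq_along(ids), ids)
    }
  } else if (!is.null(blocks)) {
    if (is.data.frame(blocks)) {
      b <- as.data.table(blocks)
      setnames(b, names(b)[1:2], c("snp_id", "block"))
      lab <- stats::setNames(as.character(b$block), as.character(b$snp_id))
    } else {
      lab <- stats::setNames(as.character(blocks), names(blocks))
    }
    extra <- setdiff(as.character(snps), names(lab))
    if (length(extra)) {
      lab <- c(lab, stats::setNames(paste0(".singleton.", extra), extra))
    }
    block_of <- stats::setNames(as.integer(factor(lab)), names(lab))
  } else {
    ids <- as.character(snps)
    block_of <- stats::setNames(seq_along(ids), ids)
  }
  structure(list(edges = edge_dt, block_of = block_of,
                 r2_threshold = r2_threshold),
            class = "ld_reference")
}

#' @export
print.ld_reference <- function(x, ...) {
  cat("ld_reference:", length(x$block_of), "SNPs,",
      length(unique(x$block_of)), "blocks, r2 >", x$r2_threshold,
      if (is.null(x$edges)) "(block-defined)\n" else "(pairwise edges)\n")
  invisible(x)
}

#' Load an LD reference from a file
#'
#' Auto-detects the dialect: a 3-column file (`id_a id_b r2`) is read as a
#' pairwise r-squared list, a 2-column file (`id block`) as a precomputed
#' block assignment.
#'
#' @inheritParams ld_reference
#' @param path file path (tab/whitespace-delimited, header required).
#' @return an [ld_reference()].
#' @export
load_ld <- function(path, r2_threshold = 0.1, snps = NULL) {
  dt <- fread(path, header = TRUE)
  if (ncol(dt) >= 3) {
    ld_reference(edges = dt[, 1:3], snps = snps, r2_threshold = r2_threshold)
  } else if (ncol(dt) == 2) {
    ld_reference(blocks = dt, snps = snps, r2_threshold = r2_threshold)
  } else {
    stop2("LD file must have 2 (block) or 3 (pairwise) columns")
  }
}

# block membership for a set of ids; unknown ids become fresh singletons
block_ids <- function(ids, ld, warn_unknown = TRUE) {
  bl <- ld$block_of[ids]
  unknown <- is.na(bl)
  if (any(unknown)) {
    if (warn_unknown) {
      warn2(sum(unknown), " SNP(s) unknown to the LD reference; ",
            "treated as singleton blocks")
    }
    bl[unknown] <- max(ld$block_of, 0L) + seq_len(sum(unknown))
  }
  stats::setNames(as.integer(bl), ids)
}

#' Neighbors in the r-squared partner graph, within a candidate set
#'
#' @param ld an [ld_reference()].
#' @param ids SNP ids delimiting the subgraph.
#' @return named list: for each id, the character vector of its partners
#'   among `ids`.
#' @keywords internal
adjacency_within <- function(ld, ids) {
  adj <- stats::setNames(vector("list", length(ids)), ids)
  if (is.null(ld$edges)) {
    bl <- block_ids(ids, ld, warn_unknown = FALSE)
    for (grp in split(ids, bl)) {
      if (length(grp) > 1) for (s in grp) adj[[s]] <- setdiff(grp, s)
    }
  } else {
    e <- ld$edges[a %chin% ids & b %chin% ids]
    if (nrow(e)) {
      pairs <- data.table(from = c(e$a, e$b), to = c(e$b, e$a))
      lst <- split(pairs$to, pairs$from)
      adj[names(lst)] <- lst
    }
  }
  adj
}

#' Random pruning: one random SNP per LD block
#'
#' Selects exactly one SNP, uniformly at random, from every LD block
#' intersecting the input set. Deterministic for a given seed and
#' independent of the input ordering.
#'
#' @param snps character vector of SNP ids.
#' @param ld an [ld_reference()]; ids unknown to it count as singleton
#'   blocks (warned).
#' @param seed integer RNG seed.
#' @return character vector of retained SNP ids.
#' @export
random_prune <- function(snps, ld, seed = NULL) {
  if (!length(snps)) stop2("empty SNP set")
  ids <- sort(unique(as.character(snps)))
  bl <- block_ids(ids, ld)
  with_seed2(seed, {
    u <- runif(length(ids))
    dt <- data.table(snp_id = ids, block = bl, u = u)
    dt[dt[, .I[which.min(u)], by = block]$V1, snp_id]
  })
}

#' A genomic region (1-based, inclusive)
#'
#' @param chrom chromosome label.
#' @param start,end 1-based inclusive bounds, `start <= end`.
#' @param label region name.
#' @return one-row `data.table(chrom, start, end, label)`.
#' @export
genomic_region <- function(chrom, start, end, label = "") {
  if (any(start > end)) stop2("region start must be <= end")
  data.table(chrom = as.character(chrom), start = as.integer(start),
             end = as.integer(end), label = as.character(label))
}

#' Default extended-LD exclusion regions
#'
#' The extended major histocompatibility complex (MHC) on chromosome 6 and
#' the 8p23.1 inversion region on chromosome 8 — two regions of intricate
#' long-range LD conventionally excluded when fitting genome-wide FDR
#' models. Coordinates are editable; they ship as the values used
#' throughout this package's defaults.
#'
#' @return `data.table(chrom, start, end, label)` with two rows.
#' @export
default_exclusion_regions <- function() {
  rbind(genomic_region("6", 25652429L, 33368333L, "MHC"),
        genomic_region("8", 7242715L, 12483982L, "8p23.1"))
}

#' Read a BED-like region file
#'
#' Four columns: chrom, start, end, label. Internally regions are 1-based
#' inclusive; set `zero_based = TRUE` for BED-convention input (half-open,
#' 0-based starts).
#'
#' @param path file path.
#' @param zero_based is the file 0-based half-open (BED) rather than
#'   1-based inclusive?
#' @return `data.table(chrom, start, end, label)`.
#' @export
read_regions <- function(path, zero_based = FALSE) {
  dt <- fread(path, header = TRUE)
  setnames(dt, names(dt)[1:4], c("chrom", "start", "end", "label"))
  dt[, `:=`(chrom = as.character(chrom), start = as.integer(start),
            end = as.integer(end), label = as.character(label))]
  if (zero_based) dt[, start := start + 1L]
  dt[]
}

#' Remove SNPs inside regions, and their r-squared partners
#'
#' Drops every SNP whose position falls inside any of the regions
#' (inclusive bounds) and, conservatively, every SNP sharing an
#' `r^2 > threshold` edge with a dropped SNP.
#'
#' @param snps character vector of SNP ids.
#' @param ld an [ld_reference()].
#' @param regions `data.table(chrom, start, end, label)`
#'   (see [default_exclusion_regions()]).
#' @param positions data.frame with columns `snp_id, chrom, pos` covering
#'   `snps`.
#' @return character vector of retained ids (input order preserved).
#' @export
exclude_regions <- function(snps, ld, regions, positions) {
  ids <- as.character(snps)
  pos <- as.data.table(positions)[snp_id %chin% ids]
  if (nrow(pos) < length(unique(ids))) stop2("positions missing for some SNPs")
  regions <- as.data.table(regions)
  unknown_chr <- setdiff(regions$chrom, unique(pos$chrom))
  if (length(unknown_chr)) {
    warn2("region chromosome(s) absent from data: ",
          paste(unknown_chr, collapse = ", "))
  }
  inside <- rep(FALSE, nrow(pos))
  for (k in seq_len(nrow(regions))) {
    inside <- inside | (pos$chrom == regions$chrom[k] &
                          pos$pos >= regions$start[k] &
                          pos$pos <= regions$end[k])
  }
  removed <- pos$snp_id[inside]
  if (length(removed)) {
    removed <- union(removed, ld_partners(ld, removed))
  }
  ids[!ids %chin% removed]
}

#' All r-squared partners of a SNP set
#'
#' @param ld an [ld_reference()].
#' @param ids SNP ids.
#' @return character vector of partner ids (not including `ids` unless
#'   they partner each other).
#' @export
ld_partners <- function(ld, ids) {
  ids <- as.character(ids)
  if (is.null(ld$edges)) {
    bl <- ld$block_of[ids]
    bl <- bl[!is.na(bl)]
    if (!length(bl)) return(character(0))
    setdiff(names(ld$block_of)[ld$block_of %in% bl], ids)
  } else {
    e <- ld$edges
    unique(c(e[a %chin% ids, b], e[b %chin% ids, a]))
  }
}

#' Greedy LD clumping by an arbitrary ranking score
#'
#' Iterates SNPs by ascending score (lower = stronger) and keeps a SNP iff
#' it has no `r^2 > threshold` edge to any already-kept SNP. Ties are
#' broken by smaller `p`, then lexicographic id, so the result is
#' deterministic and independent of the input ordering.
#'
#' @param scores named numeric vector (names are SNP ids); finite.
#' @param ld an [ld_reference()].
#' @param p optional named numeric vector of p-values used as first
#'   tie-break.
#' @return character vector of index SNP ids in selection order.
#' @export
greedy_clump <- function(scores, ld, p = NULL) {
  if (any(!is.finite(scores))) stop2("scores must be finite")
  ids <- names(scores)
  if (is.null(ids)) stop2("scores must be named by SNP id")
  tie_p <- if (is.null(p)) rep(0, length(ids)) else unname(p[ids])
  ord <- order(scores, tie_p, ids)
  ids <- ids[ord]
  adj <- adjacency_within(ld, ids)
  kept <- character(0)
  in_kept <- new.env(hash = TRUE, parent = emptyenv())
  for (s in ids) {
    nb <- adj[[s]]
    free <- !length(nb) ||
      !any(vapply(nb, function(x) !is.null(in_kept[[x]]), logical(1)))
    if (free) {
      kept <- c(kept, s)
      assign(s, TRUE, envir = in_kept)
    }
  }
  kept
}

#' Write an LD reference to file
#'
#' Pairwise references are written as 3 columns (`id_a id_b r2`, with
#' `r2 = 1` recorded for stored suprathreshold edges when the original
#' values were not kept); block references as 2 columns (`id block`).
#'
#' @param ld an [ld_reference()].
#' @param path output path.
#' @param r2 optional numeric vector of r2 values matching `ld$edges` rows.
#' @return `path`, invisibly.
#' @export
write_ld <- function(ld, path, r2 = NULL) {
  if (is.null(ld$edges)) {
    fwrite(data.table(id = names(ld$block_of), block = unname(ld$block_of)),
           path, sep = "\t")
  } else {
    vals <- if (is.null(r2)) rep(1, nrow(ld$edges)) else r2
    out <- data.table(id_a = ld$edges$a, id_b = ld$edges$b, r2 = vals)
    fwrite(out, path, sep = "\t")
  }
  invisible(path)
}
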