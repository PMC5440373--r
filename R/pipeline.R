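#' Run the full cross-trait pleiotropy pipeline
#'
#' Executes harmonization, genomic-control correction, conditional Q-Q /
#' fold / TDR curves, conditional and conjunction FDR, locus definition
#' with optional gene annotation, Manhattan export, and (when a substudy
#' panel is supplied) stratified replication curves. All stage outputs
#' are written as tab-delimited tables plus a manifest recording the seed,
#' inflation factors and md5 checksum of every file, so a rerun with the
#' same inputs and seed reproduces the outputs bit-exactly.
#'
#' @param trait1,trait2 summary statistics: validated tables or file paths
#'   (read with [read_sumstats()]).
#' @param ld an [ld_reference()] or LD file path ([load_ld()]).
#' @param out_dir output directory (created).
#' @param regions exclusion regions table or file path; default
#'   [default_exclusion_regions()].
#' @param genes optional gene annotation table or file path.
#' @param panel optional [substudy_panel()] for the replication stage.
#' @param seed integer seed governing every random draw in the run.
#' @param fdr_threshold overall conjunction-FDR threshold (default 0.05).
#' @param thresholds secondary strata cutoffs (default
#'   `c(1, 0.1, 0.01, 0.001)`).
#' @param prune_iters random prunings averaged in the Q-Q stage
#'   (default 100).
#' @param n_partitions,bins replication-stage resampling controls
#'   (defaults 500 and 1000).
#' @param grid_size cfdr grid nodes per axis (default 201).
#' @return invisibly, a list with the in-memory stage results (`pairs`,
#'   `lambda1`, `lambda2`, `qq`, `fold`, `tdr`, `result`, `loci`,
#'   `manhattan`, `replication`, `manifest`).
#' @export
run_pipeline <- function(trait1, trait2, ld, out_dir,
                         regions = default_exclusion_regions(),
                         genes = NULL, panel = NULL, seed = 1,
                         fdr_threshold = 0.05,
                         thresholds = c(1, 0.1, 0.01, 0.001),
                         prune_iters = 100, n_partitions = 500,
                         bins = 1000, grid_size = 201) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(out_dir, "run.log")
  log_lines <- character(0)
  say <- function(...) {
    line <- paste0(format(Sys.time(), "%H:%M:%S "), ...)
    log_lines <<- c(log_lines, line)
    message(line)
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop2("pipeline stage '", name, "' failed: ", conditionMessage(e))
    })
  }

  if (is.character(trait1)) trait1 <- read_sumstats(trait1)
  if (is.character(trait2)) trait2 <- read_sumstats(trait2)
  if (is.character(ld)) ld <- load_ld(ld)
  if (is.character(regions)) regions <- read_regions(regions)
  if (!is.null(genes) && is.character(genes)) genes <- read_genes(genes)

  say("harmonize: ", nrow(trait1), " x ", nrow(trait2), " SNPs")
  pairs <- stage("harmonize", intersect_traits(trait1, trait2))
  say("shared SNPs: ", nrow(pairs))

  gc_res <- stage("genomic_control",
                  genomic_control_pairs(pairs, ld = ld, seed = seed))
  pairs <- gc_res$pairs
  say(sprintf("genomic control: lambda1 = %.4f, lambda2 = %.4f",
              gc_res$lambda1, gc_res$lambda2))

  say("enrichment curves")
  qq <- stage("qq", conditional_qq(pairs, ld = ld, thresholds = thresholds,
                                   seed = seed, prune_iters = prune_iters))
  fold <- stage("fold", fold_enrichment(pairs, thresholds = thresholds))
  tdr <- stage("tdr", conditional_tdr(pairs, thresholds = thresholds))

  say("conditional/conjunction FDR")
  g12 <- stage("cfdr", build_cfdr_grid(pairs, ld = ld, exclude = regions,
                                       seed = seed, direction = "1|2",
                                       grid_size = grid_size))
  g21 <- stage("cfdr", build_cfdr_grid(pairs, ld = ld, exclude = regions,
                                       seed = seed, direction = "2|1",
                                       grid_size = grid_size))
  result <- stage("conjunction",
                  conjunction_fdr(g12, g21, pairs,
                                  threshold = fdr_threshold))
  say("significant SNPs: ", sum(result$significant))

  loci <- stage("loci", define_loci(result, ld))
  if (!is.null(genes) && nrow(loci)) {
    loci <- stage("loci", annotate_nearest_gene(loci, genes))
  }
  say("loci: ", nrow(loci))
  manhattan <- stage("manhattan", manhattan_export(result, loci))

  replication <- NULL
  if (!is.null(panel)) {
    say("replication: ", ncol(panel$z), " substudies, ", n_partitions,
        " partitions")
    p2 <- stats::setNames(pairs$p2, pairs$snp_id)
    keep <- panel$snp_id %chin% names(p2)
    sub <- substudy_panel(panel$z[keep, , drop = FALSE], panel$n,
                          panel$labels)
    replication <- stage("replication",
                         replication_curves(sub, p2,
                                            thresholds = thresholds,
                                            n_partitions = n_partitions,
                                            bins = bins, seed = seed))
  }

  outputs <- list(pairs = pairs, qq = qq, fold = fold, tdr = tdr,
                  conjfdr = result, loci = loci, manhattan = manhattan)
  if (!is.null(replication)) outputs$replication <- replication
  files <- character(0)
  for (nm in names(outputs)) {
    f <- file.path(out_dir, paste0(nm, ".tsv"))
    fwrite(outputs[[nm]], f, sep = "\t", na = "NA", quote = FALSE)
    files <- c(files, f)
  }
  writeLines(log_lines, log_path)

  manifest <- data.table(file = basename(files),
                         md5 = unname(tools::md5sum(files)))
  manifest_meta <- data.table(
    file = c(".seed", ".lambda1", ".lambda2", ".fdr_threshold",
             ".package_version"),
    md5 = as.character(c(seed, signif(gc_res$lambda1, 10),
                         signif(gc_res$lambda2, 10), fdr_threshold,
                         as.character(utils::packageVersion("condconj")))))
  fwrite(rbind(manifest, manifest_meta),
         file.path(out_dir, "manifest.tsv"), sep = "\t")

  invisible(list(pairs = pairs, lambda1 = gc_res$lambda1,
                 lambda2 = gc_res$lambda2, qq = qq, fold = fold,
                 tdr = tdr, result = result, loci = loci,
                 manhattan = manhattan, replication = replication,
                 manifest = manifest))
}
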