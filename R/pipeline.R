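#' Pipeline configuration
#'
#' Validated configuration for [run_pipeline()].  Exactly one input mode
#' must be set: FASTQ files plus a read taxonomy TSV (QC mode), or a
#' pre-built count TSV plus metadata TSV (table mode).
#'
#' @param fastq named character vector of FASTQ paths (names = sample
#'   ids), or NULL.
#' @param taxonomy_tsv read-id to taxonomy TSV path (QC mode).
#' @param counts_tsv,metadata_tsv count-table input mode paths.
#' @param groups named character vector sample id -> group label; required
#'   in QC mode, read from `metadata_tsv` in table mode.
#' @param comparisons list of length-2 character vectors of group labels
#'   to compare pairwise; default: all pairs of observed groups.
#' @param qc a [qc_params()].
#' @param min_prop prevalence-filter threshold (default 0.5).
#' @param pca_k number of principal components (default min(n-1, p),
#'   capped at 5).
#' @param rf_trees random-forest size (default 10000).
#' @param out_dir output directory.
#' @param seed integer seed for the random forest.
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(fastq = NULL, taxonomy_tsv = NULL,
                            counts_tsv = NULL, metadata_tsv = NULL,
                            groups = NULL, comparisons = NULL,
                            qc = qc_params(), min_prop = 0.5,
                            pca_k = NULL, rf_trees = 10000,
                            out_dir = "micropart_out", seed = 1) {
  fastq_mode <- !is.null(fastq)
  table_mode <- !is.null(counts_tsv)
  if (fastq_mode == table_mode)
    stop("set exactly one input mode: fastq+taxonomy_tsv or counts_tsv+metadata_tsv")
  if (fastq_mode && (is.null(taxonomy_tsv) || is.null(groups)))
    stop("QC mode needs taxonomy_tsv and groups")
  if (table_mode && is.null(metadata_tsv))
    stop("table mode needs metadata_tsv")
  structure(list(fastq = fastq, taxonomy_tsv = taxonomy_tsv,
                 counts_tsv = counts_tsv, metadata_tsv = metadata_tsv,
                 groups = groups, comparisons = comparisons, qc = qc,
                 min_prop = min_prop, pca_k = pca_k, rf_trees = rf_trees,
                 out_dir = out_dir, seed = seed),
            class = "pipeline_config")
}

write_tsv6 <- function(df, path) {
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], signif, digits = 6)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  path
}

#' Run the full analysis pipeline
#'
#' Executes the stages in order -- QC (FASTQ mode only), count table,
#' group summaries, per-pair two-part comparisons, Kruskal-Wallis screen
#' across all groups (when > 2 groups), effect views, CLR-PCA, and
#' random-forest ranking -- writing every stage's tables as TSV under
#' `out_dir` plus a JSON manifest with input md5 hashes, parameters and
#' seed.  All statistical outputs are a pure function of (inputs, config,
#' seed): re-running the same configuration reproduces them byte for
#' byte.
#'
#' @param config a [pipeline_config()].
#' @return invisibly, the manifest list (also written to
#'   `out_dir/manifest.json`).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  outputs <- character(0)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  inputs <- c(config$fastq, config$taxonomy_tsv, config$counts_tsv,
              config$metadata_tsv)
  input_hashes <- as.list(tools::md5sum(inputs))

  # validate requested comparisons against the metadata before any compute
  glabels <- if (!is.null(config$groups)) unique(unname(config$groups))
             else unique(utils::read.delim(config$metadata_tsv,
                                           stringsAsFactors = FALSE)[[2]])
  comparisons <- config$comparisons
  if (is.null(comparisons))
    comparisons <- utils::combn(glabels, 2, simplify = FALSE)
  for (cmp in comparisons) {
    bad <- setdiff(cmp, glabels)
    if (length(bad))
      stop("comparison group not present in metadata: ",
           paste(bad, collapse = ", "))
  }

  if (!is.null(config$fastq)) {
    qc <- stage("qc", run_qc(config$fastq, config$taxonomy_tsv,
                             config$groups, config$qc))
    tab <- qc$table
    outputs <- c(outputs, write_tsv6(qc$report,
                                     file.path(config$out_dir, "qc_report.tsv")))
  } else {
    tab <- stage("table", read_taxon_table(config$counts_tsv,
                                           config$metadata_tsv))
  }

  ct_path <- file.path(config$out_dir, "count_table.tsv")
  md_path <- file.path(config$out_dir, "metadata.tsv")
  stage("table", write_taxon_table(tab, ct_path, md_path))
  outputs <- c(outputs, ct_path, md_path)

  outputs <- c(outputs, stage("summaries",
    write_tsv6(group_summary(tab),
               file.path(config$out_dir, "group_summary.tsv"))))

  for (cmp in comparisons) {
    tag <- paste0(gsub("[^A-Za-z0-9_.-]", "_", cmp[1]), "_vs_",
                  gsub("[^A-Za-z0-9_.-]", "_", cmp[2]))
    fit <- stage(paste0("two_part:", tag),
                 two_part(tab, cmp[1], cmp[2], config$min_prop))
    outputs <- c(outputs,
      write_tsv6(summary(fit),
                 file.path(config$out_dir, paste0("two_part_", tag, ".tsv"))),
      write_tsv6(manhattan_points(fit),
                 file.path(config$out_dir, paste0("manhattan_", tag, ".tsv"))),
      write_tsv6(delta_effects(fit),
                 file.path(config$out_dir, paste0("effects_", tag, ".tsv"))))
    png_path <- file.path(config$out_dir, paste0("manhattan_", tag, ".png"))
    grDevices::png(png_path, 900, 500)
    plot(fit, type = "manhattan")
    grDevices::dev.off()
    png_path2 <- file.path(config$out_dir, paste0("effects_", tag, ".png"))
    grDevices::png(png_path2, 700, 700)
    plot(fit, type = "effects")
    grDevices::dev.off()
    outputs <- c(outputs, png_path, png_path2)
  }

  if (length(glabels) > 2) {
    outputs <- c(outputs, stage("kruskal_wallis",
      write_tsv6(kw_screen(tab),
                 file.path(config$out_dir, "kruskal_wallis.tsv"))))
  }

  clr <- stage("ordination", clr_transform(tab))
  kmax <- min(nrow(tab) - 1, ncol(tab))
  k <- if (is.null(config$pca_k)) min(kmax, 5) else config$pca_k
  pca <- stage("ordination", clr_pca(clr, k = k))
  clr_df <- data.frame(sample_id = rownames(clr), clr, check.names = FALSE)
  outputs <- c(outputs,
    write_tsv6(clr_df, file.path(config$out_dir, "clr.tsv")),
    write_tsv6(data.frame(sample_id = rownames(pca$scores), pca$scores,
                          check.names = FALSE),
               file.path(config$out_dir, "pca_scores.tsv")),
    write_tsv6(data.frame(taxon = rownames(pca$loadings), pca$loadings,
                          check.names = FALSE),
               file.path(config$out_dir, "pca_loadings.tsv")),
    write_tsv6(data.frame(component = paste0("PC", seq_len(k)),
                          explained_variance_ratio =
                            pca$explained_variance_ratio),
               file.path(config$out_dir, "pca_variance.tsv")))
  png_path <- file.path(config$out_dir, "pca_biplot.png")
  grDevices::png(png_path, 700, 700)
  plot(pca)
  grDevices::dev.off()
  outputs <- c(outputs, png_path)

  rf <- stage("random_forest",
              rf_importance(tab, which_groups = comparisons[[1]],
                            n_trees = config$rf_trees, seed = config$seed))
  outputs <- c(outputs,
    write_tsv6(rf$ranking, file.path(config$out_dir, "rf_ranking.tsv")))

  manifest <- list(
    inputs = input_hashes,
    parameters = list(min_prop = config$min_prop,
                      qc = unclass(config$qc),
                      pca_k = k, rf_trees = config$rf_trees,
                      seed = config$seed,
                      comparisons = comparisons),
    package_version = as.character(utils::packageVersion("micropart")),
    outputs = basename(outputs))
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}
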