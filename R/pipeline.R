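#' Run configuration for a full analysis
#'
#' Exactly one of `sim` (a [sim_config()]) or the three input paths must be
#' given. All analysis thresholds live here and nowhere else.
#'
#' @param counts_path,lengths_path,metadata_path Input TSVs (see
#'   [read_experiment()]); `lengths_path` may be a GFF3 file (extension
#'   `.gff`/`.gff3`).
#' @param phenotypes_path Optional phenotype CSV.
#' @param sim Optional [sim_config()] replacing the expression inputs.
#' @param expressed_threshold Expressed-gene RPKM cutoff, default 1.0.
#' @param lfc_threshold DEG |log2FC| cutoff, default 1.5.
#' @param fdr_threshold DEG adjusted-p cutoff, default 0.05.
#' @param margin Transgressive margin, default 0.2.
#' @param pseudocount Fold-change pseudocount, default 1.
#' @param seed Integer seed (used by the simulator).
#' @param out_dir Output directory, or NULL to skip writing files.
#' @return Object of class `run_config`.
#' @export
run_config <- function(counts_path = NULL, lengths_path = NULL,
                       metadata_path = NULL, phenotypes_path = NULL,
                       sim = NULL, expressed_threshold = 1.0,
                       lfc_threshold = 1.5, fdr_threshold = 0.05,
                       margin = 0.2, pseudocount = 1, seed = 1,
                       out_dir = NULL) {
  have_paths <- !is.null(counts_path)
  if (have_paths == !is.null(sim))
    stop("provide exactly one of input paths or a `sim` config")
  if (have_paths && (is.null(lengths_path) || is.null(metadata_path)))
    stop("counts, lengths, and metadata paths are all required")
  for (v in c(expressed_threshold, lfc_threshold, fdr_threshold, margin,
              pseudocount))
    if (v < 0) stop("thresholds must be non-negative")
  structure(list(
    counts_path = counts_path, lengths_path = lengths_path,
    metadata_path = metadata_path, phenotypes_path = phenotypes_path,
    sim = sim, expressed_threshold = expressed_threshold,
    lfc_threshold = lfc_threshold, fdr_threshold = fdr_threshold,
    margin = margin, pseudocount = pseudocount, seed = as.integer(seed),
    out_dir = out_dir
  ), class = "run_config")
}

#' Run the full inheritance-mode pipeline
#'
#' Stages: load or simulate the count matrix; RPKM normalization; type-mean
#' aggregation; expressed-gene filter; the six pairwise exact-test DE
#' contrasts on the expressed universe; transgressive classification and
#' class summary; hybrid overlap; phenotype statistics when a phenotype table
#' is supplied. When `out_dir` is set, every table is written and a manifest
#' (config echo, file checksums, seed, package version) accompanies them;
#' identical config and inputs yield identical outputs.
#'
#' @param config A [run_config()].
#' @return List of class `pipeline_result` with elements `cm`, `rpkm`,
#'   `type_means`, `expressed`, `de` (named list of six data frames),
#'   `calls`, `summary`, `overlap`, `pheno` (or NULL), `truth` (simulated
#'   runs only), and `manifest`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  log_stage <- function(...) message(sprintf(...))

  truth <- NULL
  library_sizes <- NULL
  if (!is.null(config$sim)) {
    sim <- generate_counts(config$sim)
    cm <- sim$cm
    truth <- sim$truth
    library_sizes <- sim$library_sizes
    log_stage("simulated %d genes x %d samples", nrow(cm$counts), ncol(cm$counts))
  } else {
    lengths_is_gff <- grepl("\\.gff3?$", config$lengths_path, ignore.case = TRUE)
    if (lengths_is_gff) {
      counts <- read_counts(config$counts_path)
      lengths <- gff_gene_lengths(config$lengths_path)
      type_map <- read_metadata(config$metadata_path)
      shared <- intersect(rownames(counts), names(lengths))
      if (!length(shared)) stop("no genes shared between counts and GFF3")
      cm <- count_matrix(counts[shared, , drop = FALSE], lengths[shared], type_map)
    } else {
      cm <- read_experiment(config$counts_path, config$lengths_path,
                            config$metadata_path)
    }
    log_stage("loaded %d genes x %d samples", nrow(cm$counts), ncol(cm$counts))
  }
  missing_types <- setdiff(GENETIC_TYPES, unique(cm$type_map))
  if (length(missing_types))
    stop("genetic type(s) missing from the metadata: ",
         paste(missing_types, collapse = ", "))

  rpkm <- compute_rpkm(cm, library_sizes)
  type_means <- aggregate_by_type(rpkm, cm$type_map)
  expressed <- filter_expressed(type_means, config$expressed_threshold)
  if (!length(expressed)) stop("no genes pass the expressed filter")
  log_stage("expressed universe: %d of %d genes (type-mean RPKM > %g)",
            length(expressed), nrow(rpkm), config$expressed_threshold)

  de <- list()
  for (i in seq_len(nrow(TYPE_PAIRS))) {
    a <- TYPE_PAIRS[i, 1]; b <- TYPE_PAIRS[i, 2]
    tab <- de_pairwise(cm, a, b, genes = expressed,
                       pseudocount = config$pseudocount,
                       lfc_threshold = config$lfc_threshold,
                       fdr_threshold = config$fdr_threshold,
                       library_sizes = library_sizes)
    de[[sprintf("%s_vs_%s", a, b)]] <- tab
    log_stage("DE %s vs %s: %d DEGs of %d tested (phi = %.4f)",
              a, b, sum(tab$is_deg), nrow(tab), attr(tab, "phi"))
  }

  calls <- classify_all(type_means, expressed, config$margin)
  summary <- summarize_classes(calls, length(expressed))
  overlap <- tryCatch(hybrid_overlap(calls), error = function(e) NULL)
  log_stage("transgressive: %d of %d expressed genes (%.1f%%)",
            summary$n_transgressive, summary$universe_size,
            summary$pct_transgressive)

  pheno <- NULL
  if (!is.null(config$phenotypes_path)) {
    pheno_tab <- read_phenotypes(config$phenotypes_path)
    pheno <- pheno_statistics(pheno_tab)
    log_stage("phenotypes: %d traits x %d individuals",
              nrow(pheno), nrow(pheno_tab))
  }

  result <- structure(list(
    cm = cm, rpkm = rpkm, type_means = type_means, expressed = expressed,
    de = de, calls = calls, summary = summary, overlap = overlap,
    pheno = pheno, truth = truth, manifest = NULL
  ), class = "pipeline_result")

  if (!is.null(config$out_dir)) {
    result$manifest <- write_results(result, config)
  }
  result
}

# write all tables plus a manifest with checksums; returns the manifest
write_results <- function(result, config) {
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  out <- function(name) file.path(config$out_dir, name)
  paths <- c(
    write_table(result$rpkm, out("rpkm.tsv")),
    write_table(result$type_means, out("type_means.tsv")),
    write_table(data.frame(gene_id = result$expressed), out("expressed.tsv")),
    write_table(result$calls, out("transgressive_calls.tsv"))
  )
  for (nm in names(result$de))
    paths <- c(paths, write_table(result$de[[nm]], out(sprintf("de_%s.tsv", nm))))
  if (!is.null(result$truth))
    paths <- c(paths, write_table(result$truth, out("truth.tsv")))
  if (!is.null(result$pheno))
    paths <- c(paths, write_table(result$pheno, out("phenotype_stats.tsv")))
  s <- result$summary
  jsonlite::write_json(
    list(counts = as.list(s$counts), n_transgressive = s$n_transgressive,
         universe_size = s$universe_size,
         pct_transgressive = s$pct_transgressive,
         pct_concordant_down = s$pct_concordant_down,
         pct_discordant_I = s$pct_discordant_I,
         pct_discordant_II = s$pct_discordant_II,
         overlap = result$overlap),
    out("class_summary.json"), auto_unbox = TRUE, digits = NA
  )
  paths <- c(paths, out("class_summary.json"))
  cfg <- unclass(config)
  cfg$sim <- if (!is.null(config$sim)) unclass(config$sim) else NULL
  manifest <- list(
    package_version = as.character(utils::packageVersion("hybridexpr")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    seed = config$seed,
    config = cfg,
    checksums = as.list(tools::md5sum(paths))
  )
  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  manifest
}
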