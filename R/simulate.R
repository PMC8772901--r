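#' Simulation configuration for planted inheritance modes
#'
#' Defines a synthetic reciprocal-cross RNA-seq experiment. Each gene is
#' assigned an inheritance mode that fixes its expected expression (RPKM
#' scale) in the four genetic types:
#'
#' * `null` -- all four types at the gene's baseline.
#' * `additive` -- parents separated by `effect_size` (geometrically around
#'   the baseline), both hybrids at the mid-parent value.
#' * `dominant_PC` / `dominant_PB` -- parents separated as above, both
#'   hybrids at the named parent's level.
#' * `concordant_up` / `concordant_down` -- both hybrids `effect_size`-fold
#'   beyond the parental envelope (above the larger parent / below the
#'   smaller).
#' * `discordant_I` -- F1BC transgressive-up, F1CB at the mid-parent value
#'   (the transgressive hybrid is fixed to F1BC and recorded in the truth
#'   table).
#' * `discordant_II` -- F1BC transgressive-up, F1CB transgressive-down.
#'
#' Per-gene baselines are drawn log-normally around `baseline_mean` so the
#' matrix spans a realistic dynamic range. Defaults emulate the reciprocal
#' channel x blue catfish liver study design: 2 replicates per type, ~13k
#' genes with a class mix matching the reported composition, 5M reads per
#' sample.
#'
#' @param n_genes_per_mode Named integer vector of gene counts per mode.
#' @param baseline_mean Median baseline expression, RPKM scale; default 30.
#' @param baseline_sdlog Log-normal sd of gene baselines; default 0.5.
#' @param dispersion NB dispersion phi (variance = mu + phi mu^2); phi = 0 is
#'   exact Poisson sampling. Default 0.1, a typical bulk-RNA-seq value.
#' @param effect_size Fold separation (> 1) of the parents and, for
#'   transgressive modes, of hybrids beyond the parental envelope; default 2.
#' @param replicates_per_type Replicates per genetic type; default 2.
#' @param library_sizes Library size per sample, recycled to the 4 x
#'   replicates samples; default 5e6.
#' @param gene_length_range Range (bp) of uniform gene lengths; default
#'   c(500, 5000).
#' @param seed Integer seed.
#' @return Object of class `sim_config`.
#' @export
sim_config <- function(n_genes_per_mode = c(null = 10000, additive = 800,
                                            dominant_PC = 400, dominant_PB = 400,
                                            concordant_up = 60,
                                            concordant_down = 925,
                                            discordant_I = 106,
                                            discordant_II = 49),
                       baseline_mean = 30, baseline_sdlog = 0.5,
                       dispersion = 0.1, effect_size = 2,
                       replicates_per_type = 2, library_sizes = 5e6,
                       gene_length_range = c(500, 5000), seed = 1) {
  modes <- c("null", "additive", "dominant_PC", "dominant_PB",
             "concordant_up", "concordant_down", "discordant_I", "discordant_II")
  if (length(n_genes_per_mode) && is.null(names(n_genes_per_mode)))
    stop("`n_genes_per_mode` must be named by mode")
  bad <- setdiff(names(n_genes_per_mode), modes)
  if (length(bad)) stop("unknown mode(s): ", paste(bad, collapse = ", "))
  if (!length(n_genes_per_mode) || sum(n_genes_per_mode) <= 0)
    stop("`n_genes_per_mode` must request at least one gene")
  if (any(n_genes_per_mode < 0)) stop("gene counts must be non-negative")
  if (effect_size <= 1) stop("`effect_size` must exceed 1")
  if (dispersion < 0) stop("`dispersion` must be >= 0")
  if (baseline_mean <= 0) stop("`baseline_mean` must be positive")
  if (replicates_per_type < 1) stop("`replicates_per_type` must be >= 1")
  n_samples <- 4L * replicates_per_type
  library_sizes <- rep_len(library_sizes, n_samples)
  if (any(library_sizes <= 0)) stop("library sizes must be positive")
  if (length(gene_length_range) != 2 || any(gene_length_range <= 0) ||
      gene_length_range[1] > gene_length_range[2])
    stop("`gene_length_range` must be an increasing pair of positive integers")
  structure(list(
    n_genes_per_mode = n_genes_per_mode,
    baseline_mean = baseline_mean, baseline_sdlog = baseline_sdlog,
    dispersion = dispersion, effect_size = effect_size,
    replicates_per_type = as.integer(replicates_per_type),
    library_sizes = library_sizes,
    gene_length_range = as.integer(gene_length_range),
    seed = as.integer(seed)
  ), class = "sim_config")
}

# expected per-type expression for one mode given baseline b and effect e
mode_expectations <- function(mode, b, e) {
  # parents geometrically separated around b for modes with a parental
  # difference; transgressive modes use a milder e^(1/4) separation so the
  # envelope is exercised without conflating parent DE with transgression
  switch(mode,
    null = c(PC = b, PB = b, F1BC = b, F1CB = b),
    additive = {
      pc <- b * sqrt(e); pb <- b / sqrt(e); mp <- (pc + pb) / 2
      c(PC = pc, PB = pb, F1BC = mp, F1CB = mp)
    },
    dominant_PC = {
      pc <- b * sqrt(e); pb <- b / sqrt(e)
      c(PC = pc, PB = pb, F1BC = pc, F1CB = pc)
    },
    dominant_PB = {
      pc <- b * sqrt(e); pb <- b / sqrt(e)
      c(PC = pc, PB = pb, F1BC = pb, F1CB = pb)
    },
    concordant_up = {
      pc <- b * e^0.25; pb <- b / e^0.25
      c(PC = pc, PB = pb, F1BC = e * pc, F1CB = e * pc)
    },
    concordant_down = {
      pc <- b * e^0.25; pb <- b / e^0.25
      c(PC = pc, PB = pb, F1BC = pb / e, F1CB = pb / e)
    },
    discordant_I = {
      pc <- b * e^0.25; pb <- b / e^0.25
      c(PC = pc, PB = pb, F1BC = e * pc, F1CB = (pc + pb) / 2)
    },
    discordant_II = {
      pc <- b * e^0.25; pb <- b / e^0.25
      c(PC = pc, PB = pb, F1BC = e * pc, F1CB = pb / e)
    },
    stop("unknown mode: ", mode)
  )
}

#' Generate a count matrix with planted inheritance modes
#'
#' Expected counts are `expression * (length_bp / 1000) * (library_size /
#' 1e6)`, so RPKM normalization inverts the construction in expectation and
#' the generator is self-verifying. Counts are drawn NB(mu, phi) (Poisson
#' when phi = 0).
#'
#' @param config A [sim_config()].
#' @return List with `cm` (a [count_matrix()]), `truth` (data frame:
#'   `gene_id`, `mode`, and the planted expected RPKM `exp_PC`, `exp_PB`,
#'   `exp_F1BC`, `exp_F1CB`), and `library_sizes` (named, per sample).
#' @export
generate_counts <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  modes <- rep(names(config$n_genes_per_mode), config$n_genes_per_mode)
  n_genes <- length(modes)
  gene_ids <- sprintf("gene%05d", seq_len(n_genes))
  reps <- config$replicates_per_type
  sample_ids <- as.vector(vapply(GENETIC_TYPES, function(ty)
    sprintf("%s_rep%d", ty, seq_len(reps)), character(reps)))
  type_map <- stats::setNames(rep(GENETIC_TYPES, each = reps), sample_ids)
  library_sizes <- stats::setNames(config$library_sizes, sample_ids)

  baselines <- stats::rlnorm(n_genes, meanlog = log(config$baseline_mean),
                             sdlog = config$baseline_sdlog)
  lengths <- stats::setNames(
    sample(config$gene_length_range[1]:config$gene_length_range[2],
           n_genes, replace = TRUE),
    gene_ids
  )
  expect <- t(vapply(seq_len(n_genes), function(i)
    mode_expectations(modes[i], baselines[i], config$effect_size),
    numeric(4)))
  colnames(expect) <- GENETIC_TYPES

  mu <- expect[, type_map[sample_ids], drop = FALSE] *
    (as.numeric(lengths) / 1000) %o% (library_sizes / 1e6)
  counts <- matrix(0L, n_genes, length(sample_ids),
                   dimnames = list(gene_ids, sample_ids))
  if (config$dispersion == 0) {
    counts[] <- stats::rpois(length(mu), lambda = mu)
  } else {
    counts[] <- stats::rnbinom(length(mu), size = 1 / config$dispersion,
                               mu = mu)
  }
  truth <- data.frame(
    gene_id = gene_ids, mode = modes,
    exp_PC = expect[, "PC"], exp_PB = expect[, "PB"],
    exp_F1BC = expect[, "F1BC"], exp_F1CB = expect[, "F1CB"],
    row.names = NULL, stringsAsFactors = FALSE
  )
  list(
    cm = count_matrix(counts, lengths, type_map),
    truth = truth,
    library_sizes = library_sizes
  )
}

#' Generate a phenotype table with known group structure
#'
#' Draws each individual's trait values from a normal distribution truncated
#' at zero (morphometric and plasma measurements are physically
#' non-negative), with per-type means and standard deviations supplied as
#' trait x type matrices. `sd = 0` reproduces the group means exactly.
#'
#' @param group_means Numeric trait x type matrix (columns `PC`, `PB`,
#'   `F1BC`, `F1CB`; rownames are trait names).
#' @param group_sds Same shape as `group_means`, all >= 0.
#' @param n_per_type Individuals per genetic type; default 6.
#' @param seed Integer seed.
#' @return Data frame: `individual_id`, `genetic_type`, one column per trait.
#' @export
generate_phenotypes <- function(group_means, group_sds, n_per_type = 6,
                                seed = 1) {
  group_means <- as.matrix(group_means); group_sds <- as.matrix(group_sds)
  if (!identical(dim(group_means), dim(group_sds)))
    stop("`group_means` and `group_sds` must have the same shape")
  if (any(group_sds < 0)) stop("standard deviations must be >= 0")
  if (n_per_type < 1) stop("`n_per_type` must be >= 1")
  if (!all(GENETIC_TYPES %in% colnames(group_means)))
    stop("`group_means` must have columns PC, PB, F1BC, F1CB")
  if (is.null(rownames(group_means)))
    stop("`group_means` must have trait names as rownames")
  set.seed(seed)
  rtnorm <- function(n, mean, sd) {
    if (sd == 0) return(rep(mean, n))
    out <- stats::rnorm(n, mean, sd)
    while (any(out < 0)) {           # rejection sampling at the zero bound
      neg <- out < 0
      out[neg] <- stats::rnorm(sum(neg), mean, sd)
    }
    out
  }
  traits <- rownames(group_means)
  rows <- lapply(GENETIC_TYPES, function(ty) {
    vals <- vapply(traits, function(tr)
      rtnorm(n_per_type, group_means[tr, ty], group_sds[tr, ty]),
      numeric(n_per_type))
    vals <- matrix(vals, nrow = n_per_type,
                   dimnames = list(NULL, traits))
    data.frame(
      individual_id = sprintf("%s_%02d", ty, seq_len(n_per_type)),
      genetic_type = ty, vals,
      row.names = NULL, stringsAsFactors = FALSE, check.names = FALSE
    )
  })
  do.call(rbind, rows)
}
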