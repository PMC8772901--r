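#' Mid-parent heterosis for one trait
#'
#' Heterosis is the average of the two reciprocal F1 means minus the
#' mid-parent value, expressed as a percentage of the mid-parent value:
#' `100 * (f1_mean - midparent) / midparent` with
#' `midparent = (PC + PB) / 2` and `f1_mean = (F1BC + F1CB) / 2`.
#'
#' @param means Named numeric vector with elements `PC`, `PB`, `F1BC`, `F1CB`
#'   (per-type trait means).
#' @return List with `midparent`, `f1_mean`, `heterosis_pct`.
#' @export
heterosis <- function(means) {
  means <- check_type_means(means)
  midparent <- (means[["PC"]] + means[["PB"]]) / 2
  if (midparent == 0) stop("mid-parent value is zero: heterosis undefined")
  f1_mean <- (means[["F1BC"]] + means[["F1CB"]]) / 2
  list(
    midparent = midparent,
    f1_mean = f1_mean,
    heterosis_pct = 100 * (f1_mean - midparent) / midparent
  )
}

#' Heterobeltiosis: hybrid advantage over the best parent
#'
#' Percentage difference of the reciprocal-F1 average from the
#' best-performing parent. "Best" defaults to the larger parental mean
#' (growth-type traits); set `larger_is_better = FALSE` for traits where
#' lower values are superior.
#'
#' @param means Named numeric vector with elements `PC`, `PB`, `F1BC`, `F1CB`.
#' @param larger_is_better Direction of superiority, default TRUE.
#' @return List with `best_parent` (label), `best_mean`,
#'   `heterobeltiosis_pct`, and `exceeds_best` (strictly positive
#'   heterobeltiosis in the chosen direction).
#' @export
heterobeltiosis <- function(means, larger_is_better = TRUE) {
  means <- check_type_means(means)
  parents <- means[c("PC", "PB")]
  best_parent <- names(parents)[if (larger_is_better) which.max(parents)
                                else which.min(parents)]
  best <- parents[[best_parent]]
  if (best == 0) stop("best parent mean is zero: heterobeltiosis undefined")
  f1_mean <- (means[["F1BC"]] + means[["F1CB"]]) / 2
  pct <- 100 * (f1_mean - best) / best
  list(
    best_parent = best_parent,
    best_mean = best,
    heterobeltiosis_pct = pct,
    exceeds_best = if (larger_is_better) pct > 0 else pct < 0
  )
}

check_type_means <- function(means) {
  if (is.null(names(means)) || !all(GENETIC_TYPES %in% names(means)))
    stop("`means` must be named with PC, PB, F1BC, F1CB")
  means[GENETIC_TYPES]
}

#' Standardize shape traits by total length
#'
#' Divides each trait by the per-individual value of the denominator trait
#' (total length by default), removing overall size so that shape and
#' condition can be compared across genetic types.
#'
#' @param pheno Data frame with columns `individual_id`, `genetic_type`, and
#'   one numeric column per trait.
#' @param traits Traits to standardize; default all numeric trait columns
#'   except the denominator.
#' @param denominator_trait Column used as denominator, default
#'   `"total_length"`.
#' @return The phenotype table with the selected traits replaced by
#'   trait / denominator.
#' @export
standardize_by_length <- function(pheno, traits = NULL,
                                  denominator_trait = "total_length") {
  if (!denominator_trait %in% names(pheno))
    stop("denominator trait not found: ", denominator_trait)
  denom <- pheno[[denominator_trait]]
  if (any(denom <= 0)) stop("denominator trait must be positive for every individual")
  if (is.null(traits)) {
    traits <- setdiff(names(pheno)[vapply(pheno, is.numeric, logical(1))],
                      denominator_trait)
  }
  for (tr in traits) pheno[[tr]] <- pheno[[tr]] / denom
  pheno
}

#' Exact Mann-Whitney U test by complete enumeration
#'
#' U is computed from mid-rank sums (average ranks on ties). When the number
#' of group assignments `choose(n1 + n2, n1)` does not exceed `exact_cap`,
#' the p-value is exact: the permutation distribution of U is enumerated over
#' all assignments of the pooled values, tied statistics contribute their
#' full probability to the tail, and the two-sided p is twice the smaller
#' tail, capped at 1. Beyond the cap a normal approximation with tie
#' correction is used and labelled as such.
#'
#' @param x,y Numeric vectors, each non-empty.
#' @param alternative `"two.sided"` (default), `"less"`, or `"greater"`
#'   (direction refers to `x` relative to `y`).
#' @param exact_cap Maximum number of assignments for exact enumeration;
#'   default 200000 (n = 6 vs 6 needs 924).
#' @return List with `U` (statistic for `x`), `p` in (0, 1], and `method`
#'   (`"exact"` or `"normal-approx"`).
#' @export
mann_whitney_exact <- function(x, y, alternative = c("two.sided", "less", "greater"),
                               exact_cap = 200000) {
  alternative <- match.arg(alternative)
  n1 <- length(x); n2 <- length(y)
  if (n1 < 1 || n2 < 1) stop("both groups must be non-empty")
  if (anyNA(x) || anyNA(y)) stop("missing values are not supported")
  pooled <- c(x, y)
  r <- rank(pooled)           # mid-ranks
  u_of <- function(idx) sum(r[idx]) - n1 * (n1 + 1) / 2
  U <- u_of(seq_len(n1))

  n_assign <- choose(n1 + n2, n1)
  if (n_assign <= exact_cap) {
    idx <- utils::combn(n1 + n2, n1)
    u_all <- colSums(matrix(r[idx], nrow = n1)) - n1 * (n1 + 1) / 2
    eps <- 1e-9
    p_le <- mean(u_all <= U + eps)
    p_ge <- mean(u_all >= U - eps)
    p <- switch(alternative,
                two.sided = min(1, 2 * min(p_le, p_ge)),
                less = p_le,
                greater = p_ge)
    method <- "exact"
  } else {
    mu <- n1 * n2 / 2
    ties <- table(r)
    n <- n1 + n2
    tie_term <- sum(ties^3 - ties) / (n * (n - 1))
    sigma <- sqrt(n1 * n2 / 12 * (n + 1 - tie_term))
    z_le <- (U + 0.5 - mu) / sigma
    z_ge <- (U - 0.5 - mu) / sigma
    p_le <- stats::pnorm(z_le)
    p_ge <- stats::pnorm(z_ge, lower.tail = FALSE)
    p <- switch(alternative,
                two.sided = min(1, 2 * min(p_le, p_ge)),
                less = p_le,
                greater = p_ge)
    method <- "normal-approx"
  }
  list(U = U, p = p, method = method)
}

#' Per-trait phenotype statistics across the four genetic types
#'
#' For every trait: per-type means, mid-parent heterosis, heterobeltiosis,
#' and exact Mann-Whitney p-values for all six pairwise type comparisons,
#' optionally BH-adjusted across the six pairs within each trait.
#'
#' @param pheno Phenotype data frame (`individual_id`, `genetic_type`, trait
#'   columns).
#' @param traits Traits to analyse; default all numeric columns.
#' @param larger_is_better Single logical or named logical per trait.
#' @param adjust Add BH-adjusted columns across the six pairwise tests within
#'   each trait, default TRUE.
#' @return Data frame, one row per trait: type means, `midparent`, `f1_mean`,
#'   `heterosis_pct`, `best_parent`, `heterobeltiosis_pct`, `exceeds_best`,
#'   and `p_<A>_vs_<B>` (plus `padj_` columns when `adjust`).
#' @export
pheno_statistics <- function(pheno, traits = NULL, larger_is_better = TRUE,
                             adjust = TRUE) {
  stopifnot(all(c("individual_id", "genetic_type") %in% names(pheno)))
  bad <- setdiff(unique(pheno$genetic_type), GENETIC_TYPES)
  if (length(bad)) stop("unknown genetic type token(s): ", paste(bad, collapse = ", "))
  if (is.null(traits))
    traits <- setdiff(names(pheno)[vapply(pheno, is.numeric, logical(1))],
                      c("individual_id"))
  if (length(larger_is_better) == 1)
    larger_is_better <- stats::setNames(rep(larger_is_better, length(traits)), traits)
  rows <- lapply(traits, function(tr) {
    v <- pheno[[tr]]
    means <- vapply(GENETIC_TYPES, function(ty) {
      mean(v[pheno$genetic_type == ty])
    }, numeric(1))
    het <- heterosis(means)
    hb <- heterobeltiosis(means, larger_is_better[[tr]])
    row <- c(as.list(means),
             midparent = het$midparent, f1_mean = het$f1_mean,
             heterosis_pct = het$heterosis_pct,
             best_parent = hb$best_parent,
             heterobeltiosis_pct = hb$heterobeltiosis_pct,
             exceeds_best = hb$exceeds_best)
    pvals <- apply(TYPE_PAIRS, 1L, function(pair) {
      mann_whitney_exact(v[pheno$genetic_type == pair[1]],
                         v[pheno$genetic_type == pair[2]])$p
    })
    names(pvals) <- sprintf("p_%s_vs_%s", TYPE_PAIRS[, 1], TYPE_PAIRS[, 2])
    row <- c(row, as.list(pvals))
    if (adjust) {
      padj <- bh_adjust(pvals)
      names(padj) <- sub("^p_", "padj_", names(pvals))
      row <- c(row, as.list(padj))
    }
    as.data.frame(c(list(trait = tr), row), stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
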