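#' Equalize library sizes before the exact test
#'
#' The conditional argument behind the negative-binomial exact test requires
#' all samples to share a common library size. Counts are rescaled to the
#' geometric mean of the library sizes and rounded to the nearest integer.
#'
#' @param counts Integer gene x sample matrix.
#' @param library_sizes Positive numeric vector, one per column; defaults to
#'   column sums.
#' @return List with `counts` (equalized integer matrix) and `library_size`
#'   (the common size).
#' @export
equalize_libraries <- function(counts, library_sizes = colSums(counts)) {
  if (any(library_sizes <= 0)) stop("library sizes must be positive")
  if (length(library_sizes) != ncol(counts))
    stop("one library size per sample is required")
  common <- exp(mean(log(library_sizes)))
  eq <- round(sweep(counts, 2L, common / library_sizes, `*`))
  storage.mode(eq) <- "double"
  list(counts = eq, library_size = common)
}

# Conditional NB log-likelihood of phi for one group of replicate counts,
# summed over genes. Conditioning on the gene's group sum removes the
# per-gene mean, leaving phi as the only parameter (qCML).
cond_loglik_group <- function(y, phi) {
  n <- ncol(y)
  if (n < 2) return(0)
  r <- 1 / phi
  z <- rowSums(y)
  ll <- rowSums(lgamma(y + r)) + lgamma(n * r) -
    lgamma(z + n * r) - n * lgamma(r)
  sum(ll)
}

#' Common NB dispersion by conditional maximum likelihood
#'
#' Estimates a single dispersion phi (variance = mu + phi * mu^2) shared by
#' all genes, by maximizing the conditional log-likelihood given each gene's
#' within-group sum, summed over genes and over the two groups, on
#' library-size-equalized counts. Conditioning eliminates the per-gene means,
#' so only phi is estimated. The estimate is floored at zero (Poisson).
#'
#' @param counts_a,counts_b Integer gene x replicate matrices for the two
#'   groups (same genes, same row order).
#' @param library_sizes_a,library_sizes_b Optional library sizes per
#'   replicate; default column sums.
#' @param phi_max Upper bound of the search interval.
#' @return List with `phi` (>= 0) and `method = "qCML-common"`.
#' @export
estimate_common_dispersion <- function(counts_a, counts_b,
                                       library_sizes_a = colSums(counts_a),
                                       library_sizes_b = colSums(counts_b),
                                       phi_max = 5) {
  counts_a <- as.matrix(counts_a); counts_b <- as.matrix(counts_b)
  if (nrow(counts_a) != nrow(counts_b))
    stop("the two groups must cover the same genes")
  if (ncol(counts_a) < 2 && ncol(counts_b) < 2)
    stop("at least one group needs >= 2 replicates")
  if (all(counts_a == 0) && all(counts_b == 0))
    stop("all-zero count matrix: dispersion is not estimable")
  all_sizes <- c(library_sizes_a, library_sizes_b)
  eq <- equalize_libraries(cbind(counts_a, counts_b), all_sizes)$counts
  ya <- eq[, seq_len(ncol(counts_a)), drop = FALSE]
  yb <- eq[, ncol(counts_a) + seq_len(ncol(counts_b)), drop = FALSE]
  # drop genes with zero group sums: they carry no dispersion information
  keep_a <- rowSums(ya) > 0
  keep_b <- rowSums(yb) > 0
  obj <- function(log_phi) {
    phi <- exp(log_phi)
    cond_loglik_group(ya[keep_a, , drop = FALSE], phi) +
      cond_loglik_group(yb[keep_b, , drop = FALSE], phi)
  }
  lo <- log(1e-6); hi <- log(phi_max)
  opt <- stats::optimize(obj, c(lo, hi), maximum = TRUE, tol = 1e-6)
  phi <- exp(opt$maximum)
  # boundary at the lower end means the data look (sub-)Poisson: floor at 0
  if (opt$maximum < lo + 1e-3 || obj(lo) >= opt$objective) phi <- 0
  list(phi = phi, method = "qCML-common")
}

# NB probability of a group sum: the sum of n iid NB(mu, phi) variables is
# NB with mean n*mu and size n/phi; phi = 0 is the Poisson limit.
dgroupsum <- function(k, n, mu, phi) {
  if (phi == 0) {
    stats::dpois(k, lambda = n * mu)
  } else {
    stats::dnbinom(k, size = n / phi, mu = n * mu)
  }
}

#' Negative-binomial exact test for a two-group count comparison
#'
#' Conditions on the total count of the two groups. Under the null of a
#' common per-replicate mean, the probability of each split of the total is
#' proportional to `P(A = k) * P(B = total - k)`, where a group's sum of `n`
#' iid NB(mu, phi) replicates is NB with mean `n * mu` and size `n / phi`.
#' The two-sided p-value is the summed probability of every split no more
#' likely than the observed one (ties included, which is conservative). At
#' `phi = 0` the conditional law is binomial(total, n_a / (n_a + n_b)).
#'
#' @param sum_a,sum_b Non-negative integer group sums (library-size-equalized
#'   counts).
#' @param n_a,n_b Replicate counts per group (>= 1).
#' @param phi NB dispersion (>= 0).
#' @param mean Per-replicate null mean; defaults to the pooled mean
#'   `(sum_a + sum_b) / (n_a + n_b)`.
#' @return p-value in (0, 1].
#' @export
nb_exact_test <- function(sum_a, n_a, sum_b, n_b, phi,
                          mean = (sum_a + sum_b) / (n_a + n_b)) {
  if (sum_a < 0 || sum_b < 0) stop("group sums must be non-negative")
  if (n_a < 1 || n_b < 1) stop("replicate counts must be >= 1")
  if (phi < 0) stop("`phi` must be >= 0")
  total <- sum_a + sum_b
  if (total == 0) return(1)
  k <- 0:total
  log_p <- if (phi == 0) {
    stats::dbinom(k, size = total, prob = n_a / (n_a + n_b), log = TRUE)
  } else {
    stats::dnbinom(k, size = n_a / phi, mu = n_a * mean, log = TRUE) +
      stats::dnbinom(total - k, size = n_b / phi, mu = n_b * mean, log = TRUE)
  }
  # normalize on the log scale for numerical stability at large totals
  log_p <- log_p - max(log_p)
  p_split <- exp(log_p) / sum(exp(log_p))
  obs <- p_split[sum_a + 1L]
  p <- sum(p_split[p_split <= obs * (1 + 1e-12)])
  min(1, max(p, .Machine$double.xmin))
}

#' Benjamini-Hochberg adjustment
#'
#' Validating wrapper over the standard step-up procedure
#' (`stats::p.adjust(method = "BH")`).
#'
#' @param p_values Numeric vector of raw p-values in (0, 1].
#' @return Adjusted p-values, element-wise >= the raw values, clipped at 1.
#' @export
bh_adjust <- function(p_values) {
  if (!length(p_values)) return(numeric(0))
  if (anyNA(p_values) || any(p_values <= 0) || any(p_values > 1))
    stop("p-values must lie in (0, 1]")
  stats::p.adjust(p_values, method = "BH")
}

#' Log2 fold change with a pseudocount
#'
#' `log2((mean_b + pseudocount) / (mean_a + pseudocount))`; the pseudocount
#' keeps zero means finite.
#'
#' @param mean_a,mean_b Non-negative expression means (A is the reference).
#' @param pseudocount Positive stabilizer, default 1.
#' @return log2 fold change of B over A.
#' @export
log2_fold_change <- function(mean_a, mean_b, pseudocount = 1) {
  if (any(pseudocount <= 0)) stop("`pseudocount` must be positive")
  log2((mean_b + pseudocount) / (mean_a + pseudocount))
}

#' Flag differentially expressed genes
#'
#' A gene is a DEG when `|log2fc|` strictly exceeds `lfc_threshold` and the
#' BH-adjusted p-value is strictly below `fdr_threshold`.
#'
#' @param records Data frame with columns `gene_id`, `log2fc`, `p_adj`.
#' @param lfc_threshold Absolute log2 fold-change cutoff, default 1.5.
#' @param fdr_threshold Adjusted-p cutoff, default 0.05.
#' @return Character vector of DEG gene ids.
#' @export
call_degs <- function(records, lfc_threshold = 1.5, fdr_threshold = 0.05) {
  stopifnot(all(c("gene_id", "log2fc", "p_adj") %in% names(records)))
  records$gene_id[abs(records$log2fc) > lfc_threshold &
                    records$p_adj < fdr_threshold]
}

#' Pairwise differential expression between two genetic types
#'
#' Runs the full exact-test pipeline for one contrast: library-size
#' equalization, common-dispersion estimation (unless `phi` is supplied),
#' per-gene NB exact tests on the group sums, BH adjustment, fold change on
#' type-mean RPKM with a pseudocount, and DEG flags.
#'
#' @param cm A [count_matrix()].
#' @param type_a,type_b Genetic types to contrast (fold change is B over A).
#' @param genes Optional gene ids to test (e.g. the expressed universe);
#'   default all genes.
#' @param phi Optional fixed dispersion; estimated from the data when NULL.
#' @param pseudocount Pseudocount for the RPKM fold change, default 1.
#' @param lfc_threshold,fdr_threshold DEG thresholds, defaults 1.5 and 0.05.
#' @param library_sizes Optional named library sizes (see [compute_rpkm()]).
#' @return Data frame with one row per gene: `gene_id`, `mean_a`, `mean_b`
#'   (type-mean RPKM), `log2fc`, `p_raw`, `p_adj`, `is_deg`; the dispersion
#'   used is attached as attribute `"phi"`.
#' @export
de_pairwise <- function(cm, type_a, type_b, genes = NULL, phi = NULL,
                        pseudocount = 1, lfc_threshold = 1.5,
                        fdr_threshold = 0.05, library_sizes = NULL) {
  stopifnot(inherits(cm, "count_matrix"))
  for (ty in c(type_a, type_b))
    if (!any(cm$type_map == ty)) stop("no samples of genetic type ", ty)
  if (is.null(library_sizes)) library_sizes <- colSums(cm$counts)
  else library_sizes <- library_sizes[colnames(cm$counts)]
  sel <- if (is.null(genes)) rownames(cm$counts) else {
    missing <- setdiff(genes, rownames(cm$counts))
    if (length(missing))
      stop("genes not in the count matrix: ",
           paste(utils::head(missing, 5), collapse = ", "))
    genes
  }
  cols_a <- which(cm$type_map == type_a)
  cols_b <- which(cm$type_map == type_b)
  ya_all <- cm$counts[, cols_a, drop = FALSE]
  yb_all <- cm$counts[, cols_b, drop = FALSE]
  if (is.null(phi)) {
    phi <- estimate_common_dispersion(
      ya_all, yb_all, library_sizes[cols_a], library_sizes[cols_b]
    )$phi
  }
  eq <- equalize_libraries(cbind(ya_all, yb_all),
                           library_sizes[c(cols_a, cols_b)])$counts
  ya <- eq[sel, seq_along(cols_a), drop = FALSE]
  yb <- eq[sel, length(cols_a) + seq_along(cols_b), drop = FALSE]
  n_a <- ncol(ya); n_b <- ncol(yb)
  sums_a <- rowSums(ya); sums_b <- rowSums(yb)
  p_raw <- vapply(seq_along(sel), function(i) {
    nb_exact_test(sums_a[i], n_a, sums_b[i], n_b, phi)
  }, numeric(1))

  rpkm <- compute_rpkm(cm, library_sizes)
  tm <- aggregate_by_type(rpkm[sel, c(cols_a, cols_b), drop = FALSE],
                          cm$type_map[c(cols_a, cols_b)])
  mean_a <- tm[, type_a]; mean_b <- tm[, type_b]
  res <- data.frame(
    gene_id = sel,
    mean_a = unname(mean_a),
    mean_b = unname(mean_b),
    log2fc = log2_fold_change(unname(mean_a), unname(mean_b), pseudocount),
    p_raw = p_raw,
    row.names = NULL, stringsAsFactors = FALSE
  )
  res$p_adj <- bh_adjust(res$p_raw)
  res$is_deg <- abs(res$log2fc) > lfc_threshold & res$p_adj < fdr_threshold
  attr(res, "phi") <- phi
  attr(res, "contrast") <- c(type_a = type_a, type_b = type_b)
  res
}
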