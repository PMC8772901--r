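#' Construct a validated count matrix object
#'
#' Bundles an integer gene x sample count matrix with per-gene transcript
#' lengths and the sample-to-genetic-type assignment. All downstream stages
#' consume this container.
#'
#' @param counts Integer matrix, genes in rows, samples in columns; dimnames
#'   required (gene ids, sample ids).
#' @param lengths Named numeric vector of transcript lengths in bp, one entry
#'   per gene of `counts` (order is reconciled by name).
#' @param type_map Named character vector mapping each sample id to one of
#'   `PC`, `PB`, `F1BC`, `F1CB`.
#' @return An object of class `count_matrix`: a list with elements `counts`,
#'   `lengths`, `type_map`.
#' @export
count_matrix <- function(counts, lengths, type_map) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("`counts` must have gene ids as rownames and sample ids as colnames")
  if (anyDuplicated(rownames(counts)))
    stop("duplicate gene ids in `counts`")
  if (anyDuplicated(colnames(counts)))
    stop("duplicate sample ids in `counts`")
  if (any(counts < 0))
    stop("negative counts are not allowed")
  if (is.null(names(lengths)))
    stop("`lengths` must be named by gene id")
  missing_len <- setdiff(rownames(counts), names(lengths))
  if (length(missing_len))
    stop("genes without a length: ", paste(utils::head(missing_len, 5), collapse = ", "))
  lengths <- lengths[rownames(counts)]
  if (any(lengths <= 0))
    stop("gene lengths must be positive")
  if (is.null(names(type_map)))
    stop("`type_map` must be named by sample id")
  missing_ty <- setdiff(colnames(counts), names(type_map))
  if (length(missing_ty))
    stop("samples without a genetic type: ", paste(missing_ty, collapse = ", "))
  type_map <- type_map[colnames(counts)]
  bad <- setdiff(unique(type_map), GENETIC_TYPES)
  if (length(bad))
    stop("unknown genetic type token(s): ", paste(bad, collapse = ", "))
  structure(
    list(counts = counts, lengths = lengths, type_map = type_map),
    class = "count_matrix"
  )
}

#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf(
    "count_matrix: %d genes x %d samples (%s)\n",
    nrow(x$counts), ncol(x$counts),
    paste(sprintf("%s=%d", names(table(x$type_map)), table(x$type_map)),
          collapse = ", ")
  ))
  invisible(x)
}

#' RPKM normalization
#'
#' Reads Per Kilobase of transcript per Million mapped reads:
#' `RPKM = count * 1e9 / (length_bp * library_size)`. When library sizes are
#' not supplied they default to the per-sample column sums of the count
#' matrix (the total-mapped-reads denominator is not recoverable from a count
#' matrix; column sums are the standard stand-in, and an explicit vector
#' overrides them).
#'
#' @param cm A [count_matrix()].
#' @param library_sizes Optional named numeric vector of library sizes per
#'   sample; defaults to column sums.
#' @return Numeric gene x sample matrix of RPKM values (same dimnames as the
#'   counts).
#' @export
compute_rpkm <- function(cm, library_sizes = NULL) {
  stopifnot(inherits(cm, "count_matrix"))
  if (is.null(library_sizes)) {
    library_sizes <- colSums(cm$counts)
  } else {
    if (is.null(names(library_sizes)))
      stop("`library_sizes` must be named by sample id")
    missing <- setdiff(colnames(cm$counts), names(library_sizes))
    if (length(missing))
      stop("samples without a library size: ", paste(missing, collapse = ", "))
    library_sizes <- library_sizes[colnames(cm$counts)]
  }
  if (any(library_sizes <= 0))
    stop("library sizes must be positive")
  if (any(cm$lengths <= 0))
    stop("gene lengths must be positive")
  rpkm <- cm$counts * 1e9 /
    outer(as.numeric(cm$lengths), as.numeric(library_sizes))
  dimnames(rpkm) <- dimnames(cm$counts)
  rpkm
}

#' Average expression per genetic type
#'
#' Arithmetic mean of the replicate RPKM columns within each genetic type.
#'
#' @param expr Numeric gene x sample matrix (e.g. from [compute_rpkm()]).
#' @param type_map Named character vector sample id -> genetic type.
#' @return Numeric gene x type matrix with one column per genetic type
#'   present, plus a `"replicates"` attribute giving replicate counts.
#' @export
aggregate_by_type <- function(expr, type_map) {
  if (is.null(names(type_map)))
    stop("`type_map` must be named by sample id")
  type_map <- type_map[colnames(expr)]
  if (anyNA(type_map))
    stop("samples without a genetic type in `type_map`")
  types <- intersect(GENETIC_TYPES, unique(type_map))
  means <- vapply(types, function(ty) {
    cols <- which(type_map == ty)
    if (!length(cols)) stop("genetic type without samples: ", ty)
    rowMeans(expr[, cols, drop = FALSE])
  }, numeric(nrow(expr)))
  dimnames(means) <- list(rownames(expr), types)
  attr(means, "replicates") <- table(factor(type_map, levels = types))
  means
}

#' Expressed-gene filter
#'
#' A gene is expressed when its type-mean RPKM exceeds `threshold` (strictly)
#' in at least one genetic type. The default of 1.0 is the conventional RPKM
#' floor below which counts are dominated by sampling noise.
#'
#' @param type_means Gene x type matrix from [aggregate_by_type()].
#' @param threshold Non-negative RPKM cutoff (strict `>`); default 1.0.
#' @return Character vector of retained gene ids, in input order.
#' @export
filter_expressed <- function(type_means, threshold = 1.0) {
  if (threshold < 0) stop("`threshold` must be >= 0")
  keep <- apply(type_means > threshold, 1L, any)
  rownames(type_means)[keep]
}

#' Spearman rank correlation
#'
#' Pearson correlation of mid-ranks (average ranks on ties). A constant
#' vector has no rank ordering and is rejected rather than returning NA.
#'
#' @param x,y Numeric vectors of equal length >= 3.
#' @return rho in \[-1, 1\].
#' @export
spearman_correlation <- function(x, y) {
  if (length(x) != length(y)) stop("`x` and `y` must have equal length")
  if (length(x) < 3) stop("need at least 3 observations")
  if (anyNA(x) || anyNA(y)) stop("missing values are not supported")
  if (stats::var(x) == 0 || stats::var(y) == 0)
    stop("Spearman correlation is undefined for a constant vector")
  stats::cor(x, y, method = "spearman")
}
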