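#' Read a TSV count matrix
#'
#' Expected layout: header row, first column gene ids, one integer column per
#' sample. Lines starting with `#` are ignored.
#'
#' @param path File path.
#' @return Integer matrix with gene rownames and sample colnames (assemble a
#'   full container with [count_matrix()] once lengths and metadata are
#'   loaded, or use [read_experiment()]).
#' @export
read_counts <- function(path) {
  df <- utils::read.delim(path, comment.char = "#", check.names = FALSE,
                          stringsAsFactors = FALSE)
  if (ncol(df) < 2) stop("count matrix needs a gene_id column plus samples: ", path)
  ids <- as.character(df[[1]])
  if (anyDuplicated(ids)) {
    dup <- unique(ids[duplicated(ids)])
    stop("duplicate gene ids in ", path, ": ",
         paste(utils::head(dup, 5), collapse = ", "))
  }
  m <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(m)) stop("non-numeric count column in ", path)
  neg <- which(m < 0, arr.ind = TRUE)
  if (nrow(neg))
    stop(sprintf("negative count at gene '%s', sample '%s' in %s",
                 ids[neg[1, 1]], colnames(m)[neg[1, 2]], path))
  if (any(m != round(m))) stop("counts must be integers: ", path)
  rownames(m) <- ids
  storage.mode(m) <- "integer"
  m
}

#' Read a two-column gene-length TSV
#'
#' Columns: gene_id, length_bp. Lines starting with `#` are ignored.
#'
#' @param path File path.
#' @return Named numeric vector of lengths (bp).
#' @export
read_lengths <- function(path) {
  df <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  if (ncol(df) < 2) stop("lengths file needs gene_id and length_bp columns: ", path)
  ids <- as.character(df[[1]])
  if (anyDuplicated(ids)) stop("duplicate gene ids in ", path)
  len <- as.numeric(df[[2]])
  if (any(is.na(len)) || any(len <= 0))
    stop("gene lengths must be positive numbers: ", path)
  stats::setNames(len, ids)
}

#' Read a sample-metadata TSV
#'
#' Columns: sample_id, genetic_type (one of PC, PB, F1BC, F1CB).
#'
#' @param path File path.
#' @return Named character vector sample_id -> genetic type.
#' @export
read_metadata <- function(path) {
  df <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  if (!all(c("sample_id", "genetic_type") %in% names(df)))
    stop("metadata needs sample_id and genetic_type columns: ", path)
  if (anyDuplicated(df$sample_id)) stop("duplicate sample ids in ", path)
  bad <- setdiff(unique(df$genetic_type), GENETIC_TYPES)
  if (length(bad))
    stop("unknown genetic type token(s) in ", path, ": ",
         paste(bad, collapse = ", "))
  stats::setNames(as.character(df$genetic_type), df$sample_id)
}

#' Read a phenotype CSV
#'
#' Header: individual_id, genetic_type, then one numeric column per trait.
#'
#' @param path File path.
#' @return Data frame.
#' @export
read_phenotypes <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (!all(c("individual_id", "genetic_type") %in% names(df)))
    stop("phenotype table needs individual_id and genetic_type columns: ", path)
  if (anyDuplicated(df$individual_id)) stop("duplicate individual ids in ", path)
  bad <- setdiff(unique(df$genetic_type), GENETIC_TYPES)
  if (length(bad))
    stop("unknown genetic type token(s) in ", path, ": ",
         paste(bad, collapse = ", "))
  df
}

#' Assemble a count matrix from the three on-disk tables
#'
#' Reads counts, lengths, and sample metadata, reconciles the gene sets by
#' strict intersection (a warning lists dropped ids on either side), and
#' validates the result.
#'
#' @param counts_path,lengths_path,metadata_path File paths.
#' @return A [count_matrix()].
#' @export
read_experiment <- function(counts_path, lengths_path, metadata_path) {
  counts <- read_counts(counts_path)
  lengths <- read_lengths(lengths_path)
  type_map <- read_metadata(metadata_path)
  only_counts <- setdiff(rownames(counts), names(lengths))
  only_lengths <- setdiff(names(lengths), rownames(counts))
  if (length(only_counts) || length(only_lengths)) {
    warning(sprintf(
      "gene sets differ between counts and lengths; dropping %d count-only (%s) and %d length-only (%s) ids",
      length(only_counts), paste(utils::head(only_counts, 3), collapse = ", "),
      length(only_lengths), paste(utils::head(only_lengths, 3), collapse = ", ")
    ))
    shared <- intersect(rownames(counts), names(lengths))
    if (!length(shared)) stop("no genes shared between counts and lengths")
    counts <- counts[shared, , drop = FALSE]
    lengths <- lengths[shared]
  }
  count_matrix(counts, lengths, type_map)
}

#' Gene lengths from a GFF3 file
#'
#' Per-gene length is the summed width of the non-overlapping union of that
#' gene's exons (GFF3 coordinates are 1-based inclusive). Exons are linked to
#' genes through the `gene_id` attribute when present, else via their
#' `Parent` transcript's `Parent` gene. Requires the rtracklayer and
#' GenomicRanges packages.
#'
#' @param path GFF3 file path.
#' @return Named numeric vector of lengths (bp).
#' @export
gff_gene_lengths <- function(path) {
  if (!requireNamespace("rtracklayer", quietly = TRUE) ||
      !requireNamespace("GenomicRanges", quietly = TRUE))
    stop("GFF3 input requires the rtracklayer and GenomicRanges packages")
  gr <- rtracklayer::import(path, format = "gff3")
  exons <- gr[tolower(as.character(gr$type)) == "exon"]
  if (!length(exons)) stop("no exon features in ", path)
  md <- S4Vectors::mcols(exons)
  gene <- if ("gene_id" %in% names(md)) {
    as.character(md$gene_id)
  } else {
    # map exon -> transcript -> gene through Parent attributes
    parents <- as.character(md$Parent)
    tx <- gr[as.character(gr$ID) %in% parents]
    tx_gene <- stats::setNames(as.character(tx$Parent), as.character(tx$ID))
    unname(tx_gene[parents])
  }
  if (anyNA(gene)) stop("could not resolve a gene id for every exon in ", path)
  by_gene <- split(exons, gene)
  vapply(by_gene, function(e)
    sum(GenomicRanges::width(GenomicRanges::reduce(e))), numeric(1))
}

#' Write the standard output tables of a pipeline run
#'
#' @param x Object to write (matrix or data frame).
#' @param path Output file.
#' @param format `"tsv"` or `"csv"`.
#' @return `path`, invisibly.
#' @export
write_table <- function(x, path, format = c("tsv", "csv")) {
  format <- match.arg(format)
  sep <- if (format == "tsv") "\t" else ","
  if (is.matrix(x)) {
    df <- data.frame(gene_id = rownames(x), x, row.names = NULL,
                     check.names = FALSE, stringsAsFactors = FALSE)
  } else df <- x
  utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}
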