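#' Directional transgressive call for one hybrid
#'
#' A hybrid's expression is called transgressive-up when it is at least
#' `margin` above the parental envelope (`f1 >= (1 + margin) * max(parents)`)
#' and transgressive-down when at least `margin` below it
#' (`f1 <= (1 - margin) * min(parents)`); otherwise `none`. Both boundaries
#' are inclusive ("at least"). When a parental bound is zero the margin rule
#' degenerates, so an up call additionally requires `f1 > max(parents)` and a
#' down call `f1 < min(parents)`; for positive parents these extra conditions
#' are implied by the margin and change nothing.
#'
#' @param mean_pc,mean_pb Parental type-mean expression (>= 0).
#' @param mean_f1 Hybrid type-mean expression (>= 0).
#' @param margin Fractional margin beyond the parental envelope, in \[0, 1);
#'   default 0.2 (20%).
#' @return One of `"up"`, `"down"`, `"none"` (vectorized over the inputs).
#' @export
call_transgressive_per_hybrid <- function(mean_pc, mean_pb, mean_f1,
                                          margin = 0.2) {
  if (margin < 0 || margin >= 1) stop("`margin` must lie in [0, 1)")
  if (any(mean_pc < 0) || any(mean_pb < 0) || any(mean_f1 < 0))
    stop("expression means must be non-negative")
  hi <- pmax(mean_pc, mean_pb)
  lo <- pmin(mean_pc, mean_pb)
  up <- mean_f1 >= (1 + margin) * hi & mean_f1 > hi
  down <- mean_f1 <= (1 - margin) * lo & mean_f1 < lo
  out <- rep("none", length(mean_f1))
  out[up] <- "up"
  out[down] <- "down"
  out
}

#' Combine the two reciprocal-hybrid calls into an inheritance class
#'
#' Truth table over the directional calls in the two reciprocal hybrids:
#' transgressive in the same direction in both hybrids is concordant (up or
#' down); transgressive in exactly one hybrid is discordant I; transgressive
#' in opposite directions is discordant II; transgressive in neither is
#' non-transgressive.
#'
#' @param call_BC,call_CB Calls in the F1BC and F1CB hybrids, each one of
#'   `"up"`, `"down"`, `"none"` (vectorized).
#' @return Class label: `concordant_up`, `concordant_down`, `discordant_I`,
#'   `discordant_II`, or `non_transgressive`.
#' @export
classify_gene <- function(call_BC, call_CB) {
  ok <- c("up", "down", "none")
  if (!all(call_BC %in% ok) || !all(call_CB %in% ok))
    stop("calls must be one of 'up', 'down', 'none'")
  out <- character(length(call_BC))
  out[call_BC == "up" & call_CB == "up"] <- "concordant_up"
  out[call_BC == "down" & call_CB == "down"] <- "concordant_down"
  out[(call_BC == "up" & call_CB == "down") |
        (call_BC == "down" & call_CB == "up")] <- "discordant_II"
  out[xor(call_BC == "none", call_CB == "none")] <- "discordant_I"
  out[call_BC == "none" & call_CB == "none"] <- "non_transgressive"
  out
}

#' Classify every expressed gene's inheritance mode
#'
#' Applies the per-hybrid margin rule to both reciprocal hybrids and the
#' truth table of [classify_gene()] over the expressed-gene universe.
#'
#' @param type_means Gene x type matrix (columns `PC`, `PB`, `F1BC`, `F1CB`)
#'   from [aggregate_by_type()].
#' @param expressed Character vector of gene ids to classify (must be a
#'   subset of the rownames of `type_means`); non-empty.
#' @param margin Transgressive margin, default 0.2.
#' @return Data frame with columns `gene_id`, `call_BC`, `call_CB`, `klass`.
#' @export
classify_all <- function(type_means, expressed, margin = 0.2) {
  if (!length(expressed)) stop("`expressed` gene set is empty")
  if (!all(GENETIC_TYPES %in% colnames(type_means)))
    stop("`type_means` must have columns PC, PB, F1BC, F1CB")
  missing <- setdiff(expressed, rownames(type_means))
  if (length(missing))
    stop("expressed genes absent from `type_means`: ",
         paste(utils::head(missing, 5), collapse = ", "))
  tm <- type_means[expressed, , drop = FALSE]
  call_BC <- call_transgressive_per_hybrid(tm[, "PC"], tm[, "PB"],
                                           tm[, "F1BC"], margin)
  call_CB <- call_transgressive_per_hybrid(tm[, "PC"], tm[, "PB"],
                                           tm[, "F1CB"], margin)
  data.frame(
    gene_id = expressed,
    call_BC = call_BC,
    call_CB = call_CB,
    klass = classify_gene(call_BC, call_CB),
    row.names = NULL, stringsAsFactors = FALSE
  )
}

TRANSGRESSIVE_CLASSES <- c("concordant_up", "concordant_down",
                           "discordant_I", "discordant_II")

#' Summarize inheritance-class composition
#'
#' Counts per class plus the derived percentages the field reports:
#' transgressive share of the expressed universe (one decimal), the
#' downregulated fraction within concordant genes (nearest integer), and each
#' discordant class's share of all transgressive genes (one decimal). All
#' percentages are recomputed from the integer counts.
#'
#' @param calls Either a data frame from [classify_all()] (with a `klass`
#'   column) or a named numeric vector/list of class counts.
#' @param universe_size Number of genes in the expressed universe.
#' @return Object of class `class_summary`: list with `counts`,
#'   `n_transgressive`, `universe_size`, `pct_transgressive`,
#'   `pct_concordant_down`, `pct_discordant_I`, `pct_discordant_II`.
#' @export
summarize_classes <- function(calls, universe_size) {
  if (universe_size <= 0) stop("`universe_size` must be positive")
  if (is.data.frame(calls)) {
    counts <- table(factor(calls$klass,
                           levels = c(TRANSGRESSIVE_CLASSES, "non_transgressive")))
    counts <- as.numeric(counts)
    names(counts) <- c(TRANSGRESSIVE_CLASSES, "non_transgressive")
  } else {
    counts <- stats::setNames(rep(0, 5),
                              c(TRANSGRESSIVE_CLASSES, "non_transgressive"))
    counts[names(calls)] <- unlist(calls)
  }
  n_trans <- sum(counts[TRANSGRESSIVE_CLASSES])
  if (n_trans > universe_size)
    stop("more transgressive genes than the universe size")
  n_conc <- counts[["concordant_up"]] + counts[["concordant_down"]]
  structure(list(
    counts = counts,
    n_transgressive = n_trans,
    universe_size = universe_size,
    pct_transgressive = round(100 * n_trans / universe_size, 1),
    pct_concordant_down = if (n_conc > 0)
      round(100 * counts[["concordant_down"]] / n_conc) else NA_real_,
    pct_discordant_I = if (n_trans > 0)
      round(100 * counts[["discordant_I"]] / n_trans, 1) else NA_real_,
    pct_discordant_II = if (n_trans > 0)
      round(100 * counts[["discordant_II"]] / n_trans, 1) else NA_real_
  ), class = "class_summary")
}

#' @export
print.class_summary <- function(x, ...) {
  cat(sprintf("Expressed universe: %d genes\n", x$universe_size))
  cat(sprintf("Transgressive: %d (%.1f%% of expressed)\n",
              x$n_transgressive, x$pct_transgressive))
  for (k in names(x$counts))
    cat(sprintf("  %-18s %d\n", k, x$counts[[k]]))
  if (!is.na(x$pct_concordant_down))
    cat(sprintf("Concordant genes downregulated: %.0f%%\n",
                x$pct_concordant_down))
  if (!is.na(x$pct_discordant_II))
    cat(sprintf("Discordant I / II of transgressive: %.1f%% / %.1f%%\n",
                x$pct_discordant_I, x$pct_discordant_II))
  invisible(x)
}

#' Fraction of transgressive genes shared by the two reciprocal hybrids
#'
#' Venn-style overlap: genes transgressive in both hybrids (concordant or
#' discordant II) over genes transgressive in at least one hybrid.
#'
#' @param calls Data frame from [classify_all()].
#' @return List with `shared_fraction` in \[0, 1\] and the Venn cells `both`,
#'   `BC_only`, `CB_only`.
#' @export
hybrid_overlap <- function(calls) {
  in_bc <- calls$call_BC != "none"
  in_cb <- calls$call_CB != "none"
  any_t <- in_bc | in_cb
  if (!any(any_t)) stop("no transgressive genes: overlap is undefined")
  list(
    shared_fraction = sum(in_bc & in_cb) / sum(any_t),
    both = sum(in_bc & in_cb),
    BC_only = sum(in_bc & !in_cb),
    CB_only = sum(!in_bc & in_cb)
  )
}

#' Percentage helper with render-time rounding
#'
#' Percentages in reports are always recomputed from integer counts; this
#' helper centralizes the arithmetic and rounding convention.
#'
#' @param count,universe Non-negative count and positive denominator.
#' @param digits Decimal places, default 1.
#' @return `round(100 * count / universe, digits)`.
#' @export
percent_of <- function(count, universe, digits = 1) {
  if (universe <= 0) stop("`universe` must be positive")
  round(100 * count / universe, digits)
}
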