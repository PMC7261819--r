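# PSM/peptide -> protein summarization.
# Both summarizers are complete-case: a row missing any of the samples it
# should cover is dropped before aggregation, and protein counts always
# equal the number of rows actually used.

.grouped_col_medians <- function(mat, protein) {
  prot <- factor(protein, levels = unique(protein))
  idx <- split(seq_len(nrow(mat)), prot)
  out <- t(vapply(idx, function(i) {
    if (length(i) == 1L) mat[i, ]
    else apply(mat[i, , drop = FALSE], 2, stats::median)
  }, numeric(ncol(mat))))
  colnames(out) <- colnames(mat)
  list(values = out, count = lengths(idx))
}

.median_sweep_one <- function(intens, protein) {
  keep <- rowSums(is.na(intens)) == 0
  if (!any(keep))
    stop("median_sweep: no rows with complete intensities")
  if (any(!keep))
    message("median_sweep: ", sum(!keep),
            " row(s) dropped for missing intensities (",
            length(setdiff(unique(protein), unique(protein[keep]))),
            " protein(s) lost)")
  m <- log2(intens[keep, , drop = FALSE])
  m <- m - apply(m, 1, stats::median)               # row (PSM) medians out
  agg <- .grouped_col_medians(m, protein[keep])     # protein-wise medians
  vals <- sweep(agg$values, 2, apply(agg$values, 2, stats::median))
  list(values = vals, count = agg$count)
}

#' Median-sweeping summarization of PSM intensities
#'
#' Turns raw PSM (or peptide) intensities into a protein-level log2
#' relative abundance matrix in four steps: (1) log2-transform; (2) from
#' each row subtract its median across samples; (3) for each protein take,
#' per sample, the median over its rows; (4) from each sample column
#' subtract the column median.  After step 4 every column median is 0.
#' The per-protein count is the number of rows used.
#'
#' For multi-batch tables (non-`NULL` `batch`) the sweep is applied per
#' batch on that batch's observed sample columns; the per-batch matrices
#' are inner-joined on protein id, per-batch counts are kept in
#' `batch_counts`, and the single `count` is derived with
#' [combine_counts()] (default metric `"min"`).
#'
#' @param table a [quant_table()].
#' @param count_metric metric used to unify per-batch counts; see
#'   [combine_counts()].
#' @return A [protein_matrix()].
#' @export
median_sweep <- function(table, count_metric = "min") {
  stopifnot(inherits(table, "quant_table"))
  if (is.null(table$batch) || length(unique(table$batch)) == 1L) {
    res <- .median_sweep_one(table$intensities, table$protein_id)
    return(protein_matrix(res$values, res$count))
  }
  .join_batches(table, count_metric, function(intens, protein, refs)
    .median_sweep_one(intens, protein))
}

.batch_columns <- function(intens, rows) {
  # columns a batch actually measured: not entirely missing in its rows
  cols <- colSums(!is.na(intens[rows, , drop = FALSE])) > 0
  if (!any(cols)) stop("batch with no observed intensity columns")
  which(cols)
}

.join_batches <- function(table, count_metric, one_batch, design = NULL) {
  batches <- unique(table$batch)
  parts <- vector("list", length(batches))
  names(parts) <- batches
  for (b in batches) {
    rows <- which(table$batch == b)
    cols <- .batch_columns(table$intensities, rows)
    if (!is.null(design)) {
      in_b <- names(design$batches)[design$batches == b]
      cols <- intersect(cols, match(in_b, colnames(table$intensities)))
      if (!length(cols)) stop("no design samples for batch ", b)
    }
    refs <- NULL
    if (!is.null(design) && !is.null(design$reference_samples)) {
      refs <- intersect(design$reference_samples,
                        colnames(table$intensities)[cols])
      if (!length(refs))
        stop("batch ", b, " declares no reference sample")
    }
    parts[[b]] <- one_batch(table$intensities[rows, cols, drop = FALSE],
                            table$protein_id[rows], refs)
  }
  shared <- Reduce(intersect, lapply(parts, function(p) rownames(p$values)))
  if (!length(shared))
    stop("no protein quantified in every batch")
  dropped <- sum(vapply(parts, function(p) nrow(p$values), 0L)) -
    length(shared) * length(parts)
  if (dropped > 0)
    message("multi-batch join: proteins not quantified in every batch ",
            "were excluded")
  vals <- do.call(cbind, lapply(parts, function(p)
    p$values[shared, , drop = FALSE]))
  batch_counts <- do.call(cbind, lapply(parts, function(p) p$count[shared]))
  colnames(batch_counts) <- batches
  protein_matrix(vals, combine_counts(batch_counts, count_metric),
                 batch_counts = batch_counts)
}

.reference_ratio_one <- function(intens, protein, refs) {
  ref_idx <- match(refs, colnames(intens))
  den <- rowMeans(intens[, ref_idx, drop = FALSE])
  keep_cols <- setdiff(seq_len(ncol(intens)), ref_idx)
  num <- intens[, keep_cols, drop = FALSE]
  keep <- !is.na(den) & den > 0 & rowSums(is.na(num)) == 0
  if (!any(keep))
    stop("reference_ratio: no rows with observed reference and samples")
  if (any(!keep))
    message("reference_ratio: ", sum(!keep),
            " row(s) dropped (missing reference or sample intensity)")
  ratios <- num[keep, , drop = FALSE] / den[keep]
  agg <- .grouped_col_medians(ratios, protein[keep])
  list(values = log2(agg$values), count = agg$count)
}

#' Reference-channel ratio summarization
#'
#' For TMT designs with one or more internal reference channels per batch:
#' each row's sample intensities are divided by the mean intensity of the
#' reference channel(s), the per-protein per-sample median of those ratios
#' is taken, and the result is log2-transformed.  Reference columns are
#' excluded from the output; rows whose reference intensity is missing or
#' zero are dropped.
#'
#' @param table a [quant_table()].
#' @param design a [design_spec()] declaring at least one reference sample
#'   per batch (`reference_samples`, plus `batches` for multi-batch data).
#' @param count_metric metric used to unify per-batch counts.
#' @return A [protein_matrix()] over the non-reference samples.
#' @export
reference_ratio <- function(table, design, count_metric = "min") {
  stopifnot(inherits(table, "quant_table"), inherits(design, "design_spec"))
  if (is.null(design$reference_samples))
    stop("design declares no reference samples")
  if (is.null(table$batch) || length(unique(table$batch)) == 1L) {
    refs <- intersect(design$reference_samples, table$sample_ids)
    if (!length(refs)) stop("no reference sample among table columns")
    res <- .reference_ratio_one(table$intensities, table$protein_id, refs)
    return(protein_matrix(res$values, res$count))
  }
  .join_batches(table, count_metric, .reference_ratio_one, design = design)
}

#' Unify per-batch PSM counts into a single count per protein
#'
#' For data sets spanning several TMT experiments a protein is usually
#' quantified by a different number of PSMs in each set; the variance model
#' needs one count per protein.  The recommended metric is `"min"`: the
#' weakest experiment dominates the quantification error.  `"mean"` and
#' `"median"` are rounded half-up and floored at 1.
#'
#' @param per_batch integer matrix, proteins x batches (all entries >= 1).
#' @param metric one of `"min"`, `"mean"`, `"median"`, `"sum"`, `"max"`.
#' @return Named integer vector of combined counts.
#' @export
combine_counts <- function(per_batch,
                           metric = c("min", "mean", "median", "sum", "max")) {
  metric <- match.arg(metric)
  per_batch <- as.matrix(per_batch)
  if (any(is.na(per_batch)) || any(per_batch < 1))
    stop("per-batch counts must be >= 1 (proteins absent from a batch are ",
         "excluded upstream)")
  x <- switch(metric,
    min = do.call(pmin, as.data.frame(per_batch)),
    max = do.call(pmax, as.data.frame(per_batch)),
    sum = rowSums(per_batch),
    mean = floor(rowMeans(per_batch) + 0.5),
    median = floor(apply(per_batch, 1, stats::median) + 0.5))
  out <- as.integer(pmax(x, 1))
  names(out) <- rownames(per_batch)
  out
}
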