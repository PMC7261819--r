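#' PSM- or peptide-level quantification table
#'
#' Container for search-engine quantification output: one row per PSM (or
#' peptide for label-free data), with a protein assignment and one raw
#' intensity per sample.  Intensities are on an arbitrary linear scale;
#' `NA` means "not observed" (zeros in input files are converted to `NA`
#' by [read_quant_table()]).
#'
#' @param feature_id character vector of PSM/peptide identifiers.
#' @param protein_id character vector assigning each row to a protein; must
#'   be non-empty for every row.
#' @param intensities numeric matrix with one row per feature and one column
#'   per sample; values non-negative or `NA`.
#' @param sample_ids character vector of sample names; defaults to the
#'   column names of `intensities`.
#' @param batch optional character vector of batch labels per row (e.g. the
#'   TMT set a PSM was measured in).
#'
#' @return An object of class `quant_table`: a list with elements
#'   `feature_id`, `protein_id`, `intensities`, `sample_ids`, `batch`.
#' @seealso [median_sweep()], [reference_ratio()], [read_quant_table()]
#' @export
quant_table <- function(feature_id, protein_id, intensities,
                        sample_ids = colnames(intensities), batch = NULL) {
  intensities <- as.matrix(intensities)
  storage.mode(intensities) <- "double"
  n <- nrow(intensities)
  feature_id <- as.character(feature_id)
  protein_id <- as.character(protein_id)
  if (length(feature_id) != n || length(protein_id) != n)
    stop("feature_id, protein_id and intensities must have one entry per row")
  if (is.null(sample_ids))
    sample_ids <- paste0("sample", seq_len(ncol(intensities)))
  sample_ids <- as.character(sample_ids)
  if (length(sample_ids) != ncol(intensities))
    stop("sample_ids must name every intensity column")
  if (anyDuplicated(sample_ids))
    stop("duplicate sample ids")
  if (any(is.na(protein_id) | !nzchar(protein_id)))
    stop("protein_id must be non-empty for every row")
  if (any(intensities < 0, na.rm = TRUE))
    stop("intensities must be non-negative")
  if (!is.null(batch)) {
    batch <- as.character(batch)
    if (length(batch) != n)
      stop("batch must have one entry per row")
  }
  dimnames(intensities) <- list(NULL, sample_ids)
  structure(list(feature_id = feature_id, protein_id = protein_id,
                 intensities = intensities, sample_ids = sample_ids,
                 batch = batch),
            class = "quant_table")
}

#' @export
print.quant_table <- function(x, ...) {
  cat("quant_table:", nrow(x$intensities), "rows,",
      length(unique(x$protein_id)), "proteins,",
      length(x$sample_ids), "samples")
  if (!is.null(x$batch)) cat(",", length(unique(x$batch)), "batches")
  cat("\n")
  invisible(x)
}

#' Protein-level log2 relative abundance matrix
#'
#' Proteins x samples matrix of log2 relative abundances together with the
#' per-protein quantification depth: the number of PSMs (labeled data) or
#' peptides (label-free) used to quantify each protein.  The matrix is
#' complete-case: no missing values are allowed.
#'
#' @param values numeric matrix (proteins x samples) with rownames giving
#'   protein ids and colnames giving sample ids; no `NA`s.
#' @param count integer vector, one entry >= 1 per protein.
#' @param batch_counts optional integer matrix (proteins x batches) of
#'   per-batch counts, kept when a matrix is assembled from several TMT
#'   sets; see [combine_counts()].
#'
#' @return An object of class `protein_matrix`.
#' @export
protein_matrix <- function(values, count, batch_counts = NULL) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(rownames(values)))
    rownames(values) <- paste0("protein", seq_len(nrow(values)))
  if (is.null(colnames(values)))
    colnames(values) <- paste0("sample", seq_len(ncol(values)))
  if (anyNA(values))
    stop("protein_matrix must be complete-case (no missing values)")
  dup <- rownames(values)[duplicated(rownames(values))]
  if (length(dup))
    stop("duplicate protein ids: ", paste(unique(dup), collapse = ", "))
  count <- as.integer(round(count))
  if (length(count) != nrow(values))
    stop("count must have one entry per protein")
  if (any(is.na(count)) || any(count < 1))
    stop("count must be >= 1 for every protein")
  names(count) <- rownames(values)
  if (!is.null(batch_counts)) {
    batch_counts <- as.matrix(batch_counts)
    storage.mode(batch_counts) <- "integer"
    if (nrow(batch_counts) != nrow(values))
      stop("batch_counts must have one row per protein")
    if (any(is.na(batch_counts)) || any(batch_counts < 1))
      stop("batch_counts must be >= 1 everywhere")
    rownames(batch_counts) <- rownames(values)
  }
  structure(list(values = values, count = count, batch_counts = batch_counts),
            class = "protein_matrix")
}

#' @export
print.protein_matrix <- function(x, ...) {
  cat("protein_matrix:", nrow(x$values), "proteins x",
      ncol(x$values), "samples; counts", min(x$count), "-", max(x$count), "\n")
  invisible(x)
}

#' @export
dim.protein_matrix <- function(x) dim(x$values)

#' Sample-to-group design for a differential expression analysis
#'
#' @param samples character vector of sample ids, in the order the analysis
#'   uses (a matrix analysed with this design must have its columns in the
#'   same order; a mismatch is an error, never a silent reorder).
#' @param groups character vector of group labels, parallel to `samples`.
#' @param batches optional character vector of batch labels per sample.
#' @param reference_samples optional character vector of samples that carry
#'   an internal reference channel (used by [reference_ratio()]).
#' @param contrasts optional list of length-2 character vectors `c(G1, G2)`;
#'   the sign convention everywhere is first group minus second.
#'
#' @return An object of class `design_spec`.
#' @export
design_spec <- function(samples, groups, batches = NULL,
                        reference_samples = NULL, contrasts = NULL) {
  samples <- as.character(samples)
  groups <- as.character(groups)
  if (length(groups) != length(samples))
    stop("groups must be parallel to samples")
  if (anyDuplicated(samples))
    stop("duplicate sample ids in design")
  if (!is.null(batches)) {
    batches <- as.character(batches)
    if (length(batches) != length(samples))
      stop("batches must be parallel to samples")
    names(batches) <- samples
  }
  if (!is.null(reference_samples)) {
    reference_samples <- as.character(reference_samples)
    bad <- setdiff(reference_samples, samples)
    if (length(bad))
      stop("reference samples not in design: ", paste(bad, collapse = ", "))
  }
  names(groups) <- samples
  if (!is.null(contrasts)) {
    contrasts <- lapply(contrasts, as.character)
    for (ct in contrasts) {
      if (length(ct) != 2)
        stop("each contrast must be a pair of group labels")
      bad <- setdiff(ct, groups)
      if (length(bad))
        stop("contrast references unknown group(s): ",
             paste(bad, collapse = ", "))
    }
  }
  structure(list(samples = samples, groups = groups, batches = batches,
                 reference_samples = reference_samples, contrasts = contrasts),
            class = "design_spec")
}

#' @export
print.design_spec <- function(x, ...) {
  cat("design_spec:", length(x$samples), "samples,",
      length(unique(x$groups)), "groups")
  if (!is.null(x$batches)) cat(",", length(unique(x$batches)), "batches")
  if (!is.null(x$reference_samples))
    cat(",", length(x$reference_samples), "reference samples")
  cat("\n")
  invisible(x)
}

#' All pairwise group contrasts
#'
#' Enumerates every unordered pair of distinct group labels, in the order
#' the groups are given (e.g. 18 cell lines yield `choose(18, 2) = 153`
#' comparisons).
#'
#' @param groups character vector of group labels, or a [design_spec()]
#'   (whose distinct groups are taken in order of first appearance).
#' @return A list of length-2 character vectors `c(G1, G2)`.
#' @export
pairwise_contrasts <- function(groups) {
  if (inherits(groups, "design_spec"))
    groups <- unique(unname(groups$groups))
  groups <- as.character(unique(groups))
  k <- length(groups)
  if (k < 2) stop("need at least two groups")
  out <- vector("list", k * (k - 1L) / 2L)
  m <- 0L
  for (i in seq_len(k - 1L)) {
    for (j in seq.int(i + 1L, k)) {
      m <- m + 1L
      out[[m]] <- c(groups[i], groups[j])
    }
  }
  out
}

#' Analysis configuration
#'
#' Bundles the tunable parameters of the empirical-Bayes fit.
#'
#' @param loess_span span of the local regression of log variance on the
#'   covariate, in (0, 1]; default 0.75.
#' @param loess_degree degree of the local polynomial, 1 or 2; default 2.
#' @param d0_grid_step step of the prior-df grid search; default 0.1.
#' @param d0_grid_max cap of the grid search; default 500.
#' @param alpha significance threshold used by diagnostic experiments.
#' @param seed integer seed for generators that take a config.
#' @param count_metric how per-batch PSM counts are unified into one count
#'   per protein: one of `"min"` (default, the recommended metric),
#'   `"mean"`, `"median"`, `"sum"`, `"max"`.
#' @param covariate_mode covariate of the variance trend: `"count"`
#'   (default; log2 PSM/peptide count), `"intensity"` (log2 mean protein
#'   intensity, the limma-trend style fit), or `"constant"` (flat prior,
#'   the classic limma fit).
#'
#' @return An object of class `run_config`.
#' @export
run_config <- function(loess_span = 0.75, loess_degree = 2,
                       d0_grid_step = 0.1, d0_grid_max = 500,
                       alpha = 0.01, seed = 1L,
                       count_metric = c("min", "mean", "median", "sum", "max"),
                       covariate_mode = c("count", "intensity", "constant")) {
  count_metric <- match.arg(count_metric)
  covariate_mode <- match.arg(covariate_mode)
  if (!is.numeric(loess_span) || loess_span <= 0 || loess_span > 1)
    stop("loess_span must be in (0, 1]")
  if (!loess_degree %in% c(1, 2))
    stop("loess_degree must be 1 or 2")
  if (!is.numeric(d0_grid_step) || d0_grid_step <= 0)
    stop("d0_grid_step must be positive")
  if (!is.numeric(d0_grid_max) || d0_grid_max <= 0)
    stop("d0_grid_max must be positive")
  if (!is.numeric(alpha) || alpha <= 0 || alpha >= 1)
    stop("alpha must be in (0, 1)")
  structure(list(loess_span = loess_span, loess_degree = as.integer(loess_degree),
                 d0_grid_step = d0_grid_step, d0_grid_max = d0_grid_max,
                 alpha = alpha, seed = as.integer(seed),
                 count_metric = count_metric, covariate_mode = covariate_mode),
            class = "run_config")
}
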