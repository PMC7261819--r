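#' Read a PSM/peptide-level quantification table
#'
#' Reads a tab-separated table with one row per PSM (or peptide), a feature
#' id column, a protein id column, optional batch column, and one raw
#' intensity column per sample.  Intensity cells holding `0`, `NA` or the
#' empty string are treated as "not observed" and become `NA`; any other
#' non-numeric cell is a parse error reported with its row and column.
#'
#' @param path path to a TSV file with a single header line.
#' @param feature_col,protein_col,batch_col column names; `batch_col` is
#'   optional (`NULL` if the data come from a single run/TMT set).
#' @param intensity_cols character vector naming the sample intensity
#'   columns; if `NULL`, every column other than the id/batch columns is
#'   taken as a sample, in file order.
#' @return A [quant_table()].
#' @export
read_quant_table <- function(path, feature_col = "feature",
                             protein_col = "protein",
                             intensity_cols = NULL, batch_col = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- utils::read.delim(path, colClasses = "character",
                           check.names = FALSE, na.strings = NULL)
  need <- c(feature_col, protein_col, batch_col, intensity_cols)
  missing_cols <- setdiff(need, names(raw))
  if (length(missing_cols))
    stop("missing column(s) in ", path, ": ",
         paste(missing_cols, collapse = ", "))
  if (is.null(intensity_cols))
    intensity_cols <- setdiff(names(raw), c(feature_col, protein_col, batch_col))
  if (!length(intensity_cols))
    stop("no intensity columns found in ", path)
  intens <- matrix(NA_real_, nrow(raw), length(intensity_cols),
                   dimnames = list(NULL, intensity_cols))
  n_missing <- 0L
  for (j in seq_along(intensity_cols)) {
    cell <- raw[[intensity_cols[j]]]
    miss <- is.na(cell) | cell %in% c("", "NA")
    val <- suppressWarnings(as.numeric(cell))
    bad <- which(is.na(val) & !miss)
    if (length(bad))
      stop("non-numeric intensity ", dQuote(cell[bad[1]]), " at row ",
           bad[1], ", column ", dQuote(intensity_cols[j]))
    val[miss | val == 0] <- NA_real_
    n_missing <- n_missing + sum(miss)
    intens[, j] <- val
  }
  if (n_missing > 0)
    message(n_missing, " intensity cell(s) read as missing (NA or empty)")
  quant_table(feature_id = raw[[feature_col]],
              protein_id = raw[[protein_col]],
              intensities = intens,
              sample_ids = intensity_cols,
              batch = if (!is.null(batch_col)) raw[[batch_col]])
}

#' Read a protein log2-ratio matrix
#'
#' Reads a TSV with a protein id column, a count column and one numeric
#' column per sample.  Proteins with any missing value are dropped (the
#' complete-case policy of the downstream models) and reported via a
#' message; duplicate protein ids and counts below 1 are errors.
#'
#' @param path path to a TSV file.
#' @param protein_col,count_col column names.
#' @return A [protein_matrix()].
#' @export
read_protein_matrix <- function(path, protein_col = "protein",
                                count_col = "count") {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- utils::read.delim(path, check.names = FALSE)
  missing_cols <- setdiff(c(protein_col, count_col), names(raw))
  if (length(missing_cols))
    stop("missing column(s) in ", path, ": ",
         paste(missing_cols, collapse = ", "))
  ids <- as.character(raw[[protein_col]])
  dup <- unique(ids[duplicated(ids)])
  if (length(dup))
    stop("duplicate protein id(s): ", paste(dup, collapse = ", "))
  count <- raw[[count_col]]
  if (any(is.na(count)) || any(count < 1))
    stop("count must be >= 1 for every protein")
  sample_cols <- setdiff(names(raw), c(protein_col, count_col))
  vals <- as.matrix(raw[, sample_cols, drop = FALSE])
  storage.mode(vals) <- "double"
  keep <- rowSums(is.na(vals)) == 0
  if (any(!keep))
    message(sum(!keep), " protein(s) dropped for missing values")
  if (!any(keep)) stop("no complete-case proteins in ", path)
  vals <- vals[keep, , drop = FALSE]
  rownames(vals) <- ids[keep]
  protein_matrix(vals, count[keep])
}

#' Write a protein matrix as TSV
#'
#' Inverse of [read_protein_matrix()]: writes columns `protein`, `count`,
#' then one column per sample, preserving row and column order.
#'
#' @param matrix a [protein_matrix()].
#' @param path output path.
#' @export
write_protein_matrix <- function(matrix, path) {
  stopifnot(inherits(matrix, "protein_matrix"))
  df <- data.frame(protein = rownames(matrix$values),
                   count = unname(matrix$count),
                   matrix$values, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a sample design file
#'
#' TSV with columns `sample`, `group`, and optional `batch` and
#' `is_reference` (logical or 0/1).
#'
#' @param path path to the design TSV.
#' @return A [design_spec()].
#' @export
read_design <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- utils::read.delim(path, check.names = FALSE,
                           colClasses = "character")
  missing_cols <- setdiff(c("sample", "group"), names(raw))
  if (length(missing_cols))
    stop("missing column(s) in ", path, ": ",
         paste(missing_cols, collapse = ", "))
  refs <- NULL
  if ("is_reference" %in% names(raw)) {
    flag <- tolower(raw$is_reference) %in% c("1", "true", "yes")
    if (any(flag)) refs <- raw$sample[flag]
  }
  design_spec(samples = raw$sample, groups = raw$group,
              batches = if ("batch" %in% names(raw)) raw$batch,
              reference_samples = refs)
}

#' Read a YAML analysis configuration
#'
#' Unknown keys are rejected; missing keys fall back to the
#' [run_config()] defaults.
#'
#' @param path path to a YAML file.
#' @return A [run_config()].
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  vals <- yaml::read_yaml(path)
  if (is.null(vals)) vals <- list()
  known <- names(formals(run_config))
  bad <- setdiff(names(vals), known)
  if (length(bad))
    stop("unknown config key(s): ", paste(bad, collapse = ", "))
  do.call(run_config, vals)
}

#' Write a differential-expression result table
#'
#' Writes one row per protein.  Fixed column order: `protein`, `count`,
#' then per contrast (suffixed `_<G1.vs.G2>`) the columns `logFC`, `t_ord`
#' (ordinary t), `t_mod` (moderated t), `p`, `p_adj`; then the per-protein
#' variance components `pooled_var`, `prior_var`, `post_var`, and the
#' scalars `df_resid` and `d0` (repeated on every row for convenience).
#'
#' @param fit an [spectra_count_ebayes()] fit.
#' @param path output path.
#' @export
write_results <- function(fit, path) {
  stopifnot(inherits(fit, "ebayes_fit"))
  df <- as.data.frame(fit)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @export
as.data.frame.ebayes_fit <- function(x, ...) {
  df <- data.frame(protein = x$protein_ids, count = unname(x$count),
                   stringsAsFactors = FALSE)
  for (j in seq_along(x$contrasts)) {
    tag <- paste0(x$contrasts[[j]][1], ".vs.", x$contrasts[[j]][2])
    df[[paste0("logFC_", tag)]] <- x$logFC[, j]
    df[[paste0("t_ord_", tag)]] <- x$ord_t[, j]
    df[[paste0("t_mod_", tag)]] <- x$mod_t[, j]
    df[[paste0("p_", tag)]] <- x$p[, j]
    df[[paste0("p_adj_", tag)]] <- x$p_adj[, j]
  }
  df$pooled_var <- unname(x$base$pooled_var)
  df$prior_var <- unname(x$s0_sq)
  df$post_var <- unname(x$post_var)
  df$df_resid <- rep(x$base$df_resid, nrow(df))
  df$d0 <- rep(x$d0, nrow(df))
  df
}
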