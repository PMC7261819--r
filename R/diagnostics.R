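# Diagnostics: how within-group variability relates to quantification
# depth, how well a fitted variance trend explains the observed variances
# (residual sum of squares), and ROC-based benchmarking (partial AUC).

#' Within-group standard deviation profile by PSM count
#'
#' Summarizes the within-group (pooled) standard deviation of protein
#' ratios per PSM/peptide-count bin: counts above `max_count` are merged
#' into the last bin, and each bin is described by the number of proteins
#' and the quartiles of its standard deviations.  This is the boxplot-style
#' diagnostic showing that variability shrinks as quantification depth
#' grows.
#'
#' @param matrix a [protein_matrix()].
#' @param design a [design_spec()] with at least one group of >= 2
#'   replicates.
#' @param max_count largest separate count bin (default 20).
#' @return An object of class `variance_profile`: a list with `profile`
#'   (data.frame: `count_bin`, `n_proteins`, `sd_q25`, `sd_median`,
#'   `sd_q75`) and `max_count`.
#' @export
variance_profile <- function(matrix, design, max_count = 20) {
  fit <- fit_group_means(matrix, design)
  s <- sqrt(fit$pooled_var)
  bin <- pmin(matrix$count, max_count)
  bins <- sort(unique(bin))
  rows <- lapply(bins, function(b) {
    sb <- s[bin == b]
    q <- stats::quantile(sb, c(0.25, 0.5, 0.75), names = FALSE)
    data.frame(count_bin = b, n_proteins = length(sb),
               sd_q25 = q[1], sd_median = q[2], sd_q75 = q[3])
  })
  structure(list(profile = do.call(rbind, rows), max_count = max_count),
            class = "variance_profile")
}

#' @export
print.variance_profile <- function(x, ...) {
  cat("variance_profile over", sum(x$profile$n_proteins), "proteins\n")
  print(x$profile, row.names = FALSE)
  invisible(x)
}

#' Residual sum of squares of a variance-trend fit
#'
#' \eqn{\sum (\log VAR - \mathrm{fitted}(\log VAR))^2} over the proteins
#' that entered the trend fit, in total and per PSM-count bin.  A smaller
#' RSS means the covariate explains the observed variances better; for a
#' flat (constant-covariate) fit the fitted value is the shared prior log
#' variance, so the comparison quantifies the gain of the count-dependent
#' prior.
#'
#' @param trend the `variance_trend` component of an [spectra_count_ebayes()]
#'   fit.
#' @param max_count largest separate count bin for the per-bin breakdown.
#' @return A list with `rss_total` and `rss_per_bin` (data.frame:
#'   `count_bin`, `n_proteins`, `rss`); the per-bin values sum exactly to
#'   the total.
#' @export
rss_of_fit <- function(trend, max_count = 20) {
  stopifnot(inherits(trend, "variance_trend"))
  ok <- trend$ok
  r2 <- (trend$logVAR[ok] - trend$fitted_logVAR[ok])^2
  bin <- pmin(trend$count[ok], max_count)
  bins <- sort(unique(bin))
  per <- data.frame(
    count_bin = bins,
    n_proteins = vapply(bins, function(b) sum(bin == b), 0L),
    rss = vapply(bins, function(b) sum(r2[bin == b]), 0))
  list(rss_total = sum(r2), rss_per_bin = per)
}

#' Total trend RSS for each count-unification metric
#'
#' For matrices assembled from several TMT batches, refits the variance
#' trend once per candidate count metric (see [combine_counts()]) and
#' returns each metric's total residual sum of squares, plus the flat
#' (constant-covariate) RSS as a baseline.  The metric with the smallest
#' RSS explains the observed protein variances best.
#'
#' @param matrix a [protein_matrix()] with `batch_counts`.
#' @param design a [design_spec()].
#' @param metrics metrics to compare.
#' @param config a [run_config()]; its `covariate_mode` is ignored (count
#'   mode is forced for the metrics, constant mode for the baseline).
#' @return Named numeric vector of total RSS per metric, with an extra
#'   `"constant"` entry for the flat fit.
#' @export
count_metric_rss <- function(matrix, design,
                             metrics = c("min", "mean", "median", "sum", "max"),
                             config = run_config()) {
  stopifnot(inherits(matrix, "protein_matrix"))
  if (is.null(matrix$batch_counts))
    stop("matrix carries no per-batch counts")
  fit <- fit_group_means(matrix, design)
  out <- numeric(0)
  for (m in metrics) {
    cm <- protein_matrix(matrix$values,
                         combine_counts(matrix$batch_counts, m))
    cfg <- config; cfg$covariate_mode <- "count"
    eb <- spectra_count_ebayes(fit, cm, contrasts = list(), config = cfg)
    out[m] <- rss_of_fit(eb$trend)$rss_total
  }
  cfg <- config; cfg$covariate_mode <- "constant"
  eb <- spectra_count_ebayes(fit, matrix, contrasts = list(), config = cfg)
  out["constant"] <- rss_of_fit(eb$trend)$rss_total
  out
}

#' Partial area under the ROC curve at high specificity
#'
#' Sweeps thresholds over the scores in descending order (tied scores form
#' a single threshold step, giving one ROC vertex per distinct score),
#' restricts the curve to specificity above `spec_floor` (interpolating
#' linearly at the boundary) and integrates by the trapezoid rule.  The
#' area is normalized by its maximum attainable value in that range,
#' `1 - spec_floor`, and returned as a percentage, so a perfect ranking
#' scores 100 and an uninformative one about 50.
#'
#' @param scores numeric vector (larger = more confidently positive),
#'   e.g. absolute moderated t statistics.
#' @param labels logical or 0/1 vector of ground truth, parallel to
#'   `scores`; both classes must be present.
#' @param spec_floor lower specificity bound, in (0, 1); default 0.95.
#' @return The partial AUC as a percentage of its maximum.
#' @export
pauc <- function(scores, labels, spec_floor = 0.95) {
  labels <- as.logical(labels)
  if (length(scores) != length(labels))
    stop("scores and labels must be parallel")
  if (!any(labels) || all(labels))
    stop("both classes must be present")
  if (spec_floor <= 0 || spec_floor >= 1)
    stop("spec_floor must be in (0, 1)")
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]
  l <- labels[ord]
  ends <- c(which(diff(s) != 0), length(s))   # one vertex per distinct score
  tpr <- c(0, cumsum(l)[ends] / sum(l))
  fpr <- c(0, cumsum(!l)[ends] / sum(!l))
  fmax <- 1 - spec_floor
  area <- 0
  for (i in seq_len(length(fpr) - 1)) {
    f0 <- fpr[i]; f1 <- fpr[i + 1]
    if (f0 >= fmax) break
    t0 <- tpr[i]; t1 <- tpr[i + 1]
    if (f1 > fmax) {        # clip the last segment at the boundary
      t1 <- t0 + (t1 - t0) * (fmax - f0) / (f1 - f0)
      f1 <- fmax
    }
    area <- area + (f1 - f0) * (t0 + t1) / 2
  }
  100 * area / fmax
}
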