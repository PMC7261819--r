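# Synthetic-data generators: a parametric count->variance law, a null
# proteomics matrix with count-dependent variance, split enumeration for
# null (permutation) comparisons, a spike-in quantification-table
# generator, and a multi-batch (multi-TMT) matrix generator.  All
# generators are deterministic under their seed.

#' Parametric count-to-variance law
#'
#' Returns the function \eqn{v(c) = v_\infty + a \, c^{-b}}: a monotone
#' decreasing variance with a floor, the shape observed when protein
#' log-ratio variability shrinks with the number of PSMs used for
#' quantification.  The defaults (floor 0.02, amplitude 0.20, exponent
#' 0.8) give single-PSM log2-ratio standard deviations near 0.47 falling
#' to about 0.17 at 30 PSMs, magnitudes typical of deep TMT cell-line
#' data.
#'
#' @param v_inf asymptotic variance floor.
#' @param a amplitude of the count-dependent part.
#' @param b decay exponent.
#' @return A function mapping counts to variances.
#' @export
make_variance_fn <- function(v_inf = 0.02, a = 0.20, b = 0.8) {
  if (v_inf <= 0 || a < 0 || b <= 0)
    stop("variance law requires v_inf > 0, a >= 0, b > 0")
  function(count) v_inf + a * count^(-b)
}

#' Specification of a simulated proteomics experiment
#'
#' The defaults reproduce the null-simulation design used to study false
#' positive rates: 6000 proteins over 9 samples, split into 30 equal
#' groups quantified by 1-30 PSMs respectively, with the per-group
#' variance given by a fitted count-to-variance curve and all means
#' centred at 0.
#'
#' @param n_proteins total number of proteins.
#' @param n_samples number of samples.
#' @param count_groups data.frame with columns `psm_count` and
#'   `n_proteins`; group sizes must sum to `n_proteins`.  Default: 30
#'   groups with counts 1-30 and equal sizes.
#' @param variance_fn function mapping a PSM count to the true variance;
#'   see [make_variance_fn()].
#' @param fraction_de fraction of truly differentially expressed proteins
#'   (0 for a null data set).
#' @param log2fc log2 fold change applied to DE proteins.
#' @param affected_samples sample indices receiving the shift; default:
#'   the second half of the samples.
#' @param seed integer seed.
#' @return An object of class `sim_spec`.
#' @export
sim_spec <- function(n_proteins = 6000, n_samples = 9, count_groups = NULL,
                     variance_fn = make_variance_fn(), fraction_de = 0,
                     log2fc = 1, affected_samples = NULL, seed = 1L) {
  if (is.null(count_groups)) {
    sizes <- rep(n_proteins %/% 30L, 30L)
    sizes[seq_len(n_proteins - sum(sizes))] <-
      sizes[seq_len(n_proteins - sum(sizes))] + 1L
    count_groups <- data.frame(psm_count = 1:30, n_proteins = sizes)
  }
  if (!all(c("psm_count", "n_proteins") %in% names(count_groups)))
    stop("count_groups needs columns psm_count and n_proteins")
  if (sum(count_groups$n_proteins) != n_proteins)
    stop("count-group sizes must sum to n_proteins")
  if (any(count_groups$psm_count < 1))
    stop("psm_count must be >= 1")
  if (any(variance_fn(count_groups$psm_count) <= 0))
    stop("variance_fn must be positive over the used counts")
  if (fraction_de < 0 || fraction_de > 1)
    stop("fraction_de must lie in [0, 1]")
  if (is.null(affected_samples))
    affected_samples <- seq.int(n_samples %/% 2 + 1L, n_samples)
  structure(list(n_proteins = as.integer(n_proteins),
                 n_samples = as.integer(n_samples),
                 count_groups = count_groups, variance_fn = variance_fn,
                 fraction_de = fraction_de, log2fc = log2fc,
                 affected_samples = as.integer(affected_samples),
                 seed = as.integer(seed)),
            class = "sim_spec")
}

#' Simulate a null protein matrix with count-dependent variance
#'
#' Draws every protein's log2 ratios i.i.d. Normal(0, v(count)) where the
#' count is assigned by the spec's count groups: no protein is
#' differentially expressed, but low-count proteins are noisier, exactly
#' the structure the count-dependent prior is meant to capture.
#'
#' @param spec a [sim_spec()] with `fraction_de = 0`.
#' @return A list with `matrix` (a [protein_matrix()]) and `truth`
#'   (data.frame: `protein_id`, `is_de`, `true_log2fc`, `psm_count`).
#' @export
simulate_null <- function(spec = sim_spec()) {
  stopifnot(inherits(spec, "sim_spec"))
  if (spec$fraction_de != 0)
    stop("simulate_null requires fraction_de = 0")
  set.seed(spec$seed)
  counts <- rep(spec$count_groups$psm_count, spec$count_groups$n_proteins)
  sds <- sqrt(spec$variance_fn(counts))
  y <- matrix(stats::rnorm(spec$n_proteins * spec$n_samples),
              spec$n_proteins, spec$n_samples) * sds
  rownames(y) <- sprintf("protein%04d", seq_len(spec$n_proteins))
  colnames(y) <- sprintf("sample%d", seq_len(spec$n_samples))
  pm <- protein_matrix(y, counts)
  truth <- data.frame(protein_id = rownames(y), is_de = FALSE,
                      true_log2fc = 0, psm_count = counts,
                      stringsAsFactors = FALSE)
  list(matrix = pm, truth = truth)
}

#' Enumerate two-group null comparisons
#'
#' Deterministically enumerates comparisons of two disjoint groups of
#' `group_size` samples each.  Under the default `"anchored"` scheme, each
#' of the `choose(n, group_size)` choices of the first group is one
#' comparison, with the second group taken as the lexicographically
#' smallest `group_size`-subset of the remaining samples: 9 samples with
#' triples give 84 comparisons.  The `"all-disjoint"` scheme instead
#' enumerates every unordered pair of disjoint subsets.
#'
#' @param sample_ids character vector of sample ids.
#' @param group_size samples per group.
#' @param scheme `"anchored"` (default) or `"all-disjoint"`.
#' @return A list of lists with elements `a` and `b` (character vectors of
#'   sample ids), ordered lexicographically by the first group.
#' @export
enumerate_null_splits <- function(sample_ids, group_size,
                                  scheme = c("anchored", "all-disjoint")) {
  scheme <- match.arg(scheme)
  sample_ids <- as.character(sample_ids)
  n <- length(sample_ids)
  if (2 * group_size > n)
    stop("group_size too large: need at least ", 2 * group_size, " samples")
  cmb <- utils::combn(n, group_size)
  if (scheme == "anchored") {
    return(lapply(seq_len(ncol(cmb)), function(j) {
      a <- cmb[, j]
      b <- setdiff(seq_len(n), a)[seq_len(group_size)]
      list(a = sample_ids[a], b = sample_ids[b])
    }))
  }
  out <- list()
  for (i in seq_len(ncol(cmb) - 1)) {
    for (j in seq.int(i + 1, ncol(cmb))) {
      if (!length(intersect(cmb[, i], cmb[, j])))
        out[[length(out) + 1L]] <- list(a = sample_ids[cmb[, i]],
                                        b = sample_ids[cmb[, j]])
    }
  }
  out
}

#' Null false-positive-rate experiment
#'
#' Runs the ordinary t-test, the flat-prior (constant covariate) moderated
#' test and the count-covariate moderated test on every enumerated null
#' split of a null matrix, and reports each method's false positive rate:
#' the fraction of (protein, split) tests with p below `alpha`, plus the
#' fraction with Benjamini-Hochberg adjusted p below `alpha`.
#'
#' @param matrix a null [protein_matrix()] (e.g. from [simulate_null()]).
#' @param alpha significance threshold (default 0.01).
#' @param group_size samples per group in each split (default 3).
#' @param n_splits optionally use only the first `n_splits` splits.
#' @param config a [run_config()].
#' @return A data.frame with columns `method` (`"ordinary_t"`,
#'   `"ebayes_constant"`, `"ebayes_count"`), `fpr`, `fpr_adj`, `n_tests`.
#' @export
null_fpr_experiment <- function(matrix, alpha = 0.01, group_size = 3,
                                n_splits = NULL, config = run_config()) {
  stopifnot(inherits(matrix, "protein_matrix"))
  splits <- enumerate_null_splits(colnames(matrix$values), group_size)
  if (!is.null(n_splits))
    splits <- splits[seq_len(min(n_splits, length(splits)))]
  methods <- c("ordinary_t", "ebayes_constant", "ebayes_count")
  hits <- hits_adj <- stats::setNames(numeric(3), methods)
  n_tests <- 0L
  cfg_const <- config; cfg_const$covariate_mode <- "constant"
  cfg_count <- config; cfg_count$covariate_mode <- "count"
  for (sp in splits) {
    cols <- c(sp$a, sp$b)
    sub <- protein_matrix(matrix$values[, cols, drop = FALSE], matrix$count)
    des <- design_spec(cols, rep(c("A", "B"), c(length(sp$a), length(sp$b))))
    lf <- fit_group_means(sub, des)
    ct <- list(c("A", "B"))
    tt <- ordinary_t(lf, c("A", "B"))
    ebc <- spectra_count_ebayes(lf, sub, contrasts = ct, config = cfg_const)
    ebn <- spectra_count_ebayes(lf, sub, contrasts = ct, config = cfg_count)
    ps <- list(ordinary_t = tt$p, ebayes_constant = ebc$p[, 1],
               ebayes_count = ebn$p[, 1])
    pa <- list(ordinary_t = bh_adjust(tt$p), ebayes_constant = ebc$p_adj[, 1],
               ebayes_count = ebn$p_adj[, 1])
    for (m in methods) {
      hits[m] <- hits[m] + sum(ps[[m]] < alpha)
      hits_adj[m] <- hits_adj[m] + sum(pa[[m]] < alpha)
    }
    n_tests <- n_tests + nrow(sub$values)
  }
  data.frame(method = methods, fpr = unname(hits) / n_tests,
             fpr_adj = unname(hits_adj) / n_tests, n_tests = n_tests,
             stringsAsFactors = FALSE)
}

.rtrunc_geom <- function(n, prob, max) {
  pmin(1L + stats::rgeom(n, prob), max)
}

#' Simulate a spike-in quantification experiment
#'
#' Emulates a spike-in benchmark: a constant background proteome plus a
#' set of spike proteins shifted by `log2(ratio)` in the second condition,
#' measured at the PSM/peptide level.  Each protein gets a PSM count from
#' a truncated geometric distribution on 1..`max_count`; each PSM row has
#' its own ionization-efficiency offset and per-sample lognormal noise
#' whose log2-scale standard deviation is \eqn{\sqrt{c \, v(c)}}, so that
#' after median aggregation the protein-level within-group variance
#' decreases with count on the scale of `variance_fn`.
#'
#' @param type `"labeled"` (PSM rows, TMT-style) or `"label-free"`
#'   (peptide rows); the generated structure is identical, the label
#'   records which counting unit the rows represent.
#' @param n_background,n_spike numbers of background and spike proteins.
#' @param ratio linear spike ratio between conditions (> 0).
#' @param replicates integer pair: replicates in conditions A and B.
#' @param variance_fn count-to-variance law, see [make_variance_fn()].
#' @param seed integer seed.
#' @param max_count cap of the PSM-count distribution.
#' @param count_prob geometric success probability of the count
#'   distribution (smaller = deeper coverage).
#' @return A list with `quant` (a [quant_table()]), `design` (a
#'   [design_spec()] with groups `"A"` and `"B"`) and `truth` (data.frame:
#'   `protein_id`, `is_de`, `true_log2fc`, `psm_count`).
#' @export
simulate_spikein <- function(type = c("labeled", "label-free"),
                             n_background = 3000, n_spike = 600, ratio = 3,
                             replicates = c(3, 3),
                             variance_fn = make_variance_fn(), seed = 1L,
                             max_count = 30, count_prob = 0.25) {
  type <- match.arg(type)
  if (ratio <= 0) stop("ratio must be positive")
  if (length(replicates) != 2 || any(replicates < 2))
    stop("need at least 2 replicates per condition")
  set.seed(seed)
  n_prot <- n_background + n_spike
  prot_ids <- sprintf("protein%05d", seq_len(n_prot))
  is_de <- c(rep(FALSE, n_background), rep(TRUE, n_spike))
  counts <- .rtrunc_geom(n_prot, count_prob, max_count)
  n_samples <- sum(replicates)
  sample_ids <- c(sprintf("A%d", seq_len(replicates[1])),
                  sprintf("B%d", seq_len(replicates[2])))
  cond_b <- rep(c(FALSE, TRUE), replicates)
  base_l2 <- stats::rnorm(n_prot, mean = 20, sd = 2)  # log2 abundance
  row_protein <- rep.int(seq_len(n_prot), counts)
  n_rows <- length(row_protein)
  row_offset <- stats::rnorm(n_rows, 0, 1)            # per-PSM efficiency
  row_sd <- sqrt(counts[row_protein] * variance_fn(counts[row_protein]))
  shift <- outer(is_de[row_protein], cond_b) * log2(ratio)
  noise <- matrix(stats::rnorm(n_rows * n_samples), n_rows, n_samples) * row_sd
  l2 <- base_l2[row_protein] + row_offset + shift + noise
  intens <- 2^l2
  colnames(intens) <- sample_ids
  quant <- quant_table(
    feature_id = sprintf("%s_%s%d", prot_ids[row_protein],
                         if (type == "labeled") "psm" else "pep",
                         stats::ave(row_protein, row_protein,
                                    FUN = seq_along)),
    protein_id = prot_ids[row_protein],
    intensities = intens, sample_ids = sample_ids)
  design <- design_spec(sample_ids, rep(c("A", "B"), replicates))
  truth <- data.frame(protein_id = prot_ids, is_de = is_de,
                      true_log2fc = ifelse(is_de, log2(ratio), 0),
                      psm_count = counts, stringsAsFactors = FALSE)
  list(quant = quant, design = design, truth = truth)
}

#' Simulate a multi-batch (multi-TMT) protein matrix
#'
#' Emulates a deep multi-TMT design in which each group's replicates are
#' spread across batches: there are `n_batches * n_groups` samples, one
#' replicate of each group per batch, and a protein's quantification error
#' in a sample is governed by its PSM count in that sample's batch.
#' Counts share a per-protein base across batches (deep coverage,
#' `4 + Geom(0.10)` capped at `max_count`) with lognormal batch-to-batch
#' jitter, and with probability `p_weak` one batch drops to a weak count
#' of 1-3 PSMs -- the "weakest experiment" phenomenon that makes the
#' minimum count the informative summary.
#'
#' @param n_proteins number of proteins.
#' @param n_batches number of TMT batches (default 3).
#' @param n_groups number of sample groups (default 9); each group has one
#'   replicate per batch.
#' @param variance_fn count-to-variance law.
#' @param p_weak probability that a protein has one weak batch.
#' @param max_count count cap.
#' @param seed integer seed.
#' @return A list with `matrix` (a [protein_matrix()] whose `batch_counts`
#'   holds the per-batch counts and whose `count` is the minimum) and
#'   `design` (a [design_spec()] with groups `G1..Gm` and batch labels).
#' @export
simulate_multibatch <- function(n_proteins = 2000, n_batches = 3,
                                n_groups = 9,
                                variance_fn = make_variance_fn(),
                                p_weak = 0.4, max_count = 30, seed = 1L) {
  set.seed(seed)
  base <- pmin(4L + stats::rgeom(n_proteins, 0.10), max_count)
  cnt <- matrix(rep(base, n_batches), n_proteins, n_batches)
  jitter <- matrix(exp(stats::rnorm(n_proteins * n_batches, 0, 0.2)),
                   n_proteins, n_batches)
  cnt <- pmax(round(cnt * jitter), 1)
  cnt <- pmin(cnt, max_count)
  weak <- stats::runif(n_proteins) < p_weak
  wb <- sample.int(n_batches, n_proteins, replace = TRUE)
  wv <- sample.int(3L, n_proteins, replace = TRUE)
  sel <- cbind(which(weak), wb[weak])
  cnt[sel] <- pmin(wv[weak], cnt[sel])
  colnames(cnt) <- sprintf("batch%d", seq_len(n_batches))
  n_samples <- n_batches * n_groups
  bat <- rep(seq_len(n_batches), each = n_groups)
  grp <- rep(seq_len(n_groups), times = n_batches)
  sample_ids <- sprintf("b%dg%d", bat, grp)
  y <- matrix(NA_real_, n_proteins, n_samples,
              dimnames = list(sprintf("protein%04d", seq_len(n_proteins)),
                              sample_ids))
  for (j in seq_len(n_samples))
    y[, j] <- stats::rnorm(n_proteins, 0, sqrt(variance_fn(cnt[, bat[j]])))
  rownames(cnt) <- rownames(y)
  pm <- protein_matrix(y, combine_counts(cnt, "min"), batch_counts = cnt)
  design <- design_spec(sample_ids, sprintf("G%d", grp),
                        batches = sprintf("batch%d", bat))
  list(matrix = pm, design = design)
}
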