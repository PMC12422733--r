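#' Pearson correlation coefficient
#'
#' Thin wrapper over [stats::cor()] with the domain checks used throughout
#' the correlation layer: at least three paired observations and nonzero
#' variance in both vectors.
#'
#' @param x,y Numeric vectors of equal length (>= 3).
#' @return The sample Pearson correlation.
#' @examples
#' pearson_r(c(1, 2, 3, 4), c(1, 3, 2, 4)) # 0.8
#' @export
pearson_r <- function(x, y) {
  if (length(x) != length(y)) abort("x and y must have equal length")
  if (length(x) < 3) abort("need at least 3 observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    abort("undefined correlation: zero variance")
  }
  cor(x, y)
}

#' Two-sided p-value for a Pearson correlation
#'
#' Uses the exact t transform `t = r * sqrt((n - 2) / (1 - r^2))` with
#' `n - 2` degrees of freedom; `|r| = 1` returns 0.
#'
#' @param r Correlation coefficient(s) in `[-1, 1]`.
#' @param n Sample size(s), >= 3.
#' @return Two-sided p-value(s).
#' @export
correlation_p <- function(r, n) {
  if (any(n < 3)) abort("n must be >= 3")
  if (any(abs(r) > 1 + 1e-12)) abort("|r| must be <= 1")
  r <- pmin(pmax(r, -1), 1)
  p <- ifelse(
    abs(r) == 1, 0,
    2 * pt(-abs(r * sqrt((n - 2) / (1 - r^2))), df = n - 2)
  )
  pmin(p, 1)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment (via [stats::p.adjust()]),
#' validated for the `[0, 1]` domain.
#'
#' @param p Vector of p-values in `[0, 1]`.
#' @return Adjusted p-values, capped at 1.
#' @export
bh_adjust <- function(p) {
  if (any(is.na(p)) || any(p < 0) || any(p > 1)) {
    abort("p-values must be in [0, 1]")
  }
  p.adjust(p, method = "BH")
}

presence_filter <- function(mat, ids, presence_frac, label) {
  ids <- intersect(ids, rownames(mat))
  keep <- ids[rowMeans(mat[ids, , drop = FALSE] > 0) >= presence_frac]
  dropped <- setdiff(ids, keep)
  if (length(dropped) > 0) {
    inform(sprintf("presence filter dropped %d %s feature(s)",
                   length(dropped), label))
  }
  keep
}

#' All-pairs gene-by-TE correlation within a sample group
#'
#' Computes Pearson correlations between every (gene, TE) pair on the
#' selected samples, derives two-sided p-values from the t transform, and
#' adjusts them with Benjamini-Hochberg jointly across *all* pairs of the
#' group (positives and negatives pooled; one family per group). A pair is
#' `significant` when `padj < cor_alpha` and `|r| > min_abs_r`. Features are
#' first required to be expressed (count > 0) in at least `presence_frac`
#' of the selected samples; zero-variance features are dropped with a
#' message. Output is deterministic given the inputs.
#'
#' @param x A [te_counts] object or numeric expression matrix (normalized).
#' @param genes,tes Character vectors of feature ids (disjoint).
#' @param samples Sample ids to use; default all columns.
#' @param group Label stored in the output records; default "all".
#' @param min_abs_r,cor_alpha,presence_frac Thresholds, see
#'   [analysis_config()].
#' @return A tibble of correlation records: `gene_id`, `te_id`, `r`, `n`,
#'   `p`, `padj`, `group`, `significant`.
#' @export
correlate_all <- function(x, genes, tes, samples = NULL, group = "all",
                          min_abs_r = 0.4, cor_alpha = 0.01,
                          presence_frac = 0.8) {
  mat <- count_matrix_of(x)
  samples <- samples %||% colnames(mat)
  if (length(samples) < 3) abort("need at least 3 samples")
  if (length(genes) == 0 || length(tes) == 0) {
    abort("genes and tes must be nonempty")
  }
  if (length(intersect(genes, tes)) > 0) {
    abort("genes and tes must be disjoint id sets")
  }
  mat <- mat[, samples, drop = FALSE]
  genes <- presence_filter(mat, genes, presence_frac, "gene")
  tes <- presence_filter(mat, tes, presence_frac, "TE")
  drop_constant <- function(ids, label) {
    keep <- ids[matrixStats_rowVars(mat[ids, , drop = FALSE]) > 0]
    if (length(keep) < length(ids)) {
      warn(sprintf("dropping %d constant %s feature(s)",
                   length(ids) - length(keep), label))
    }
    keep
  }
  genes <- drop_constant(genes, "gene")
  tes <- drop_constant(tes, "TE")
  if (length(genes) == 0 || length(tes) == 0) {
    return(tibble(gene_id = character(), te_id = character(),
                  r = numeric(), n = integer(), p = numeric(),
                  padj = numeric(), group = character(),
                  significant = logical()))
  }
  n <- length(samples)
  rmat <- cor(t(mat[genes, , drop = FALSE]), t(mat[tes, , drop = FALSE]))
  rec <- tibble(
    gene_id = rep(genes, times = length(tes)),
    te_id = rep(tes, each = length(genes)),
    r = as.vector(rmat),
    n = n
  )
  rec$p <- correlation_p(rec$r, rec$n)
  rec$padj <- bh_adjust(rec$p)
  rec$group <- group
  rec$significant <- rec$padj < cor_alpha & abs(rec$r) > min_abs_r
  rec
}

# rowVars without a matrixStats dependency
matrixStats_rowVars <- function(m) {
  if (nrow(m) == 0) return(numeric(0))
  apply(m, 1, var)
}

#' Leave-one-out consensus correlations
#'
#' Repeats [correlate_all()] once per individual, each time excluding all of
#' that individual's samples, and keeps only the pairs that are significant
#' with the same sign of `r` in *every* leave-one-out subset. Reported `r`,
#' `p`, `padj` come from the full-sample run. Used when one species has
#' more biological replicates than the others, so that no single individual
#' can drive a reported correlation.
#'
#' @inheritParams correlate_all
#' @param individuals Character vector naming the individuals to leave out;
#'   default all individuals in the metadata of `x` (restricted to
#'   `samples`). Requires a [te_counts] input unless both `samples` and
#'   `sample_individuals` are given.
#' @param sample_individuals Optional named character vector mapping sample
#'   id to individual, overriding the metadata.
#' @return A tibble of full-sample correlation records restricted to the
#'   consensus pairs.
#' @export
leave_one_out_consensus <- function(x, genes, tes, samples = NULL,
                                    group = "all", individuals = NULL,
                                    sample_individuals = NULL,
                                    min_abs_r = 0.4, cor_alpha = 0.01,
                                    presence_frac = 0.8) {
  mat <- count_matrix_of(x)
  samples <- samples %||% colnames(mat)
  if (is.null(sample_individuals)) {
    if (!inherits(x, "te_counts")) {
      abort("need a te_counts object or an explicit sample_individuals map")
    }
    sample_individuals <- setNames(x$meta$individual, x$meta$sample_id)
  }
  sample_individuals <- sample_individuals[samples]
  if (any(is.na(sample_individuals))) {
    abort("every sample needs an individual assignment")
  }
  individuals <- individuals %||% unique(unname(sample_individuals))
  if (length(individuals) < 3) abort("need at least 3 individuals")

  full <- correlate_all(x, genes, tes, samples, group,
                        min_abs_r, cor_alpha, presence_frac)
  key <- function(d) paste(d$gene_id, d$te_id, sep = "\r")
  consensus <- NULL
  for (ind in individuals) {
    sub <- samples[sample_individuals != ind]
    if (length(sub) < 3) {
      abort(sprintf("leave-one-out subset without '%s' has < 3 samples", ind))
    }
    rec <- correlate_all(x, genes, tes, sub, group,
                         min_abs_r, cor_alpha, presence_frac)
    sig <- rec[rec$significant, , drop = FALSE]
    signed <- paste(key(sig), sign(sig$r))
    consensus <- if (is.null(consensus)) signed else intersect(consensus, signed)
  }
  keep <- paste(key(full), sign(full$r)) %in% consensus
  full[keep, , drop = FALSE]
}

#' Extract the significant pairs of a record table
#'
#' @param records Correlation records ([correlate_all()] layout).
#' @return Tibble with columns `gene_id`, `te_id` of significant pairs.
#' @export
significant_pairs <- function(records) {
  distinct(select(filter(records, .data$significant), "gene_id", "te_id"))
}

#' Correlation-strength overview plot
#'
#' Histogram of coefficients with the significance band marked, one facet
#' per group.
#'
#' @param records Correlation records.
#' @param min_abs_r Significance band half-width to draw. Default 0.4.
#' @return A ggplot object.
#' @export
plot_correlations <- function(records, min_abs_r = 0.4) {
  ggplot2::ggplot(records, ggplot2::aes(x = .data$r,
                                        fill = .data$significant)) +
    ggplot2::geom_histogram(bins = 60, boundary = 0) +
    ggplot2::geom_vline(xintercept = c(-1, 1) * min_abs_r, linetype = 2) +
    ggplot2::facet_wrap(~group) +
    ggplot2::scale_fill_manual(values = c(`FALSE` = "grey70",
                                          `TRUE` = "firebrick")) +
    ggplot2::labs(x = "Pearson r", y = "pairs")
}
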