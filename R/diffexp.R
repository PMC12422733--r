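#' Differential expression between two sample groups
#'
#' A compact negative-binomial Wald test for two-group contrasts of gene or
#' TE counts. Library-depth differences are removed with median-of-ratios
#' size factors; per-feature dispersions are estimated by method of moments
#' (floored at 1e-8) and shrunk 50% (on the log scale) toward a mean-
#' dispersion trend; the Wald statistic tests the log2 fold change of group
#' B over group A. P-values are Benjamini-Hochberg adjusted across all
#' tested features of this contrast. A feature is called `up` when
#' `log2fc >= lfc_threshold` and `padj < alpha`, `down` symmetrically, and
#' `ns` otherwise. Cross-species contrasts conventionally use
#' `lfc_threshold = 1.5`; within-species condition contrasts (where effects
#' are weaker) 0.5.
#'
#' @param x A [te_counts] object or count matrix (raw or scaled).
#' @param group_a,group_b Disjoint character vectors of sample ids, at least
#'   two samples each. Fold changes are reported as B over A.
#' @param lfc_threshold Absolute log2 fold-change call threshold.
#' @param alpha Adjusted-p call threshold.
#' @return A tibble with one row per tested feature: `feature_id`,
#'   `base_mean`, `log2fc`, `se`, `stat`, `p`, `padj`, `status`.
#' @examples
#' sim <- simulate_dataset(sim_spec(n_genes = 40, n_tes = 10, seed = 1))
#' x <- sim$counts$human
#' ids <- split(x$meta$sample_id, x$meta$group)
#' de <- differential_expression(x, ids[[1]], ids[[2]])
#' table(de$status)
#' @export
differential_expression <- function(x, group_a, group_b,
                                    lfc_threshold = 1.5, alpha = 0.05) {
  mat <- count_matrix_of(x)
  if (length(intersect(group_a, group_b)) > 0) {
    abort("groups must be disjoint")
  }
  if (length(group_a) < 2 || length(group_b) < 2) {
    abort("each group needs at least 2 samples")
  }
  missing_s <- setdiff(c(group_a, group_b), colnames(mat))
  if (length(missing_s) > 0) {
    abort(sprintf("unknown sample id(s): %s",
                  paste(missing_s, collapse = ", ")))
  }
  sel <- mat[, c(group_a, group_b), drop = FALSE]
  all_zero <- rowSums(sel) == 0
  if (any(all_zero)) {
    inform(sprintf("excluding %d feature(s) with all-zero counts",
                   sum(all_zero)))
    sel <- sel[!all_zero, , drop = FALSE]
  }
  if (nrow(sel) == 0) abort("no features with nonzero counts")

  sf <- size_factors(sel)
  k <- sweep(sel, 2, sf, "/")
  ka <- k[, group_a, drop = FALSE]
  kb <- k[, group_b, drop = FALSE]
  mu_a <- rowMeans(ka)
  mu_b <- rowMeans(kb)
  mu_all <- rowMeans(k)

  # method-of-moments dispersion from the pooled within-group variance
  n_a <- length(group_a); n_b <- length(group_b)
  var_w <- (apply(ka, 1, var) * (n_a - 1) + apply(kb, 1, var) * (n_b - 1)) /
    (n_a + n_b - 2)
  disp_raw <- pmax((var_w - mu_all) / mu_all^2, 1e-8)
  disp <- shrink_dispersion(disp_raw, mu_all)

  pseudo <- ifelse(mu_a == 0 | mu_b == 0, 0.5, 0)
  log2fc <- log2((mu_b + pseudo) / (mu_a + pseudo))

  var_mean <- function(mu, ids, n, ps) {
    (sum(1 / sf[ids]) * (mu + ps) / n^2) + (mu + ps)^2 * disp / n
  }
  v_a <- var_mean(mu_a, group_a, n_a, pseudo)
  v_b <- var_mean(mu_b, group_b, n_b, pseudo)
  se <- sqrt(v_a / (mu_a + pseudo)^2 + v_b / (mu_b + pseudo)^2) / log(2)
  stat <- ifelse(se > 0, log2fc / se, 0)
  p <- 2 * pnorm(-abs(stat))
  padj <- p.adjust(p, method = "BH")
  status <- dplyr::case_when(
    log2fc >= lfc_threshold & padj < alpha ~ "up",
    log2fc <= -lfc_threshold & padj < alpha ~ "down",
    TRUE ~ "ns"
  )
  tibble(
    feature_id = rownames(sel), base_mean = unname(mu_all),
    log2fc = unname(log2fc), se = unname(se), stat = unname(stat),
    p = unname(p), padj = unname(padj),
    status = factor(unname(status), levels = c("down", "ns", "up"))
  )
}

# DESeq-style median-of-ratios size factors over features with all-positive
# counts; falls back to column-sum ratios when none exist.
size_factors <- function(mat) {
  pos <- rowSums(mat > 0) == ncol(mat)
  if (sum(pos) >= 1) {
    logs <- log(mat[pos, , drop = FALSE])
    log_gm <- rowMeans(logs)
    sf <- exp(apply(logs - log_gm, 2, median))
  } else {
    cs <- colSums(mat)
    sf <- cs / exp(mean(log(cs)))
  }
  sf / exp(mean(log(sf)))
}

# 50% shrinkage (log scale) toward a log-linear mean-dispersion trend.
shrink_dispersion <- function(disp, mu) {
  usable <- mu > 0 & disp > 1e-8
  if (sum(usable) >= 3 && length(unique(mu[usable])) >= 2) {
    fit <- stats::lm(log(disp[usable]) ~ log(mu[usable]))
    trend <- exp(cbind(1, log(pmax(mu, 1e-8))) %*% stats::coef(fit))[, 1]
  } else {
    trend <- rep(exp(mean(log(disp))), length(disp))
  }
  pmax(exp(0.5 * log(disp) + 0.5 * log(pmax(trend, 1e-8))), 1e-8)
}

#' Volcano plot of a differential-expression result
#'
#' @param de Tibble from [differential_expression()].
#' @param lfc_threshold,alpha Thresholds to draw as guide lines; defaults
#'   match [differential_expression()].
#' @return A ggplot object.
#' @export
plot_volcano <- function(de, lfc_threshold = 1.5, alpha = 0.05) {
  ggplot2::ggplot(de, ggplot2::aes(x = .data$log2fc,
                                   y = -log10(pmax(.data$padj, 1e-300)),
                                   colour = .data$status)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::geom_vline(xintercept = c(-1, 1) * lfc_threshold, linetype = 2) +
    ggplot2::geom_hline(yintercept = -log10(alpha), linetype = 2) +
    ggplot2::scale_colour_manual(
      values = c(down = "steelblue", ns = "grey60", up = "firebrick")) +
    ggplot2::labs(x = "log2 fold change", y = "-log10 adjusted p")
}
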