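new_permutation_summary <- function(observed, null_values, statistic) {
  b <- length(null_values)
  structure(
    list(
      observed = observed, null_values = null_values, B = b,
      empirical_p = (1 + sum(null_values >= observed)) / (1 + b),
      statistic = statistic
    ),
    class = "permutation_summary"
  )
}

#' @export
print.permutation_summary <- function(x, ...) {
  cat(sprintf(
    "<permutation_summary> %s: observed %.4g, null mean %.4g (B = %d), empirical p = %.4g\n",
    x$statistic, x$observed, mean(x$null_values), x$B, x$empirical_p
  ))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.permutation_summary <- function(x, ...) {
  tibble(iteration = seq_len(x$B), null_value = x$null_values)
}

#' @exportS3Method generics::glance
glance.permutation_summary <- function(x, ...) {
  tibble(statistic = x$statistic, observed = x$observed, B = x$B,
         null_mean = mean(x$null_values), empirical_p = x$empirical_p)
}

#' @exportS3Method ggplot2::autoplot
autoplot.permutation_summary <- function(object, ...) {
  ggplot2::ggplot(tidy(object), ggplot2::aes(x = .data$null_value)) +
    ggplot2::geom_histogram(bins = 40, fill = "grey70") +
    ggplot2::geom_vline(xintercept = object$observed, colour = "firebrick") +
    ggplot2::labs(x = object$statistic, y = "null draws",
                  title = sprintf("empirical p = %.3g", object$empirical_p))
}

#' Do focal genes have more TE correlations than random gene sets?
#'
#' Counts the significant correlations (all, positive, negative) between
#' the focal gene set and the TEs, then repeats the identical correlation
#' pipeline `B` times with gene sets of the same size drawn without
#' replacement from a null pool (by default: any expressed gene outside the
#' focal set). One-sided "greater" empirical p-values use the plus-one rule
#' `(1 + #\{null >= observed\}) / (1 + B)`, so they are never exactly zero.
#'
#' @inheritParams correlate_all
#' @param focal_genes Gene ids whose correlation excess is tested.
#' @param pool Candidate null gene ids, disjoint from `focal_genes`, at
#'   least as many as `|focal_genes|`.
#' @param B Permutation iterations (>= 100). Default 1000.
#' @param seed Optional integer; fixes the permutation stream without
#'   touching the caller's RNG state.
#' @return A named list of three `permutation_summary` objects:
#'   `all`, `positive`, `negative`.
#' @export
random_geneset_null <- function(x, focal_genes, tes, pool,
                                samples = NULL, group = "all",
                                B = 1000, seed = NULL,
                                min_abs_r = 0.4, cor_alpha = 0.01,
                                presence_frac = 0.8) {
  pool <- setdiff(pool, focal_genes)
  if (length(pool) < length(focal_genes)) {
    abort("null pool smaller than the focal gene set")
  }
  if (B < 100) abort("B must be >= 100")
  count3 <- function(gene_set) {
    rec <- correlate_all(x, gene_set, tes, samples, group,
                         min_abs_r, cor_alpha, presence_frac)
    sig <- rec[rec$significant, , drop = FALSE]
    c(all = nrow(sig), positive = sum(sig$r > 0), negative = sum(sig$r < 0))
  }
  observed <- count3(focal_genes)
  nulls <- with_optional_seed(seed, {
    vapply(seq_len(B), function(i) {
      count3(sample(pool, length(focal_genes)))
    }, numeric(3))
  })
  list(
    all = new_permutation_summary(observed["all"], nulls["all", ],
                                  "significant correlations (all)"),
    positive = new_permutation_summary(observed["positive"],
                                       nulls["positive", ],
                                       "significant correlations (positive)"),
    negative = new_permutation_summary(observed["negative"],
                                       nulls["negative", ],
                                       "significant correlations (negative)")
  )
}

with_optional_seed <- function(seed, code) {
  if (is.null(seed)) code else withr::with_seed(seed, code)
}

#' Jaccard similarity of two sets
#'
#' `|A intersect B| / |A union B|`; two empty sets give 0 by convention.
#'
#' @param a,b Vectors treated as sets.
#' @return A number in `[0, 1]`.
#' @examples
#' jaccard(c("a", "b"), c("b", "c")) # 1/3
#' @export
jaccard <- function(a, b) {
  a <- unique(a); b <- unique(b)
  u <- length(union(a, b))
  if (u == 0) return(0)
  length(intersect(a, b)) / u
}

pair_key <- function(pairs) {
  paste(pairs$gene_id, pairs$te_id, sep = "\r")
}

#' Overlap of significant pairs with binding evidence
#'
#' Measures the Jaccard similarity between the significant (gene, TE) pairs
#' and an experimental binding-evidence pair list, both restricted to a
#' stated pair universe, and compares it against random pair sets of the
#' same size drawn from the universe.
#'
#' @param sig_pairs Tibble of significant pairs (`gene_id`, `te_id`),
#'   a subset of `universe`.
#' @param evidence Evidence pair tibble; restricted to `universe` first.
#' @param universe Tibble of all candidate (gene, te) pairs.
#' @param B Permutation iterations. Default 1000.
#' @param seed Optional integer seed.
#' @return A `permutation_summary` with the observed Jaccard similarity.
#' @export
evidence_overlap_test <- function(sig_pairs, evidence, universe,
                                  B = 1000, seed = NULL) {
  if (nrow(sig_pairs) == 0) abort("sig_pairs is empty")
  uni <- unique(pair_key(universe))
  sig <- unique(pair_key(sig_pairs))
  if (!all(sig %in% uni)) abort("sig_pairs must be a subset of the universe")
  ev <- intersect(unique(pair_key(evidence)), uni)
  observed <- jaccard(sig, ev)
  nulls <- with_optional_seed(seed, {
    vapply(seq_len(B), function(i) {
      jaccard(sample(uni, length(sig)), ev)
    }, numeric(1))
  })
  new_permutation_summary(observed, nulls, "Jaccard similarity with evidence")
}

#' Keep only evidence-confirmed correlation records
#'
#' @param records Correlation records ([correlate_all()] layout).
#' @param evidence Evidence pair tibble (`gene_id`, `te_id`).
#' @return The records whose (gene, te) pair appears in the evidence list,
#'   original order preserved.
#' @export
filter_by_evidence <- function(records, evidence) {
  keep <- pair_key(records) %in% pair_key(evidence)
  records[keep, , drop = FALSE]
}
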