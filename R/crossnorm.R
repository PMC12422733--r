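#' Null probability for the conserved-feature equality test
#'
#' For one conserved feature with counts `x_a`, `x_b` in two species, the
#' equality null conditions on the total `x_a + x_b` and asks whether the
#' species-B share is consistent with equal underlying expression once
#' feature lengths, library sizes and a between-species scaling factor `f`
#' are accounted for. The species-B success probability is
#' \deqn{p(f) = \frac{f N_B L_B}{N_A L_A + f N_B L_B}}
#' where `N` are library sizes and `L` feature lengths.
#'
#' @param len_a,len_b Feature lengths (bp) in species A and B.
#' @param lib_a,lib_b Library sizes (total counts) of species A and B.
#' @param f Scaling factor (> 0).
#' @return The binomial success probability for species-B reads.
#' @examples
#' conserved_null_prob(1000, 1000, 1e6, 1e6, f = 1) # 0.5
#' @export
conserved_null_prob <- function(len_a, len_b, lib_a, lib_b, f) {
  if (any(f <= 0)) abort("scaling factor f must be > 0")
  stopifnot(all(len_a > 0), all(len_b > 0), all(lib_a > 0), all(lib_b > 0))
  f * lib_b * len_b / (lib_a * len_a + f * lib_b * len_b)
}

# Vectorized two-sided exact binomial p-value (minimum-likelihood rule, the
# same tail definition as stats::binom.test) computed with a binary search
# over each monotone flank of the mass function instead of an O(n) scan.
binom_two_sided_p <- function(x, n, p) {
  len <- max(length(x), length(n), length(p))
  x <- rep_len(x, len); n <- rep_len(n, len); p <- rep_len(p, len)
  stopifnot(all(n >= 1), all(p > 0), all(p < 1), all(x >= 0), all(x <= n))
  rel_err <- 1 + 1e-07
  d <- dbinom(x, n, p)
  thr <- d * rel_err
  m <- n * p
  out <- numeric(len)
  eq <- x == m
  out[eq] <- 1
  lower <- x < m & !eq
  upper <- x > m & !eq

  # smallest k in [lo, hi] with dbinom(k) <= thr, where dbinom is
  # nonincreasing on [lo, hi]; hi + 1 when none
  search_smallest <- function(lo, hi, n, p, thr) {
    none <- dbinom(hi, n, p) > thr
    l <- lo; h <- hi
    for (it in seq_len(42)) {
      if (all(l >= h)) break
      mid <- (l + h) %/% 2
      ok <- dbinom(mid, n, p) <= thr
      h <- ifelse(ok, mid, h)
      l <- ifelse(ok, l, mid + 1)
    }
    ifelse(none, hi + 1, l)
  }

  if (any(lower)) {
    i <- which(lower)
    a <- ceiling(m[i])
    k0 <- search_smallest(a, n[i], n[i], p[i], thr[i])
    y <- n[i] - k0 + 1 # count of upper-flank terms inside the tail
    out[i] <- pbinom(x[i], n[i], p[i]) +
      pbinom(n[i] - y, n[i], p[i], lower.tail = FALSE)
  }
  if (any(upper)) {
    i <- which(upper)
    b <- floor(m[i])
    # dbinom nondecreasing on [0, b]; largest k with mass <= thr
    none <- dbinom(0, n[i], p[i]) > thr[i]
    l <- rep_len(0, length(i)); h <- b
    for (it in seq_len(42)) {
      if (all(l >= h)) break
      mid <- (l + h + 1) %/% 2
      ok <- dbinom(mid, n[i], p[i]) <= thr[i]
      l <- ifelse(ok, mid, l)
      h <- ifelse(ok, h, mid - 1)
    }
    y <- ifelse(none, 0, l + 1) # count of lower-flank terms inside the tail
    out[i] <- pbinom(y - 1, n[i], p[i]) +
      pbinom(x[i] - 1, n[i], p[i], lower.tail = FALSE)
  }
  pmin(out, 1)
}

#' Estimate the between-species scaling factor
#'
#' Chooses the factor `f` whose induced equality test on conserved features
#' has an empirical type I error closest to the nominal level `alpha`.
#' Counts are first summed across replicate samples per feature (the factor
#' is a species-level constant). Each conserved feature is then tested with
#' a two-sided exact binomial test of `x_b` successes in `x_a + x_b` trials
#' at [conserved_null_prob()]; the empirical type I error at a candidate `f`
#' is the fraction of features with p < `alpha`. The search grid is
#' `grid_size` log2-spaced points covering a 2^(+/- `grid_span`) range
#' around the median moment estimate of `f`. Objective ties are broken
#' toward the grid point nearest 1 (no-change prior).
#'
#' @param counts_a,counts_b Per-feature conserved counts (one value per
#'   feature, replicates already summed; vectors aligned by position).
#' @param lengths_a,lengths_b Per-feature lengths (bp) in each species.
#' @param lib_a,lib_b Species library sizes (total matrix counts).
#' @param alpha Nominal type I error. Default 0.05.
#' @param grid_size Number of grid points. Default 401.
#' @param grid_span Half-width of the grid in log2 units. Default 2.
#' @param min_features Minimum conserved features required. Default 20.
#' @return A `scaling_result`: list with `factor`, `grid`, `empirical_t1`,
#'   `alpha`, `n_conserved`.
#' @seealso [estimate_scaling()], [estimate_te_scaling()], [apply_scaling()]
#' @export
estimate_scaling_factor <- function(counts_a, counts_b,
                                    lengths_a, lengths_b,
                                    lib_a, lib_b,
                                    alpha = 0.05,
                                    grid_size = 401,
                                    grid_span = 2,
                                    min_features = 20) {
  stopifnot(length(counts_a) == length(counts_b),
            length(lengths_a) == length(counts_a),
            length(lengths_b) == length(counts_a),
            alpha > 0, alpha < 1, grid_size >= 3, grid_span > 0)
  zero <- counts_a + counts_b == 0
  if (any(zero)) {
    warn(sprintf("dropping %d all-zero conserved feature(s)", sum(zero)))
    counts_a <- counts_a[!zero]; counts_b <- counts_b[!zero]
    lengths_a <- lengths_a[!zero]; lengths_b <- lengths_b[!zero]
  }
  if (length(counts_a) < min_features) {
    abort(sprintf("only %d conserved features with nonzero counts (need >= %d)",
                  length(counts_a), min_features))
  }
  both <- counts_a > 0 & counts_b > 0
  ratio <- if (any(both)) {
    (counts_b[both] / counts_a[both]) *
      (lib_a * lengths_a[both]) / (lib_b * lengths_b[both])
  } else {
    ((counts_b + 0.5) / (counts_a + 0.5)) *
      (lib_a * lengths_a) / (lib_b * lengths_b)
  }
  center <- median(ratio)
  grid <- center * 2^seq(-grid_span, grid_span, length.out = grid_size)
  n_tot <- counts_a + counts_b
  t1 <- vapply(grid, function(f) {
    p0 <- conserved_null_prob(lengths_a, lengths_b, lib_a, lib_b, f)
    mean(binom_two_sided_p(counts_b, n_tot, p0) < alpha)
  }, numeric(1))
  objective <- abs(t1 - alpha)
  winners <- which(objective == min(objective))
  best <- winners[which.min(abs(log2(grid[winners])))]
  structure(
    list(factor = grid[best], grid = grid, empirical_t1 = t1,
         alpha = alpha, n_conserved = length(counts_a)),
    class = "scaling_result"
  )
}

#' @export
print.scaling_result <- function(x, ...) {
  cat(sprintf(
    "<scaling_result> factor = %.4g (empirical type I %.4f at alpha %.3g, %d conserved features)\n",
    x$factor, x$empirical_t1[which(x$grid == x$factor)[1]], x$alpha,
    x$n_conserved
  ))
  invisible(x)
}

#' @describeIn estimate_scaling_factor One row per grid point with the
#'   empirical type I error and objective.
#' @param x A `scaling_result`.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.scaling_result <- function(x, ...) {
  tibble(factor = x$grid, empirical_t1 = x$empirical_t1,
         objective = abs(x$empirical_t1 - x$alpha),
         selected = x$grid == x$factor)
}

#' @describeIn estimate_scaling_factor One-row summary of the fit.
#' @exportS3Method generics::glance
glance.scaling_result <- function(x, ...) {
  tibble(factor = x$factor,
         empirical_t1 = x$empirical_t1[which(x$grid == x$factor)[1]],
         alpha = x$alpha, n_conserved = x$n_conserved)
}

#' @describeIn estimate_scaling_factor Calibration curve: empirical type I
#'   error across the factor grid, nominal level and selected factor marked.
#' @param object A `scaling_result`.
#' @exportS3Method ggplot2::autoplot
autoplot.scaling_result <- function(object, ...) {
  ggplot2::ggplot(tidy(object),
                  ggplot2::aes(x = .data$factor, y = .data$empirical_t1)) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = object$alpha, linetype = 2) +
    ggplot2::geom_vline(xintercept = object$factor, colour = "red") +
    ggplot2::scale_x_continuous(trans = "log2") +
    ggplot2::labs(x = "scaling factor (log2 grid)",
                  y = "empirical type I error",
                  title = sprintf("selected factor %.3g", object$factor))
}

#' Estimate the gene scaling factor from two count containers
#'
#' Convenience wrapper around [estimate_scaling_factor()]: selects ortholog
#' pairs present in both matrices (optionally high-confidence only), sums
#' counts across samples, and uses total matrix counts as library sizes.
#'
#' @param x_a,x_b [te_counts] (or matrices) for species A and B.
#' @param orthologs Ortholog map tibble ([read_ortholog_map()] layout).
#' @param confidence Orthology confidence classes to use. Default "high".
#' @inheritParams estimate_scaling_factor
#' @inheritDotParams estimate_scaling_factor grid_size grid_span min_features
#' @return A `scaling_result`.
#' @export
estimate_scaling <- function(x_a, x_b, orthologs, alpha = 0.05,
                             confidence = "high", ...) {
  ma <- count_matrix_of(x_a); mb <- count_matrix_of(x_b)
  om <- validate_ortholog_map(orthologs)
  om <- om[om$confidence %in% confidence, , drop = FALSE]
  om <- om[om$feature_id_a %in% rownames(ma) &
             om$feature_id_b %in% rownames(mb), , drop = FALSE]
  if (nrow(om) == 0) abort("no conserved ortholog pairs found in both matrices")
  estimate_scaling_factor(
    counts_a = rowSums(ma[om$feature_id_a, , drop = FALSE]),
    counts_b = rowSums(mb[om$feature_id_b, , drop = FALSE]),
    lengths_a = om$length_a_bp, lengths_b = om$length_b_bp,
    lib_a = sum(ma), lib_b = sum(mb), alpha = alpha, ...
  )
}

# Collapse subfamily-level TE classes onto the mobile-element superfamilies
# whose consensus sequences are homologous across species.
te_superfamily <- function(te_class) {
  dplyr::case_when(
    te_class %in% c("Alu", "MIR", "SINE") ~ "SINE",
    te_class %in% c("L1", "L2", "CR1", "RTE", "LINE") ~ "LINE",
    grepl("^ERV", te_class) | te_class %in% c("LTR", "Gypsy") ~ "LTR",
    grepl("^TcMar", te_class) | te_class %in% c("hAT", "DNA") ~ "DNA",
    te_class == "SVA" ~ "SVA",
    TRUE ~ "other"
  )
}

#' Estimate the TE scaling factor
#'
#' As [estimate_scaling()], but the conserved set is the TE subfamilies of
#' the homologous superfamilies (LTR, LINE, SINE, SVA, DNA transposons)
#' present in both species; the consensus length from the annotation serves
#' as the length in both species.
#'
#' @param x_a,x_b [te_counts] (or matrices) of TE subfamily counts.
#' @param annotation Feature annotation ([read_feature_annotation()] layout).
#' @inheritParams estimate_scaling
#' @inheritDotParams estimate_scaling_factor grid_size grid_span min_features
#' @return A `scaling_result`.
#' @export
estimate_te_scaling <- function(x_a, x_b, annotation, alpha = 0.05, ...) {
  ma <- count_matrix_of(x_a); mb <- count_matrix_of(x_b)
  ann <- validate_annotation(annotation)
  tes <- ann[ann$kind == "TE" &
               te_superfamily(ann$te_class) %in%
                 c("LTR", "LINE", "SINE", "SVA", "DNA"), , drop = FALSE]
  shared <- intersect(intersect(tes$feature_id, rownames(ma)), rownames(mb))
  if (length(shared) == 0) abort("no homologous TE subfamilies in both species")
  len <- tes$length_bp[match(shared, tes$feature_id)]
  estimate_scaling_factor(
    counts_a = rowSums(ma[shared, , drop = FALSE]),
    counts_b = rowSums(mb[shared, , drop = FALSE]),
    lengths_a = len, lengths_b = len,
    lib_a = sum(ma), lib_b = sum(mb), alpha = alpha, ...
  )
}

#' Apply a scaling factor to the species-B matrix
#'
#' Divides every entry of the species-B matrix by the estimated factor so
#' that expression levels are comparable with species A (whose matrix is by
#' convention left unchanged).
#'
#' @param x A [te_counts] object or numeric matrix (species B).
#' @param scaling A `scaling_result`, or a bare positive number.
#' @return Same container type as `x`, with real-valued entries.
#' @export
apply_scaling <- function(x, scaling) {
  f <- if (inherits(scaling, "scaling_result")) scaling$factor else scaling
  if (!is.numeric(f) || length(f) != 1 || f <= 0) {
    abort("scaling factor must be a single positive number")
  }
  if (inherits(x, "te_counts")) {
    x$counts <- x$counts / f
    x
  } else {
    as.matrix(x) / f
  }
}
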