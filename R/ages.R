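#' Evolutionary age class of a feature
#'
#' Features that emerged at or after the split (default 44.2 million years
#' ago, the emergence of Simiiformes) are `young`; strictly older features
#' are `old`. The boundary value itself is `young` (`age <= split`).
#'
#' @param age_mya Nonnegative age(s) in million years.
#' @param split Age split in Mya. Default 44.2.
#' @return Factor with levels `young`, `old`.
#' @examples
#' age_class(c(0, 44.2, 90))
#' @export
age_class <- function(age_mya, split = 44.2) {
  if (any(age_mya < 0, na.rm = TRUE)) abort("age_mya must be nonnegative")
  factor(ifelse(age_mya <= split, "young", "old"), levels = c("young", "old"))
}

#' Class of a correlation link
#'
#' A link is `young` when *either* endpoint is evolutionarily young and
#' `old` only when both endpoints are old; combined with the sign of the
#' correlation this yields the four classes P-O, P-Y, N-O, N-Y
#' (positive/negative x old/young).
#'
#' @param r Correlation coefficient(s), nonzero.
#' @param gene_age,te_age Age classes (`young`/`old`) of the endpoints.
#' @return Factor with levels `P-O`, `P-Y`, `N-O`, `N-Y`.
#' @examples
#' link_class(0.6, "old", "old")    # P-O
#' link_class(-0.5, "old", "young") # N-Y
#' @export
link_class <- function(r, gene_age, te_age) {
  if (any(r == 0)) abort("link sign undefined for r = 0")
  ok <- c("young", "old")
  if (!all(as.character(gene_age) %in% ok) ||
      !all(as.character(te_age) %in% ok)) {
    abort("ages must be 'young' or 'old'")
  }
  young <- as.character(gene_age) == "young" | as.character(te_age) == "young"
  cls <- paste0(ifelse(r > 0, "P-", "N-"), ifelse(young, "Y", "O"))
  factor(cls, levels = c("P-O", "P-Y", "N-O", "N-Y"))
}

#' Attach age and link classes to correlation records
#'
#' Looks up each endpoint's age in the annotation, classifies features at
#' the split, and assigns the link class from [link_class()]. Records whose
#' endpoints cannot be dated (missing `age_mya`) are excluded with a
#' warning, mirroring how undatable elements are left out of age-stratified
#' summaries.
#'
#' @param records Correlation records ([correlate_all()] layout).
#' @param annotation Feature annotation with `feature_id` and `age_mya`.
#' @param split Age split in Mya. Default 44.2.
#' @return `records` with added columns `gene_age`, `te_age`, `link_class`.
#' @export
classify_links <- function(records, annotation, split = 44.2) {
  ann <- as_tibble(annotation)
  age_of <- setNames(ann$age_mya, ann$feature_id)
  ga <- age_of[records$gene_id]
  ta <- age_of[records$te_id]
  drop <- is.na(ga) | is.na(ta) | records$r == 0
  if (any(drop)) {
    warn(sprintf(
      "excluding %d link(s) with undated endpoints or zero correlation",
      sum(drop)))
  }
  out <- records[!drop, , drop = FALSE]
  out$gene_age <- age_class(ga[!drop], split)
  out$te_age <- age_class(ta[!drop], split)
  out$link_class <- link_class(out$r, out$gene_age, out$te_age)
  out
}

#' Per-TE-family link-class composition test
#'
#' For each TE family, tests whether its distribution over the four link
#' classes (P-O, P-Y, N-O, N-Y) differs from the pooled distribution of all
#' other families, using a chi-squared test on the 2x4 contingency table.
#' When any expected cell is below 5 the asymptotic p is replaced by a
#' Monte-Carlo p (`mc_reps` simulated tables with fixed margins), since the
#' asymptotic approximation is invalid on the sparse rows common for rare
#' families.
#'
#' @param records Classified links ([classify_links()] output).
#' @param family_of Named character vector mapping `te_id` to family, or an
#'   annotation tibble with `feature_id` and `te_class`.
#' @param alpha Flagging threshold. Default 0.001.
#' @param mc_reps Monte-Carlo replicates for sparse tables. Default 1e5.
#' @param seed Optional integer seed for the Monte-Carlo p.
#' @return A tibble: one row per family with the four class counts,
#'   `chi2`, `p`, `method`, `flagged`.
#' @export
family_class_test <- function(records, family_of, alpha = 0.001,
                              mc_reps = 1e5, seed = NULL) {
  if (is.data.frame(family_of)) {
    family_of <- setNames(family_of$te_class, family_of$feature_id)
  }
  fam <- unname(family_of[records$te_id])
  if (any(is.na(fam))) abort("every te_id needs a family assignment")
  classes <- levels(records$link_class)
  tab <- table(factor(fam), factor(records$link_class, levels = classes))
  if (nrow(tab) < 2) abort("need at least 2 families with links")
  with_optional_seed(seed, {
    purrr::map_dfr(rownames(tab), function(f) {
      focal <- tab[f, ]
      rest <- colSums(tab) - focal
      if (sum(focal) == 0) {
        warn(sprintf("family '%s' has no links; skipped", f))
        return(tibble())
      }
      m <- rbind(focal, rest)
      keep_cols <- colSums(m) > 0
      m2 <- m[, keep_cols, drop = FALSE]
      if (ncol(m2) < 2 || any(rowSums(m2) == 0)) {
        res <- list(statistic = NA_real_, p.value = 1)
        method <- "degenerate"
      } else {
        expected <- outer(rowSums(m2), colSums(m2)) / sum(m2)
        if (any(expected < 5)) {
          res <- suppressWarnings(
            chisq.test(m2, simulate.p.value = TRUE, B = mc_reps))
          method <- "monte-carlo"
        } else {
          res <- suppressWarnings(chisq.test(m2, correct = FALSE))
          method <- "asymptotic"
        }
      }
      out <- tibble(
        family = f,
        chi2 = unname(res$statistic), p = res$p.value,
        method = method, flagged = res$p.value < alpha
      )
      for (cl in classes) out[[cl]] <- unname(focal[cl])
      out
    })
  })
}

#' Link-class composition plot
#'
#' Stacked per-family counts of the four link classes.
#'
#' @param records Classified links ([classify_links()] output).
#' @param family_of Named character vector `te_id -> family` or annotation
#'   tibble with `feature_id`, `te_class`.
#' @return A ggplot object.
#' @export
plot_link_classes <- function(records, family_of) {
  if (is.data.frame(family_of)) {
    family_of <- setNames(family_of$te_class, family_of$feature_id)
  }
  d <- mutate(records, family = unname(family_of[.data$te_id]))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$family,
                                  fill = .data$link_class)) +
    ggplot2::geom_bar() +
    ggplot2::scale_fill_manual(values = c(
      `P-O` = "#2166ac", `P-Y` = "#92c5de",
      `N-O` = "#b2182b", `N-Y` = "#f4a582")) +
    ggplot2::labs(x = "TE family", y = "links", fill = "class") +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
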