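#' Analysis configuration
#'
#' Collects every tunable threshold of the workflow in one place. Individual
#' functions expose the same values as arguments with these defaults, so a
#' config object is only needed when driving the full pipeline with
#' non-default settings.
#'
#' @param min_abs_r Minimum absolute Pearson coefficient for a correlation to
#'   be called significant. Default 0.4.
#' @param cor_alpha Adjusted-p (BH) cutoff for correlations. Default 0.01.
#' @param lfc_threshold Absolute log2 fold-change threshold for differential
#'   expression calls. Default 1.5; condition contrasts within one species
#'   (e.g. control vs disease) typically use 0.5.
#' @param de_alpha Adjusted-p cutoff for differential expression. Default 0.05.
#' @param age_split_mya Age (in million years) separating evolutionarily
#'   young (<= split) from old (> split) features. Default 44.2, the
#'   emergence of Simiiformes.
#' @param hub_fraction Top fraction of nodes (by bipartite degree and
#'   strength) called hubs. Default 0.05.
#' @param n_perm Permutation iterations for null tests. Default 1000.
#' @param n_sim_fisher Monte-Carlo tables for module enrichment. Default 1e6.
#' @param presence_frac A feature is "expressed" in a group when its count is
#'   positive in at least this fraction of the group's samples. Default 0.8.
#' @param scaling_alpha Nominal type I error targeted by the cross-species
#'   scaling factor. Default 0.05.
#'
#' @return A list with class `"tecnet_config"`.
#' @examples
#' cfg <- analysis_config(lfc_threshold = 0.5)
#' cfg$lfc_threshold
#' @export
analysis_config <- function(min_abs_r = 0.4,
                            cor_alpha = 0.01,
                            lfc_threshold = 1.5,
                            de_alpha = 0.05,
                            age_split_mya = 44.2,
                            hub_fraction = 0.05,
                            n_perm = 1000,
                            n_sim_fisher = 1e6,
                            presence_frac = 0.8,
                            scaling_alpha = 0.05) {
  stopifnot(
    min_abs_r >= 0, min_abs_r < 1,
    cor_alpha > 0, cor_alpha < 1,
    lfc_threshold >= 0,
    de_alpha > 0, de_alpha < 1,
    age_split_mya >= 0,
    hub_fraction > 0, hub_fraction <= 1,
    n_perm >= 1, n_sim_fisher >= 1,
    presence_frac >= 0, presence_frac <= 1,
    scaling_alpha > 0, scaling_alpha < 1
  )
  structure(
    list(
      min_abs_r = min_abs_r, cor_alpha = cor_alpha,
      lfc_threshold = lfc_threshold, de_alpha = de_alpha,
      age_split_mya = age_split_mya, hub_fraction = hub_fraction,
      n_perm = n_perm, n_sim_fisher = n_sim_fisher,
      presence_frac = presence_frac, scaling_alpha = scaling_alpha
    ),
    class = "tecnet_config"
  )
}

#' @export
print.tecnet_config <- function(x, ...) {
  cat("<tecnet analysis configuration>\n")
  for (nm in names(x)) cat(sprintf("  %-14s %g\n", nm, x[[nm]]))
  invisible(x)
}
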