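default_species <- function() {
  list(
    human = list(scaling_factor = 1.0, n_individuals = 4),
    chimp = list(scaling_factor = 1.3, n_individuals = 3),
    bonobo = list(scaling_factor = 0.8, n_individuals = 3),
    macaque = list(scaling_factor = 1.6, n_individuals = 3)
  )
}

#' Specification of a synthetic multi-species expression study
#'
#' Describes the study design emulated by [simulate_dataset()]: a
#' primate-brain-style cohort (four species with 4+3+3+3 individuals,
#' seven region groups, several samples per region group) of gene and TE
#' subfamily counts, with a known between-species scaling factor per
#' species and a set of planted correlated (KRAB-ZNF, TE) pairs. Counts
#' are negative-binomial draws linked through a Gaussian copula, so a
#' planted pair's target correlation can be set analytically while the
#' marginals stay count-like. An unscaled background transcriptome is
#' included so that species library sizes are dominated by features
#' outside the compared set, which is what makes the scaling factor
#' identifiable from matrix sums (as in real data, where orthologous
#' genes are a minority of the library).
#'
#' @param n_genes,n_tes,n_krabznf Feature counts; the first `n_krabznf`
#'   genes are flagged as KRAB-ZNFs (`n_krabznf <= n_genes`).
#' @param species Named list; per species a list with `scaling_factor`
#'   (> 0) and `n_individuals`.
#' @param groups Region-group labels.
#' @param samples_per_group Samples per individual per group.
#' @param conditions Condition labels (e.g. `c("control", "AD")`); every
#'   individual contributes samples to every condition.
#' @param planted_links Optional tibble (`gene_id`, `te_id`, `target_r`,
#'   optional `species`, `condition` scopes, `"all"` meaning every one);
#'   when NULL, `n_planted` pairs are drawn at random among KRAB-ZNFs and
#'   TEs with `|target_r| = target_r` and a `prop_positive` share of
#'   positive signs.
#' @param n_planted,target_r,prop_positive See `planted_links`.
#' @param age_young_frac Fraction of features dated younger than the
#'   44.2-Mya split.
#' @param nb_dispersion Negative-binomial dispersion (variance =
#'   mu + mu^2 * dispersion).
#' @param background_cor When > 0, all features additionally load on one
#'   latent sample factor with loadings uniform on (-background_cor,
#'   background_cor), producing the diffuse correlation background seen in
#'   transcriptome data; 0 (default) gives an exact null between
#'   non-planted pairs.
#' @param n_background,background_mean Size and mean expression of the
#'   unscaled background transcriptome.
#' @param evidence_frac Fraction of planted links included in the
#'   binding-evidence list.
#' @param n_decoy_evidence Non-planted decoy pairs added to the evidence
#'   list.
#' @param seed Integer seed; [simulate_dataset()] is byte-reproducible
#'   given the spec.
#' @return A list with class `"sim_spec"`.
#' @export
sim_spec <- function(n_genes = 1000, n_tes = 900, n_krabznf = 340,
                     species = default_species(),
                     groups = paste0("region", 1:7),
                     samples_per_group = 5,
                     conditions = "control",
                     planted_links = NULL,
                     n_planted = 30, target_r = 0.8, prop_positive = 0.7,
                     age_young_frac = 0.3,
                     nb_dispersion = 0.15,
                     background_cor = 0,
                     n_background = 2000, background_mean = 300,
                     evidence_frac = 2 / 3, n_decoy_evidence = 50,
                     seed = 1) {
  stopifnot(
    n_krabznf <= n_genes, n_genes >= 1, n_tes >= 1,
    length(species) >= 1, samples_per_group >= 1,
    target_r > 0, target_r < 1,
    prop_positive >= 0, prop_positive <= 1,
    age_young_frac >= 0, age_young_frac <= 1,
    nb_dispersion > 0, background_cor >= 0, background_cor < 1,
    n_background >= 0, evidence_frac >= 0, evidence_frac <= 1
  )
  for (sp in species) {
    stopifnot(sp$scaling_factor > 0, sp$n_individuals >= 1)
  }
  if (!is.null(planted_links)) {
    planted_links <- as_tibble(planted_links)
    stopifnot(all(c("gene_id", "te_id", "target_r") %in%
                    names(planted_links)))
    if (any(abs(planted_links$target_r) >= 1) ||
        any(planted_links$target_r == 0)) {
      abort("planted |target_r| must be in (0, 1)")
    }
    if (is.null(planted_links$species)) planted_links$species <- "all"
    if (is.null(planted_links$condition)) planted_links$condition <- "all"
  }
  structure(
    list(
      n_genes = n_genes, n_tes = n_tes, n_krabznf = n_krabznf,
      species = species, groups = groups,
      samples_per_group = samples_per_group, conditions = conditions,
      planted_links = planted_links, n_planted = n_planted,
      target_r = target_r, prop_positive = prop_positive,
      age_young_frac = age_young_frac, nb_dispersion = nb_dispersion,
      background_cor = background_cor, n_background = n_background,
      background_mean = background_mean, evidence_frac = evidence_frac,
      n_decoy_evidence = n_decoy_evidence, seed = seed
    ),
    class = "sim_spec"
  )
}

#' Pure-null copy of a simulation spec
#'
#' Same design with the planted links removed, for calibration tests.
#'
#' @param spec A [sim_spec()].
#' @return The spec with an empty `planted_links` table and `n_planted = 0`.
#' @export
null_spec <- function(spec) {
  spec$planted_links <- tibble(gene_id = character(), te_id = character(),
                               target_r = numeric(), species = character(),
                               condition = character())
  spec$n_planted <- 0
  spec
}

te_class_pool <- function() {
  c("Alu" = 0.3, "L1" = 0.2, "ERVK" = 0.08, "ERVL" = 0.08, "ERV1" = 0.08,
    "SVA" = 0.04, "TcMar-Tigger" = 0.08, "hAT" = 0.06, "MIR" = 0.05,
    "L2" = 0.03)
}

#' Simulate a multi-species gene/TE expression study
#'
#' Draws the dataset described by a [sim_spec()]: one count container per
#' species (genes, TE subfamilies and an unscaled background transcriptome
#' over the same feature ids), a feature annotation with TE classes and
#' ages, pairwise one-to-one ortholog maps against the first (reference)
#' species, a binding-evidence pair list (planted pairs plus decoys), and
#' a ground-truth table for every planted link. Latent per-sample
#' log-expression is Gaussian; a planted pair's TE latent is
#' `rho * gene + sqrt(1 - rho^2) * noise` within its species/condition
#' scope; counts are NB quantiles of the latent normal (Gaussian copula),
#' with the species scaling factor multiplying the mean of every annotated
#' feature.
#'
#' @param spec A [sim_spec()].
#' @return A list: `counts` (named list of [te_counts]), `annotation`,
#'   `ortholog_maps` (named list, reference vs each other species),
#'   `evidence`, `truth` (list with `planted_links`, `scaling_factors`,
#'   `library_sizes`), `spec`.
#' @export
simulate_dataset <- function(spec) {
  stopifnot(inherits(spec, "sim_spec"))
  withr::with_seed(spec$seed, simulate_dataset_impl(spec))
}

simulate_dataset_impl <- function(spec) {
  n_g <- spec$n_genes; n_t <- spec$n_tes; n_b <- spec$n_background
  gene_ids <- c(
    sprintf("ZNF%04d", seq_len(spec$n_krabznf)),
    if (n_g > spec$n_krabznf) {
      sprintf("GENE%04d", seq(spec$n_krabznf + 1, n_g))
    }
  )
  te_ids <- sprintf("TE%04d", seq_len(n_t))
  bg_ids <- if (n_b > 0) sprintf("BG%04d", seq_len(n_b)) else character()
  classes <- sample(names(te_class_pool()), n_t, replace = TRUE,
                    prob = te_class_pool())

  ann <- bind_rows(
    tibble(feature_id = gene_ids, kind = "gene", te_class = "",
           is_krab_znf = seq_len(n_g) <= spec$n_krabznf,
           length_bp = round(runif(n_g, 500, 4000)),
           age_mya = ifelse(runif(n_g) < spec$age_young_frac,
                            runif(n_g, 5, 44.2), runif(n_g, 44.3, 300))),
    tibble(feature_id = te_ids, kind = "TE", te_class = classes,
           is_krab_znf = FALSE,
           length_bp = round(runif(n_t, 200, 5000)),
           age_mya = ifelse(runif(n_t) < spec$age_young_frac,
                            runif(n_t, 5, 44.2), runif(n_t, 44.3, 300)))
  )

  planted <- spec$planted_links
  if (is.null(planted)) {
    n_p <- min(spec$n_planted, spec$n_krabznf, n_t)
    planted <- tibble(
      gene_id = sample(gene_ids[seq_len(spec$n_krabznf)], n_p),
      te_id = sample(te_ids, n_p),
      target_r = spec$target_r *
        ifelse(runif(n_p) < spec$prop_positive, 1, -1),
      species = "all", condition = "all"
    )
  }
  if (anyDuplicated(planted$te_id)) {
    abort("planted links must use each TE at most once")
  }

  feat_ids <- c(gene_ids, te_ids, bg_ids)
  n_feat <- length(feat_ids)
  base_mean <- c(
    stats::rlnorm(n_g, log(80), 0.7),
    stats::rlnorm(n_t, log(60), 0.8),
    if (n_b > 0) stats::rlnorm(n_b, log(spec$background_mean), 1)
  )
  loading <- if (spec$background_cor > 0) {
    runif(n_feat, -spec$background_cor, spec$background_cor)
  } else {
    rep(0, n_feat)
  }

  ref <- names(spec$species)[1]
  # per-species gene lengths: reference lengths with mild species drift
  gene_len <- matrix(
    rep(ann$length_bp[seq_len(n_g)], length(spec$species)),
    n_g, length(spec$species),
    dimnames = list(gene_ids, names(spec$species))
  )
  for (sp in names(spec$species)) {
    if (sp != ref) {
      gene_len[, sp] <- pmax(50, round(gene_len[, sp] *
                                         runif(n_g, 0.85, 1.18)))
    }
  }

  gi <- match(planted$gene_id, feat_ids)
  ti <- match(planted$te_id, feat_ids)
  if (any(is.na(gi)) || any(is.na(ti))) {
    abort("planted link endpoints must be simulated features")
  }

  counts <- list()
  lib_sizes <- numeric(0)
  for (sp in names(spec$species)) {
    info <- spec$species[[sp]]
    design <- tidyr::expand_grid(
      individual = sprintf("%s_i%d", sp, seq_len(info$n_individuals)),
      condition = spec$conditions,
      group = spec$groups,
      rep = seq_len(spec$samples_per_group)
    )
    design$sample_id <- sprintf("%s_%s_%s_r%d",
                                design$individual, design$group,
                                design$condition, design$rep)
    n_s <- nrow(design)
    z <- matrix(rnorm(n_feat * n_s), n_feat, n_s)
    if (spec$background_cor > 0) {
      w <- rnorm(n_s)
      z <- loading %o% w + sqrt(1 - loading^2) * z
    }
    for (i in seq_len(nrow(planted))) {
      sp_ok <- planted$species[i] == "all" || planted$species[i] == sp
      if (!sp_ok) next
      in_scope <- planted$condition[i] == "all" |
        design$condition == planted$condition[i]
      rho <- planted$target_r[i]
      z[ti[i], in_scope] <- rho * z[gi[i], in_scope] +
        sqrt(1 - rho^2) * z[ti[i], in_scope]
    }
    len_kb <- c(gene_len[, sp], ann$length_bp[n_g + seq_len(n_t)],
                if (n_b > 0) rep(1000, n_b)) / 1000
    scale_f <- c(rep(info$scaling_factor, n_g + n_t),
                 rep(1, n_b)) # background not scaled
    mu <- base_mean * len_kb * scale_f
    cnt <- matrix(
      qnbinom(pnorm(z), size = 1 / spec$nb_dispersion,
              mu = rep(mu, n_s)),
      n_feat, n_s, dimnames = list(feat_ids, design$sample_id)
    )
    meta <- tibble(
      sample_id = design$sample_id, species = sp,
      individual = design$individual, group = design$group,
      condition = design$condition
    )
    counts[[sp]] <- te_counts(cnt, meta)
    lib_sizes[sp] <- sum(cnt)
  }

  ortholog_maps <- list()
  for (sp in setdiff(names(spec$species), ref)) {
    ortholog_maps[[sp]] <- tibble(
      feature_id_a = gene_ids, feature_id_b = gene_ids,
      length_a_bp = gene_len[, ref], length_b_bp = gene_len[, sp],
      confidence = ifelse(runif(n_g) < 0.9, "high", "low")
    )
  }

  n_ev <- round(spec$evidence_frac * nrow(planted))
  ev_idx <- if (nrow(planted) > 0) {
    sort(sample(nrow(planted), n_ev))
  } else {
    integer()
  }
  planted$in_evidence <- seq_len(nrow(planted)) %in% ev_idx
  decoys <- tibble(
    gene_id = sample(gene_ids, spec$n_decoy_evidence, replace = TRUE),
    te_id = sample(te_ids, spec$n_decoy_evidence, replace = TRUE)
  )
  evidence <- distinct(bind_rows(
    select(planted[ev_idx, , drop = FALSE], "gene_id", "te_id"),
    decoys
  ))
  # decoys never duplicate a non-evidence planted pair
  hidden <- pair_key(planted[!planted$in_evidence, , drop = FALSE])
  evidence <- evidence[!pair_key(evidence) %in% hidden, , drop = FALSE]

  list(
    counts = counts,
    annotation = ann,
    ortholog_maps = ortholog_maps,
    evidence = evidence,
    truth = list(
      planted_links = planted,
      scaling_factors = vapply(spec$species, `[[`, numeric(1),
                               "scaling_factor"),
      library_sizes = lib_sizes
    ),
    spec = spec
  )
}
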