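#' Feature sets expressed in every species
#'
#' Applies the presence filter (count > 0 in at least `presence_frac` of a
#' species' samples) per species and intersects the resulting gene and TE
#' sets, so that cross-species link comparisons use one shared feature
#' universe and cannot be confounded by features detectable in only some
#' species.
#'
#' @param counts_list Named list of [te_counts] objects, one per species
#'   (>= 2).
#' @param annotation Feature annotation with `feature_id` and `kind`.
#' @param presence_frac Presence threshold. Default 0.8.
#' @return List with character vectors `genes` and `tes`.
#' @export
restrict_to_shared_features <- function(counts_list, annotation,
                                        presence_frac = 0.8) {
  if (length(counts_list) < 2) abort("need at least 2 species")
  ann <- as_tibble(annotation)
  kinds <- setNames(ann$kind, ann$feature_id)
  per_species <- purrr::map(counts_list, function(x) {
    mat <- count_matrix_of(x)
    expressed <- rownames(mat)[rowMeans(mat > 0) >= presence_frac]
    list(genes = expressed[kinds[expressed] %in% "gene"],
         tes = expressed[kinds[expressed] %in% "TE"])
  })
  genes <- Reduce(intersect, purrr::map(per_species, "genes"))
  tes <- Reduce(intersect, purrr::map(per_species, "tes"))
  if (length(genes) == 0 && length(tes) == 0) {
    abort("no shared expressed features across species")
  }
  list(genes = sort(genes), tes = sort(tes))
}

#' Compare significant links across groups
#'
#' Assigns each (gene, TE) pair a per-group status (`sig_pos`, `sig_neg`,
#' `ns`) and a cross-group category relative to a reference group:
#' * `sign_flip` — significant in the reference and significant with the
#'   opposite sign in at least one comparison group;
#' * `conserved` — significant in the reference and significant with the
#'   same sign in at least one comparison group (and never flipped);
#' * `human_specific` — significant in the reference and `ns` in every
#'   comparison group (the reference is conventionally the human group);
#' * `other` — not significant in the reference.
#' Categories are mutually exclusive in that precedence order. All groups
#' must have used the same shared feature universe
#' ([restrict_to_shared_features()]).
#'
#' @param records_by_group Named list of correlation record tibbles
#'   ([correlate_all()] layout), one per group.
#' @param reference Name of the reference group.
#' @return A tibble: `gene_id`, `te_id`, one `status_<group>` column per
#'   group, and `category`.
#' @export
compare_groups <- function(records_by_group, reference) {
  if (!reference %in% names(records_by_group)) {
    abort(sprintf("reference group '%s' not in records_by_group", reference))
  }
  status_of <- function(rec) {
    mutate(
      select(as_tibble(rec), "gene_id", "te_id", "r", "significant"),
      status = dplyr::case_when(
        .data$significant & .data$r > 0 ~ "sig_pos",
        .data$significant & .data$r < 0 ~ "sig_neg",
        TRUE ~ "ns"
      )
    )
  }
  groups <- names(records_by_group)
  statuses <- purrr::imap(records_by_group, function(rec, g) {
    rename(select(status_of(rec), "gene_id", "te_id", "status"),
           !!paste0("status_", g) := "status")
  })
  out <- purrr::reduce(statuses, dplyr::full_join,
                       by = c("gene_id", "te_id"))
  status_cols <- paste0("status_", groups)
  out <- mutate(out, across(dplyr::all_of(status_cols),
                            ~tidyr::replace_na(.x, "ns")))
  ref_col <- paste0("status_", reference)
  comp_cols <- setdiff(status_cols, ref_col)
  comp <- as.matrix(out[, comp_cols, drop = FALSE])
  ref <- out[[ref_col]]
  opposite <- ifelse(ref == "sig_pos", "sig_neg", "sig_pos")
  any_flip <- rowSums(comp == opposite) > 0
  any_same <- rowSums(comp == ref) > 0
  all_ns <- rowSums(comp != "ns") == 0
  out$category <- dplyr::case_when(
    ref == "ns" ~ "other",
    any_flip ~ "sign_flip",
    any_same ~ "conserved",
    all_ns ~ "human_specific",
    TRUE ~ "other"
  )
  arrange(out, .data$gene_id, .data$te_id)
}

#' Links lost in the disease condition
#'
#' Returns the pairs significant in the control records, not significant in
#' the disease records, and present in an externally defined pair set
#' (typically the reference-specific links of an independent cross-species
#' comparison from the same brain region).
#'
#' @param control,disease Correlation record tibbles for the two conditions.
#' @param external_specific Tibble of pairs (`gene_id`, `te_id`) to
#'   intersect with.
#' @return A tibble of pairs (`gene_id`, `te_id`).
#' @export
condition_lost_links <- function(control, disease, external_specific) {
  ctrl_sig <- significant_pairs(control)
  dis_sig_keys <- pair_key(significant_pairs(disease))
  lost <- ctrl_sig[!pair_key(ctrl_sig) %in% dis_sig_keys, , drop = FALSE]
  lost[pair_key(lost) %in% pair_key(external_specific), , drop = FALSE]
}
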