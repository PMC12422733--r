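#' Construct a count container
#'
#' Bundles a nonnegative feature-by-sample count matrix with per-sample
#' metadata. All readers and the simulator return this class; analysis
#' functions accept it (or a bare matrix) as first argument.
#'
#' @param counts Numeric matrix, features in rows (rownames = feature ids),
#'   samples in columns (colnames = sample ids). Entries must be finite and
#'   nonnegative.
#' @param meta Data frame with one row per sample: columns `sample_id`,
#'   `species`, `individual`, `group`, `condition`. Extra columns are kept.
#' @return An object of class `"te_counts"`.
#' @examples
#' m <- matrix(0:5, 3, 2, dimnames = list(c("g1", "g2", "AluY"), c("s1", "s2")))
#' meta <- tibble::tibble(sample_id = c("s1", "s2"), species = "hs",
#'                        individual = c("i1", "i2"), group = "cortex",
#'                        condition = "control")
#' x <- te_counts(m, meta)
#' dim(x)
#' @export
te_counts <- function(counts, meta) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts))) {
    abort("`counts` must have feature rownames and sample colnames.")
  }
  dup <- rownames(counts)[duplicated(rownames(counts))]
  if (length(dup) > 0) {
    abort(sprintf("duplicate feature id(s): %s",
                  paste(unique(dup), collapse = ", ")))
  }
  dup <- colnames(counts)[duplicated(colnames(counts))]
  if (length(dup) > 0) {
    abort(sprintf("duplicate sample id(s): %s",
                  paste(unique(dup), collapse = ", ")))
  }
  bad <- which(!is.finite(counts) | counts < 0, arr.ind = TRUE)
  if (nrow(bad) > 0) {
    abort(sprintf(
      "negative or non-finite count at feature '%s', sample '%s'",
      rownames(counts)[bad[1, 1]], colnames(counts)[bad[1, 2]]
    ))
  }
  meta <- as_tibble(meta)
  required <- c("sample_id", "species", "individual", "group", "condition")
  missing_cols <- setdiff(required, names(meta))
  if (length(missing_cols) > 0) {
    abort(sprintf("metadata lacks column(s): %s",
                  paste(missing_cols, collapse = ", ")))
  }
  orphan <- setdiff(colnames(counts), meta$sample_id)
  if (length(orphan) > 0) {
    abort(sprintf("sample(s) in matrix missing from metadata: %s",
                  paste(orphan, collapse = ", ")))
  }
  meta <- meta[match(colnames(counts), meta$sample_id), , drop = FALSE]
  structure(list(counts = counts, meta = meta), class = "te_counts")
}

#' @export
dim.te_counts <- function(x) dim(x$counts)

#' @export
print.te_counts <- function(x, ...) {
  cat(sprintf("<te_counts> %d features x %d samples\n",
              nrow(x$counts), ncol(x$counts)))
  cat(sprintf("  species: %s\n",
              paste(unique(x$meta$species), collapse = ", ")))
  cat(sprintf("  groups:  %s\n",
              paste(unique(x$meta$group), collapse = ", ")))
  invisible(x)
}

#' @describeIn te_counts Long-format view: one row per (feature, sample).
#' @param x A `te_counts` object.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.te_counts <- function(x, ...) {
  wide <- as_tibble(x$counts, rownames = "feature_id")
  long <- tidyr::pivot_longer(wide, -"feature_id",
                              names_to = "sample_id", values_to = "count")
  left_join(long, x$meta, by = "sample_id")
}

count_matrix_of <- function(x) {
  if (inherits(x, "te_counts")) x$counts else as.matrix(x)
}

col_or <- function(d, nm, default) {
  if (nm %in% names(d)) d[[nm]] else default
}

read_tsv_quiet <- function(path, ...) {
  readr::read_tsv(path, comment = "#", show_col_types = FALSE,
                  progress = FALSE, ...)
}

#' Read a count matrix and its sample metadata
#'
#' Expects a TSV whose first column holds feature ids and whose remaining
#' column names are sample ids, plus a metadata TSV keyed by `sample_id`.
#' Lines starting with `#` are comments. Row and column order is preserved.
#' Malformed input (duplicate ids, negative or non-integer cells, samples
#' without metadata) is a hard error, never a silent drop.
#'
#' @param path Path to the count TSV.
#' @param meta_path Path to the metadata TSV (columns `sample_id`, `species`,
#'   `individual`, `group`, `condition`).
#' @return A [te_counts] object.
#' @export
read_count_matrix <- function(path, meta_path) {
  tab <- read_tsv_quiet(path)
  if (ncol(tab) < 2) abort("count matrix needs a feature column and >=1 sample")
  ids <- as.character(tab[[1]])
  mat <- as.matrix(tab[, -1, drop = FALSE])
  if (!is.numeric(mat)) {
    bad <- which(is.na(suppressWarnings(apply(tab[, -1], 2, as.numeric))),
                 arr.ind = TRUE)
    loc <- if (length(bad)) {
      sprintf(" (row %d, column '%s')", bad[1, 1],
              colnames(tab[, -1])[bad[1, 2]])
    } else ""
    abort(paste0("non-numeric count cell", loc))
  }
  bad <- which(mat < 0 | !is.finite(mat) | mat != round(mat), arr.ind = TRUE)
  if (nrow(bad) > 0) {
    abort(sprintf(
      "negative or non-integer count at row '%s', column '%s'",
      ids[bad[1, 1]], colnames(mat)[bad[1, 2]]
    ))
  }
  rownames(mat) <- ids
  meta <- read_tsv_quiet(meta_path)
  te_counts(mat, meta)
}

#' Write a count matrix (and optionally metadata) to TSV
#'
#' @param x A [te_counts] object or numeric matrix with dimnames.
#' @param path Output TSV path for counts.
#' @param meta_path Optional output path for the metadata TSV.
#' @return `path`, invisibly.
#' @export
write_count_matrix <- function(x, path, meta_path = NULL) {
  mat <- count_matrix_of(x)
  tab <- as_tibble(mat, rownames = "feature_id")
  readr::write_tsv(tab, path, progress = FALSE)
  if (!is.null(meta_path) && inherits(x, "te_counts")) {
    readr::write_tsv(x$meta, meta_path, progress = FALSE)
  }
  invisible(path)
}

#' Read a feature annotation table
#'
#' Columns: `feature_id`, `kind` (`gene` or `TE`), `te_class` (empty for
#' genes), `is_krab_znf` (logical), `length_bp` (>= 1), `age_mya`
#' (nonnegative; may be missing for features that cannot be dated, which are
#' excluded from age-classified analyses downstream with a warning there).
#'
#' @param path Path to the annotation TSV.
#' @return A tibble.
#' @export
read_feature_annotation <- function(path) {
  ann <- read_tsv_quiet(path)
  required <- c("feature_id", "kind", "te_class", "is_krab_znf",
                "length_bp", "age_mya")
  missing_cols <- setdiff(required, names(ann))
  if (length(missing_cols) > 0) {
    abort(sprintf("annotation lacks column(s): %s",
                  paste(missing_cols, collapse = ", ")))
  }
  validate_annotation(ann)
}

validate_annotation <- function(ann) {
  ann <- as_tibble(ann)
  ann$te_class[is.na(ann$te_class)] <- ""
  if (anyDuplicated(ann$feature_id)) {
    abort("duplicate feature_id in annotation")
  }
  if (!all(ann$kind %in% c("gene", "TE"))) {
    abort("annotation kind must be 'gene' or 'TE'")
  }
  if (any(ann$kind == "gene" & ann$te_class != "")) {
    abort("gene features must have empty te_class")
  }
  if (any(ann$kind == "TE" & ann$is_krab_znf)) {
    abort("TE features cannot be flagged as KRAB-ZNF")
  }
  if (any(ann$length_bp < 1)) abort("length_bp must be >= 1")
  if (any(!is.na(ann$age_mya) & ann$age_mya < 0)) {
    abort("age_mya must be nonnegative")
  }
  ann
}

#' Read a one-to-one ortholog map
#'
#' Columns: `feature_id_a`, `feature_id_b`, `length_a_bp`, `length_b_bp`,
#' `confidence` (`high` or `low`). Each feature may appear in at most one
#' row (one-to-one orthology).
#'
#' @param path Path to the ortholog-map TSV.
#' @return A tibble.
#' @export
read_ortholog_map <- function(path) {
  om <- read_tsv_quiet(path)
  required <- c("feature_id_a", "feature_id_b", "length_a_bp",
                "length_b_bp", "confidence")
  missing_cols <- setdiff(required, names(om))
  if (length(missing_cols) > 0) {
    abort(sprintf("ortholog map lacks column(s): %s",
                  paste(missing_cols, collapse = ", ")))
  }
  validate_ortholog_map(om)
}

validate_ortholog_map <- function(om) {
  om <- as_tibble(om)
  if (anyDuplicated(om$feature_id_a) || anyDuplicated(om$feature_id_b)) {
    abort("ortholog map must be one-to-one: a feature appears twice")
  }
  if (any(om$length_a_bp < 1) || any(om$length_b_bp < 1)) {
    abort("ortholog lengths must be >= 1")
  }
  if (!all(om$confidence %in% c("high", "low"))) {
    abort("ortholog confidence must be 'high' or 'low'")
  }
  om
}

#' Read a binding-evidence pair list
#'
#' A TSV with columns `gene_id` and `te_id`, one experimentally supported
#' (KRAB-ZNF, TE subfamily) pair per row. Duplicate pairs are an error.
#'
#' @param path Path to the TSV.
#' @return A tibble with columns `gene_id`, `te_id`.
#' @export
read_evidence_pairs <- function(path) {
  ev <- read_tsv_quiet(path)
  if (!all(c("gene_id", "te_id") %in% names(ev))) {
    abort("evidence file needs columns gene_id and te_id")
  }
  ev <- select(ev, "gene_id", "te_id")
  if (anyDuplicated(paste(ev$gene_id, ev$te_id, sep = "\r"))) {
    abort("duplicate evidence pair")
  }
  ev
}

#' Export a bipartite network as an edge-list TSV and GraphML
#'
#' The TSV holds one row per edge (`gene_id`, `te_id`, `r`, `padj`,
#' `link_class`, `module`); [read_edges()] reproduces the edge set exactly.
#' When `graphml_path` is given the network is additionally written as
#' GraphML with node attributes (class, module) and edge attributes
#' (r, padj, link_class).
#'
#' @param network A [build_network()] result.
#' @param path Output TSV path.
#' @param graphml_path Optional GraphML output path.
#' @return `path`, invisibly.
#' @export
write_edges <- function(network, path, graphml_path = NULL) {
  stopifnot(inherits(network, "bipartite_network"))
  ed <- network$edges
  part <- network$partition
  module_of <- function(ids) {
    if (is.null(part)) rep(NA_integer_, length(ids)) else unname(part[ids])
  }
  out <- tibble(
    gene_id = ed$gene_id, te_id = ed$te_id, r = ed$r,
    padj = col_or(ed, "padj", rep(NA_real_, nrow(ed))),
    link_class = col_or(ed, "link_class", rep(NA_character_, nrow(ed))),
    module = module_of(ed$gene_id)
  )
  readr::write_tsv(out, path, progress = FALSE)
  if (!is.null(graphml_path)) {
    g <- as_igraph(network)
    igraph::write_graph(g, graphml_path, format = "graphml")
  }
  invisible(path)
}

#' Read an edge-list TSV written by [write_edges()]
#'
#' @param path Path to the edge TSV.
#' @return A tibble with the exported edge columns.
#' @export
read_edges <- function(path) {
  ed <- read_tsv_quiet(
    path,
    col_types = readr::cols(
      gene_id = readr::col_character(), te_id = readr::col_character(),
      r = readr::col_double(), padj = readr::col_double(),
      link_class = readr::col_character(), module = readr::col_integer()
    )
  )
  if (anyDuplicated(paste(ed$gene_id, ed$te_id, sep = "\r"))) {
    abort("duplicate (gene, te) edge in file")
  }
  ed
}

as_igraph <- function(network) {
  nodes <- tibble(
    name = c(network$genes, network$tes),
    class = c(rep("gene", length(network$genes)),
              rep("TE", length(network$tes)))
  )
  if (!is.null(network$partition)) {
    nodes$module <- unname(network$partition[nodes$name])
  }
  ed <- network$edges
  edges <- tibble(from = ed$gene_id, to = ed$te_id, r = ed$r)
  if (!is.null(ed$padj)) edges$padj <- ed$padj
  if (!is.null(ed$link_class)) edges$link_class <- ed$link_class
  igraph::graph_from_data_frame(edges, directed = FALSE, vertices = nodes)
}
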