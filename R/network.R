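#' Build a bipartite gene-TE network from significant correlations
#'
#' Nodes are the genes and TEs appearing in the records; each record
#' becomes one edge weighted by its correlation coefficient. Records must
#' come from a single group and be deduplicated upstream; a duplicate
#' (gene, te) pair or an id occurring in both classes is an error.
#'
#' @param records Correlation records, typically
#'   `filter(correlate_all(...), significant)`; columns `gene_id`, `te_id`,
#'   `r`, optionally `padj` and `link_class`.
#' @return An object of class `"bipartite_network"`: list with `genes`,
#'   `tes`, `edges`, `partition` (NULL until [detect_modules()]),
#'   `modularity`.
#' @export
build_network <- function(records) {
  records <- as_tibble(records)
  if (anyDuplicated(pair_key(records))) {
    abort("duplicate (gene, te) pair in records")
  }
  genes <- sort(unique(records$gene_id))
  tes <- sort(unique(records$te_id))
  if (length(intersect(genes, tes)) > 0) {
    abort(sprintf("id(s) appear as both gene and TE: %s",
                  paste(intersect(genes, tes), collapse = ", ")))
  }
  edges <- tibble(
    gene_id = records$gene_id, te_id = records$te_id, r = records$r,
    padj = col_or(records, "padj", rep(NA_real_, nrow(records))),
    link_class = as.character(col_or(records, "link_class",
                                     rep(NA_character_, nrow(records))))
  )
  structure(
    list(genes = genes, tes = tes, edges = edges,
         partition = NULL, modularity = NA_real_),
    class = "bipartite_network"
  )
}

#' @export
print.bipartite_network <- function(x, ...) {
  cat(sprintf("<bipartite_network> %d genes, %d TEs, %d edges",
              length(x$genes), length(x$tes), nrow(x$edges)))
  if (!is.null(x$partition)) {
    cat(sprintf("; %d modules, Q_b = %.4f",
                length(unique(x$partition)), x$modularity))
  }
  cat("\n")
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.bipartite_network <- function(x, ...) {
  ed <- x$edges
  if (!is.null(x$partition)) {
    ed$module_gene <- unname(x$partition[ed$gene_id])
    ed$module_te <- unname(x$partition[ed$te_id])
  }
  ed
}

#' @exportS3Method generics::glance
glance.bipartite_network <- function(x, ...) {
  tibble(
    n_genes = length(x$genes), n_tes = length(x$tes),
    n_edges = nrow(x$edges),
    n_modules = if (is.null(x$partition)) {
      NA_integer_
    } else {
      length(unique(x$partition))
    },
    modularity = x$modularity
  )
}

# |r|-weighted biadjacency matrix, genes x TEs
biadjacency <- function(network) {
  a <- matrix(0, length(network$genes), length(network$tes),
              dimnames = list(network$genes, network$tes))
  ed <- network$edges
  a[cbind(ed$gene_id, ed$te_id)] <- abs(ed$r)
  a
}

#' Class-normalized degree of every node
#'
#' A gene's degree is divided by the number of TE nodes and vice versa, so
#' the two unequal node classes become comparable. Strength (sum of
#' absolute edge weights) and bipartite betweenness centrality are reported
#' alongside as node metadata; hub calling ([hubs()]) uses degree and
#' strength only.
#'
#' @param network A `bipartite_network`.
#' @return A tibble: `node_id`, `class`, `degree`, `strength`,
#'   `normalized_degree`, `betweenness`.
#' @export
normalized_degree <- function(network) {
  if (length(network$genes) + length(network$tes) == 0) {
    abort("empty network")
  }
  a <- biadjacency(network)
  btw <- if (nrow(network$edges) > 0) {
    g <- as_igraph(network)
    setNames(igraph::betweenness(g, directed = FALSE, weights = NA),
             igraph::V(g)$name)
  } else {
    setNames(rep(0, length(network$genes) + length(network$tes)),
             c(network$genes, network$tes))
  }
  out <- bind_rows(
    tibble(node_id = network$genes, class = "gene",
           degree = unname(rowSums(a > 0)), strength = unname(rowSums(a)),
           normalized_degree = unname(rowSums(a > 0)) /
             max(1, length(network$tes))),
    tibble(node_id = network$tes, class = "TE",
           degree = unname(colSums(a > 0)), strength = unname(colSums(a)),
           normalized_degree = unname(colSums(a > 0)) /
             max(1, length(network$genes)))
  )
  out$betweenness <- unname(btw[out$node_id])
  out
}

#' Hub nodes of a bipartite network
#'
#' Hubs are the nodes in the top `top_fraction` by bipartite degree *and*
#' by bipartite strength (intersection of the two lists, stricter than
#' either alone). The cutoff is the k-th largest value with
#' `k = max(1, floor(top_fraction * n_nodes))`; ties at the cutoff are all
#' included.
#'
#' @param network A `bipartite_network`.
#' @param top_fraction Fraction of nodes to rank as top. Default 0.05.
#' @return Character vector of hub node ids.
#' @export
hubs <- function(network, top_fraction = 0.05) {
  deg <- normalized_degree(network)
  if (nrow(deg) == 0) abort("empty network")
  k <- max(1L, floor(top_fraction * nrow(deg)))
  top_by <- function(v) {
    cutoff <- sort(v, decreasing = TRUE)[k]
    deg$node_id[v >= cutoff]
  }
  sort(intersect(top_by(deg$degree), top_by(deg$strength)))
}

#' Barber bipartite modularity
#'
#' Evaluates
#' \deqn{Q_b = \frac{1}{m}\sum_{g,t}\left(A_{gt} -
#'   \frac{k_g d_t}{m}\right)\delta(c_g, c_t)}
#' where `A` is the absolute-weight biadjacency matrix, `k`/`d` the
#' weighted degrees and `m` the total edge weight. The bipartite
#' configuration model is only defined for nonnegative weights, so edge
#' signs enter analyses as metadata (link classes), not here.
#'
#' @param network A `bipartite_network` with at least one edge.
#' @param partition Named vector (or list) mapping every node id to a
#'   module id.
#' @return The modularity value (<= 1).
#' @export
barber_modularity <- function(network, partition) {
  a <- biadjacency(network)
  m <- sum(a)
  if (m == 0) abort("modularity undefined: total edge weight is zero")
  partition <- unlist(partition)
  nodes <- c(network$genes, network$tes)
  if (!all(nodes %in% names(partition))) {
    abort("partition must assign every node")
  }
  cg <- as.character(partition[network$genes])
  ct <- as.character(partition[network$tes])
  k <- rowSums(a)
  d <- colSums(a)
  q <- 0
  for (mod in intersect(unique(cg), unique(ct))) {
    gi <- cg == mod
    ti <- ct == mod
    q <- q + sum(a[gi, ti, drop = FALSE]) - sum(k[gi]) * sum(d[ti]) / m
  }
  q / m
}

# Internal optimizer state helpers -----------------------------------------

# gene-side contribution of gene g to module mod (divided by m at the end)
module_score_gene <- function(a, k, d, ct, m, g, mod) {
  ti <- ct == mod
  if (!any(ti)) return(0)
  sum(a[g, ti]) - k[g] * sum(d[ti]) / m
}

module_score_te <- function(a, k, d, cg, m, t, mod) {
  gi <- cg == mod
  if (!any(gi)) return(0)
  sum(a[gi, t]) - sum(k[gi]) * d[t] / m
}

#' Detect modules maximizing Barber modularity
#'
#' Community detection in three phases: (1) an initial partition from
#' leading-eigenvector communities on the unipartite weighted projection
#' (nodes of one class connected when they share a neighbor, weight = sum
#' over shared neighbors of the smaller absolute correlation), with the
#' other class assigned greedily; (2) label sweeps over all nodes in fixed
#' lexicographic order accepting only moves that strictly increase Q_b,
#' until a full pass makes no move; (3) module merges that strictly
#' increase Q_b, interleaved with further sweeps until neither phase
#' improves. Singleton and all-in-one initializations are also tried and
#' the best final partition kept, which makes the search robust on small
#' graphs. Deterministic under a fixed seed and node order.
#'
#' @param network A `bipartite_network` with at least one edge.
#' @param seed Optional integer seed (leading-eigenvector initialization).
#' @return The network with `partition` (named integer vector over all
#'   nodes) and `modularity` filled in.
#' @export
detect_modules <- function(network, seed = NULL) {
  a <- biadjacency(network)
  m <- sum(a)
  if (m == 0) abort("cannot detect modules without edges")
  genes <- network$genes
  tes <- network$tes
  n <- length(genes) + length(tes)
  inits <- c(
    list(
      leading_eigen_init(network, a, seed),
      c(seq_along(genes), seq_along(tes) + length(genes)), # singletons
      rep(1L, n)                                           # one module
    ),
    # deterministic random restarts guard against local optima of the
    # greedy refinement, which matters mostly on small graphs
    withr::with_seed(seed %||% 1L, {
      lapply(seq_len(8), function(i) sample.int(max(2L, n %/% 2), n,
                                                replace = TRUE))
    })
  )
  best <- NULL
  best_q <- -Inf
  for (init in inits) {
    res <- refine_partition(a, init, length(genes))
    if (res$q > best_q + 1e-12) {
      best_q <- res$q
      best <- res$assign
    }
  }
  labels <- as.integer(factor(best, levels = unique(best)))
  network$partition <- setNames(labels, c(genes, tes))
  network$modularity <- barber_modularity(network, network$partition)
  network
}

leading_eigen_init <- function(network, a, seed) {
  n_gene <- nrow(a)
  n_te <- ncol(a)
  # gene-gene projection: weight = sum over shared TEs of min(|r|, |r'|)
  assign <- integer(n_gene + n_te)
  proj <- matrix(0, n_gene, n_gene)
  if (n_gene >= 2) {
    for (t in seq_len(n_te)) {
      w <- a[, t]
      pos <- which(w > 0)
      if (length(pos) >= 2) {
        proj[pos, pos] <- proj[pos, pos] + outer(w[pos], w[pos], pmin)
      }
    }
    diag(proj) <- 0
  }
  if (n_gene >= 2 && sum(proj) > 0) {
    g <- igraph::graph_from_adjacency_matrix(proj, mode = "undirected",
                                             weighted = TRUE)
    comm <- with_optional_seed(seed, {
      tryCatch(igraph::cluster_leading_eigen(g),
               error = function(e) NULL)
    })
    assign[seq_len(n_gene)] <- if (is.null(comm)) {
      seq_len(n_gene)
    } else {
      igraph::membership(comm)
    }
  } else {
    assign[seq_len(n_gene)] <- seq_len(n_gene)
  }
  # each TE joins the gene module with the largest weight to it
  next_mod <- max(assign[seq_len(n_gene)], 0) + 1L
  for (t in seq_len(n_te)) {
    nb <- which(a[, t] > 0)
    if (length(nb) == 0) {
      assign[n_gene + t] <- next_mod
      next_mod <- next_mod + 1L
    } else {
      w <- tapply(a[nb, t], assign[nb], sum)
      assign[n_gene + t] <- as.integer(names(w)[which.max(w)])
    }
  }
  assign
}

# Greedy Q_b refinement: single-node moves (including to a fresh module)
# then pairwise module merges, repeated to a fixed point.
refine_partition <- function(a, assign, n_gene) {
  m <- sum(a)
  k <- rowSums(a)
  d <- colSums(a)
  n_te <- ncol(a)
  n <- n_gene + n_te
  q_of <- function(as) {
    cg <- as[seq_len(n_gene)]
    ct <- as[n_gene + seq_len(n_te)]
    q <- 0
    for (mod in intersect(unique(cg), unique(ct))) {
      gi <- cg == mod
      ti <- ct == mod
      q <- q + sum(a[gi, ti, drop = FALSE]) - sum(k[gi]) * sum(d[ti]) / m
    }
    q / m
  }
  repeat {
    moved_any <- FALSE
    # ---- sweeps
    repeat {
      moved <- FALSE
      for (v in seq_len(n)) {
        is_gene <- v <= n_gene
        cur <- assign[v]
        cg <- assign[seq_len(n_gene)]
        ct <- assign[n_gene + seq_len(n_te)]
        if (is_gene) {
          nb_mods <- unique(ct[a[v, ] > 0])
          score <- function(mod) module_score_gene(a, k, d, ct, m, v, mod)
        } else {
          t <- v - n_gene
          nb_mods <- unique(cg[a[, t] > 0])
          score <- function(mod) module_score_te(a, k, d, cg, m, t, mod)
        }
        fresh <- max(assign) + 1L
        cand <- setdiff(unique(c(nb_mods, fresh)), cur)
        if (length(cand) == 0) next
        # scores are cross-class sums, so a node's own score never includes
        # same-class terms and the move gain is a plain difference
        cur_score <- score(cur)
        gains <- vapply(cand, function(mod) score(mod) - cur_score,
                        numeric(1))
        best <- which.max(gains)
        if (gains[best] > 1e-12) {
          assign[v] <- cand[best]
          moved <- TRUE
          moved_any <- TRUE
        }
      }
      if (!moved) break
    }
    # ---- merges
    mods <- unique(assign)
    best_gain <- 0
    best_pair <- NULL
    if (length(mods) >= 2) {
      cg <- assign[seq_len(n_gene)]
      ct <- assign[n_gene + seq_len(n_te)]
      for (i in seq_along(mods)) {
        for (j in seq_along(mods)) {
          if (i >= j) next
          g1 <- cg == mods[i]; t1 <- ct == mods[i]
          g2 <- cg == mods[j]; t2 <- ct == mods[j]
          gain <- (sum(a[g1, t2, drop = FALSE]) -
                     sum(k[g1]) * sum(d[t2]) / m +
                   sum(a[g2, t1, drop = FALSE]) -
                     sum(k[g2]) * sum(d[t1]) / m) / m
          if (gain > best_gain + 1e-12) {
            best_gain <- gain
            best_pair <- c(mods[i], mods[j])
          }
        }
      }
    }
    if (!is.null(best_pair)) {
      assign[assign == best_pair[2]] <- best_pair[1]
      moved_any <- TRUE
    }
    if (!moved_any) break
  }
  list(assign = assign, q = q_of(assign))
}

#' Module enrichment by Monte-Carlo Fisher test
#'
#' For every module and node category (e.g. TE family) the 2x2 table of
#' in-module vs out-of-module against category vs other is tested with a
#' Monte-Carlo Fisher exact test: `n_sim` tables are simulated under fixed
#' margins (hypergeometric draws) and the two-sided p is the plus-one-
#' corrected fraction of simulated tables at most as probable as the
#' observed one.
#'
#' @param network A `bipartite_network` with a partition (run
#'   [detect_modules()] first).
#' @param node_labels Named character vector mapping node ids to a
#'   category; nodes without a label are excluded.
#' @param n_sim Simulated tables per test. Default 1e6.
#' @param alpha Flagging threshold. Default 0.05.
#' @param seed Optional integer seed.
#' @return A tibble: `module`, `category`, counts, `odds`, `p`, `flagged`.
#' @export
module_enrichment <- function(network, node_labels, n_sim = 1e6,
                              alpha = 0.05, seed = NULL) {
  if (is.null(network$partition)) abort("run detect_modules() first")
  nodes <- names(network$partition)
  lab <- node_labels[nodes]
  keep <- !is.na(lab)
  nodes <- nodes[keep]
  lab <- unname(lab[keep])
  mods <- unname(network$partition[nodes])
  categories <- sort(unique(lab))
  if (length(categories) < 2) abort("need at least 2 categories")
  n_total <- length(nodes)
  with_optional_seed(seed, {
    purrr::map_dfr(sort(unique(mods)), function(mo) {
      in_mod <- mods == mo
      purrr::map_dfr(categories, function(cat) {
        in_cat <- lab == cat
        a <- sum(in_mod & in_cat)
        n_cat <- sum(in_cat)
        n_mod <- sum(in_mod)
        p <- mc_fisher_p(a, n_cat, n_total - n_cat, n_mod, n_sim)
        b <- n_cat - a
        c_ <- n_mod - a
        d_ <- n_total - n_cat - n_mod + a
        tibble(module = mo, category = cat,
               in_module = a, category_total = n_cat,
               module_size = n_mod, n = n_total,
               odds = (a * d_) / max(1, b * c_),
               p = p, flagged = p < alpha)
      })
    })
  })
}

# Two-sided Monte-Carlo Fisher p for a 2x2 table with margins
# (m successes, n failures, k drawn), observed successes a.
mc_fisher_p <- function(a, m, n, k, n_sim) {
  obs <- dhyper(a, m, n, k)
  sim <- rhyper(n_sim, m, n, k)
  (1 + sum(dhyper(sim, m, n, k) <= obs * (1 + 1e-7))) / (1 + n_sim)
}

#' Bipartite network plot
#'
#' Genes on the left, TEs on the right, edges colored by correlation sign;
#' node color shows the module when a partition is present.
#'
#' @param object A `bipartite_network`.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.bipartite_network <- function(object, ...) {
  pos <- bind_rows(
    tibble(node_id = object$genes, class = "gene", x = 0,
           y = seq_along(object$genes)),
    tibble(node_id = object$tes, class = "TE", x = 1,
           y = seq_along(object$tes) *
             max(1, length(object$genes)) / max(1, length(object$tes)))
  )
  if (!is.null(object$partition)) {
    pos$module <- factor(unname(object$partition[pos$node_id]))
  } else {
    pos$module <- factor(pos$class)
  }
  ed <- object$edges
  seg <- tibble(
    x = 0, xend = 1,
    y = pos$y[match(ed$gene_id, pos$node_id)],
    yend = pos$y[match(ed$te_id, pos$node_id)],
    sign = factor(ifelse(ed$r >= 0, "positive", "negative"))
  )
  ggplot2::ggplot() +
    ggplot2::geom_segment(
      data = seg,
      ggplot2::aes(x = .data$x, xend = .data$xend, y = .data$y,
                   yend = .data$yend, colour = .data$sign),
      alpha = 0.5) +
    ggplot2::geom_point(
      data = pos,
      ggplot2::aes(x = .data$x, y = .data$y, shape = .data$class,
                   fill = .data$module), size = 3, stroke = 0.3) +
    ggplot2::scale_shape_manual(values = c(gene = 21, TE = 22)) +
    ggplot2::scale_colour_manual(values = c(positive = "seagreen",
                                            negative = "brown")) +
    ggplot2::theme_void()
}
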