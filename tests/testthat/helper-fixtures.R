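# Shared fixtures and independent oracles used across the suite.

tiny_matrix <- function(n_feat = 6, n_samp = 4, seed = 1,
                        prefix = "F") {
  withr::with_seed(seed, {
    m <- matrix(rpois(n_feat * n_samp, 50), n_feat, n_samp,
                dimnames = list(paste0(prefix, seq_len(n_feat)),
                                paste0("s", seq_len(n_samp))))
    m
  })
}

tiny_meta <- function(sample_ids, species = "hs", group = "cortex",
                      condition = "control") {
  tibble::tibble(
    sample_id = sample_ids, species = species,
    individual = paste0("i", seq_along(sample_ids)),
    group = group, condition = condition
  )
}

small_spec <- function(...) {
  sim_spec(
    n_genes = 40, n_tes = 20, n_krabznf = 12,
    species = list(human = list(scaling_factor = 1, n_individuals = 4)),
    groups = "g1", samples_per_group = 6,
    n_planted = 4, target_r = 0.9, n_background = 100,
    seed = 42, ...
  )
}

# restricted-growth-string enumeration of all set partitions of n items
all_partitions <- function(n) {
  res <- list()
  rec <- function(prefix, mx) {
    if (length(prefix) == n) {
      res[[length(res) + 1]] <<- prefix
      return(invisible())
    }
    for (v in seq_len(mx + 1)) rec(c(prefix, v), max(mx, v))
  }
  rec(integer(0), 0L)
  res
}

# hand implementation of the BH step-up rule, independent of p.adjust
hand_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  out <- numeric(m)
  out[o] <- pmin(adj, 1)
  out
}

# build a correlation-record tibble directly
make_records <- function(gene_id, te_id, r, padj = 0.001, group = "g",
                         significant = TRUE) {
  tibble::tibble(
    gene_id = gene_id, te_id = te_id, r = r, n = 10L,
    p = padj, padj = padj, group = group, significant = significant
  )
}

random_bipartite_net <- function(n_gene, n_te, p_edge = 0.5, seed = 1) {
  withr::with_seed(seed, {
    repeat {
      a <- matrix(rbinom(n_gene * n_te, 1, p_edge) *
                    runif(n_gene * n_te, 0.4, 1), n_gene, n_te)
      if (sum(a) > 0) break
    }
    genes <- paste0("G", seq_len(n_gene))
    tes <- paste0("T", seq_len(n_te))
    idx <- which(a > 0, arr.ind = TRUE)
    build_network(tibble::tibble(
      gene_id = genes[idx[, 1]], te_id = tes[idx[, 2]], r = a[a > 0]
    ))
  })
}

# exhaustive maximum Barber modularity over all set partitions (<= 10 nodes);
# evaluates Q directly on the null-corrected matrix for speed
exhaustive_best_modularity <- function(net) {
  nodes <- c(net$genes, net$tes)
  ng <- length(net$genes)
  a <- matrix(0, ng, length(net$tes),
              dimnames = list(net$genes, net$tes))
  a[cbind(net$edges$gene_id, net$edges$te_id)] <- abs(net$edges$r)
  m <- sum(a)
  b <- (a - outer(rowSums(a), colSums(a)) / m) / m
  parts <- all_partitions(length(nodes))
  max(vapply(parts, function(p) {
    cg <- p[seq_len(ng)]
    ct <- p[ng + seq_along(net$tes)]
    sum(b[outer(cg, ct, "==")])
  }, numeric(1)))
}
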