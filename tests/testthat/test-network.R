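test_that("build_network collects nodes, edges and rejects bad input", {
  rec <- make_records(c("G1", "G1", "G2"), c("T1", "T2", "T1"),
                      r = c(0.5, -0.6, 0.7))
  net <- build_network(rec)
  expect_equal(length(net$genes) + length(net$tes), 4)
  expect_equal(nrow(net$edges), 3)

  empty <- build_network(rec[0, ])
  expect_equal(nrow(empty$edges), 0)

  expect_error(build_network(rec[c(1, 1), ]), "duplicate")
  bad <- make_records(c("G1", "T1"), c("T1", "G2"), r = c(0.5, 0.5))
  expect_error(build_network(bad), "both gene and TE")
})

test_that("normalized degree accounts for unequal class sizes", {
  rec <- make_records(rep("G1", 4), paste0("T", 1:4), r = rep(0.5, 4))
  net <- build_network(rec)
  deg <- normalized_degree(net)
  expect_equal(deg$normalized_degree[deg$node_id == "G1"], 1) # all TEs
  expect_equal(deg$normalized_degree[deg$node_id == "T1"], 1) # its one gene
  rec2 <- dplyr::bind_rows(
    make_records(paste0("G", 1:4), rep("T1", 4), r = rep(0.5, 4)),
    make_records(c("G1", "G2"), c("T2", "T2"), r = c(0.4, 0.4))
  )
  deg2 <- normalized_degree(build_network(rec2))
  expect_equal(deg2$normalized_degree[deg2$node_id == "T2"], 0.5)
})

test_that("hub rule: top fraction by degree AND strength, ties included", {
  # star: the center is the single hub
  star <- build_network(
    make_records(rep("G1", 20), paste0("T", 1:20), r = rep(0.5, 20))
  )
  expect_equal(hubs(star, 0.05), "G1")
  # regular graph: everything ties into the hub set
  ring <- build_network(make_records(
    c("G1", "G1", "G2", "G2"), c("T1", "T2", "T1", "T2"),
    r = rep(0.5, 4)
  ))
  expect_setequal(hubs(ring, 0.05), c("G1", "G2", "T1", "T2"))
  # planted single high-degree gene at 1%
  withr::local_seed(1)
  rec <- dplyr::bind_rows(
    make_records(rep("HUB", 30), paste0("T", 1:30), r = rep(0.8, 30)),
    make_records(paste0("G", 1:40), paste0("T", rep(31:50, 2)),
                 r = runif(40, 0.4, 0.6))
  )
  expect_equal(hubs(build_network(rec), 0.01), "HUB")
})

test_that("barber modularity matches closed-form worked examples", {
  one <- build_network(make_records("G1", "T1", r = 1))
  expect_equal(barber_modularity(one, c(G1 = 1, T1 = 1)), 0)
  two <- build_network(
    make_records(c("G1", "G2"), c("T1", "T2"), r = c(1, 1))
  )
  expect_equal(barber_modularity(two, c(G1 = 1, G2 = 2, T1 = 1, T2 = 2)),
               0.5)
  expect_equal(barber_modularity(two, c(G1 = 1, G2 = 1, T1 = 1, T2 = 1)), 0)
  expect_error(barber_modularity(two, c(G1 = 1)), "every node")
})

test_that("modularity is invariant to relabeling and weight scaling", {
  net <- random_bipartite_net(4, 5, seed = 2)
  nodes <- c(net$genes, net$tes)
  part <- setNames(rep(1:3, length.out = length(nodes)), nodes)
  q1 <- barber_modularity(net, part)
  relabeled <- setNames(c(7, 9, 8)[part], nodes)
  expect_equal(barber_modularity(net, relabeled), q1)
  scaled <- net
  scaled$edges$r <- scaled$edges$r * 0.25
  expect_equal(barber_modularity(scaled, part), q1)
})

test_that("two disconnected bicliques split into their components", {
  rec <- dplyr::bind_rows(
    make_records(rep(c("A1", "A2"), each = 3), rep(paste0("TA", 1:3), 2),
                 r = rep(0.9, 6)),
    make_records(rep(c("B1", "B2", "B3"), each = 2), rep(paste0("TB", 1:2), 3),
                 r = rep(0.9, 6))
  )
  net <- detect_modules(build_network(rec), seed = 1)
  part <- net$partition
  expect_equal(length(unique(part)), 2)
  expect_equal(length(unique(part[c("A1", "A2", "TA1", "TA2", "TA3")])), 1)
  expect_equal(length(unique(part[c("B1", "B2", "B3", "TB1", "TB2")])), 1)
  expect_true(part[["A1"]] != part[["B1"]])
})

test_that("a single biclique is one module with the closed-form Q_b", {
  rec <- make_records(rep(paste0("G", 1:2), each = 2),
                      rep(paste0("T", 1:2), 2), r = rep(1, 4))
  net <- detect_modules(build_network(rec), seed = 1)
  expect_equal(length(unique(net$partition)), 1)
  expect_equal(net$modularity,
               barber_modularity(net, net$partition))
  expect_equal(net$modularity, 0) # complete bipartite graph has Q_b = 0
})

test_that("detected modularity equals the exhaustive optimum on small graphs", {
  for (seed in 1:8) {
    ng <- sample(2:4, 1)
    nt <- sample(2:4, 1)
    net <- random_bipartite_net(ng, nt, p_edge = 0.5, seed = seed)
    best <- exhaustive_best_modularity(net)
    det <- detect_modules(net, seed = 1)
    expect_equal(det$modularity, best, tolerance = 1e-10)
  }
})

test_that("module enrichment recovers a planted category concentration", {
  # module 1: star of 10 Alu TEs; module 2: star of 10 mixed TEs
  rec <- dplyr::bind_rows(
    make_records(rep("G1", 10), paste0("TA", 1:10), r = rep(0.9, 10)),
    make_records(rep("G2", 10), paste0("TB", 1:10), r = rep(0.9, 10))
  )
  net <- detect_modules(build_network(rec), seed = 1)
  labels <- setNames(
    c(rep("Alu", 10), rep(c("L1", "ERVK"), 5)),
    c(paste0("TA", 1:10), paste0("TB", 1:10))
  )
  res <- module_enrichment(net, labels, n_sim = 2e4, alpha = 0.05, seed = 3)
  alu_mod <- unname(net$partition[["TA1"]])
  row <- res[res$module == alu_mod & res$category == "Alu", ]
  expect_true(row$flagged)
  expect_equal(row$in_module, 10)
})

test_that("Monte-Carlo Fisher p agrees with the exact test", {
  withr::local_seed(4)
  for (i in 1:10) {
    m <- sample(3:12, 1)
    n <- sample(3:12, 1)
    k <- sample(3:(m + n - 1), 1)
    a <- rhyper(1, m, n, k)
    tab <- matrix(c(a, m - a, k - a, n - k + a), 2)
    exact <- fisher.test(tab)$p.value
    mc <- tecnet:::mc_fisher_p(a, m, n, k, n_sim = 1e5)
    expect_lt(abs(mc - exact), 0.005)
  }
  # strongly diagonal table
  expect_lt(tecnet:::mc_fisher_p(10, 10, 10, 10, 1e5), 1e-3)
  expect_lt(abs(tecnet:::mc_fisher_p(10, 10, 10, 10, 1e5) -
                  fisher.test(matrix(c(10, 0, 0, 10), 2))$p.value), 5e-4)
})

test_that("network summaries and plots work", {
  net <- detect_modules(random_bipartite_net(3, 4, seed = 5), seed = 1)
  gl <- generics::glance(net)
  expect_equal(gl$n_genes, 3)
  expect_false(is.na(gl$modularity))
  td <- generics::tidy(net)
  expect_true(all(c("module_gene", "module_te") %in% names(td)))
  expect_s3_class(ggplot2::autoplot(net), "ggplot")
})
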