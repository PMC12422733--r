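test_that("pearson_r reproduces hand-computed values and errors cleanly", {
  expect_equal(pearson_r(c(1, 2, 3), c(2, 4, 6)), 1)
  expect_equal(pearson_r(c(1, 2, 3), c(3, 2, 1)), -1)
  # deviation products 4.0 over sqrt(5)*sqrt(5)
  expect_equal(pearson_r(c(1, 2, 3, 4), c(1, 3, 2, 4)), 0.8)
  expect_error(pearson_r(c(1, 1, 1), c(1, 2, 3)), "zero variance")
  expect_error(pearson_r(1:2, 1:2), "at least 3")
})

test_that("pearson_r is invariant to positive affine maps, flips sign", {
  withr::local_seed(1)
  x <- rnorm(20)
  y <- rnorm(20)
  r <- pearson_r(x, y)
  expect_equal(pearson_r(3 * x + 5, y), r)
  expect_equal(pearson_r(-2 * x + 1, y), -r)
  expect_equal(pearson_r(y, x), r)
})

test_that("correlation p-values agree with cor.test", {
  expect_equal(correlation_p(0, 10), 1)
  expect_equal(correlation_p(1, 5), 0)
  expect_lt(correlation_p(0.8, 30), 1e-6)
  withr::local_seed(2)
  for (i in 1:20) {
    n <- sample(4:40, 1)
    x <- rnorm(n)
    y <- rnorm(n)
    expect_equal(correlation_p(cor(x, y), n),
                 cor.test(x, y)$p.value, tolerance = 1e-12)
  }
  expect_error(correlation_p(0.5, 2), "n must be")
})

test_that("bh_adjust matches the hand step-up rule", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_adjust(0.2), 0.2)
  expect_equal(bh_adjust(rep(0.07, 4)), rep(0.07, 4))
  withr::local_seed(3)
  for (i in 1:25) {
    p <- runif(sample(1:40, 1))
    expect_equal(bh_adjust(p), hand_bh(p))
  }
  # permutation equivariance
  p <- runif(15)
  o <- sample(15)
  expect_equal(bh_adjust(p)[o], bh_adjust(p[o]))
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("correlate_all equals a naive double loop", {
  withr::local_seed(4)
  for (i in 1:20) {
    mat <- matrix(rnorm(30 * 10), 30, 10,
                  dimnames = list(paste0("F", 1:30), paste0("s", 1:10)))
    genes <- paste0("F", 1:20)
    tes <- paste0("F", 21:30)
    rec <- correlate_all(mat, genes, tes, presence_frac = 0)
    naive_r <- mapply(function(g, t) cor(mat[g, ], mat[t, ]),
                      rec$gene_id, rec$te_id)
    expect_lt(max(abs(rec$r - naive_r)), 1e-10)
    naive_p <- mapply(function(g, t) cor.test(mat[g, ], mat[t, ])$p.value,
                      rec$gene_id, rec$te_id)
    expect_lt(max(abs(rec$p - naive_p)), 1e-10)
    expect_equal(rec$padj, hand_bh(rec$p))
  }
})

test_that("a planted copula pair is significant; constant rows are dropped", {
  spec <- small_spec()
  sim <- simulate_dataset(spec)
  x <- sim$counts$human
  kz <- sim$annotation$feature_id[sim$annotation$is_krab_znf]
  tes <- sim$annotation$feature_id[sim$annotation$kind == "TE"]
  rec <- suppressMessages(correlate_all(x, kz, tes, group = "human"))
  pl <- sim$truth$planted_links
  planted_rec <- dplyr::semi_join(rec, pl, by = c("gene_id", "te_id"))
  expect_equal(nrow(planted_rec), nrow(pl))
  expect_true(all(planted_rec$significant))
  expect_true(all(sign(planted_rec$r) == sign(pl$target_r[
    match(paste(planted_rec$gene_id, planted_rec$te_id),
          paste(pl$gene_id, pl$te_id))])))

  m <- x$counts
  m["TE0001", ] <- 7 # constant TE row
  expect_warning(
    rec2 <- suppressMessages(correlate_all(m, kz, tes, presence_frac = 0)),
    "constant"
  )
  expect_false("TE0001" %in% rec2$te_id)
})

test_that("false-positive rate under an independent null is bounded", {
  withr::local_seed(5)
  mat <- matrix(rnbinom(100 * 24, mu = 100, size = 10), 100, 24,
                dimnames = list(paste0("F", 1:100), paste0("s", 1:24)))
  rec <- correlate_all(mat, paste0("F", 1:50), paste0("F", 51:100),
                       presence_frac = 0)
  bound <- 0.01 + 3 * sqrt(0.01 * 0.99 / 2500)
  expect_lte(mean(rec$significant), bound)
})

test_that("guard rails: sample count, empty and overlapping id sets", {
  mat <- tiny_matrix(6, 4)
  expect_error(correlate_all(mat[, 1:2], "F1", "F2"), "at least 3")
  expect_error(correlate_all(mat, character(), "F2"), "nonempty")
  expect_error(correlate_all(mat, c("F1", "F2"), c("F2", "F3")), "disjoint")
})

test_that("leave-one-out consensus keeps robust pairs only", {
  spec <- small_spec()
  sim <- simulate_dataset(spec)
  x <- sim$counts$human
  kz <- sim$annotation$feature_id[sim$annotation$is_krab_znf]
  tes <- sim$annotation$feature_id[sim$annotation$kind == "TE"]
  loo <- suppressMessages(leave_one_out_consensus(x, kz, tes))
  full <- suppressMessages(correlate_all(x, kz, tes))
  pl <- sim$truth$planted_links
  # strong planted pairs survive every subset
  expect_true(all(paste(pl$gene_id, pl$te_id) %in%
                    paste(loo$gene_id, loo$te_id)))
  # consensus is a subset of the full-sample records
  expect_true(all(paste(loo$gene_id, loo$te_id) %in%
                    paste(full$gene_id, full$te_id)))
})

test_that("an outlier-driven correlation is dropped by leave-one-out", {
  # 4 individuals x 3 samples; the pair only correlates through individual i4
  withr::local_seed(6)
  n <- 12
  ind <- rep(paste0("i", 1:4), each = 3)
  base <- rnbinom(n, mu = 60, size = 20)
  gene <- base
  te <- rnbinom(n, mu = 60, size = 20)
  # individual i4 has an extreme coordinated excursion in both features
  gene[ind == "i4"] <- gene[ind == "i4"] + c(300, 400, 500)
  te[ind == "i4"] <- te[ind == "i4"] + c(310, 390, 510)
  filler <- matrix(rnbinom(4 * n, mu = 50, size = 20), 4, n)
  mat <- rbind(GENE1 = gene, TE1 = te, filler)
  rownames(mat) <- c("GENE1", "TE1", paste0("X", 1:4))
  colnames(mat) <- paste0("s", 1:n)
  full <- correlate_all(mat, "GENE1", "TE1", presence_frac = 0,
                        cor_alpha = 0.05)
  expect_true(abs(full$r) > 0.4)
  loo <- leave_one_out_consensus(
    mat, "GENE1", "TE1",
    sample_individuals = setNames(ind, colnames(mat)),
    presence_frac = 0, cor_alpha = 0.05
  )
  expect_equal(nrow(loo), 0)
})

test_that("leave-one-out needs 3+ individuals and viable subsets", {
  mat <- tiny_matrix(4, 4)
  ind <- setNames(c("i1", "i1", "i2", "i2"), colnames(mat))
  expect_error(
    leave_one_out_consensus(mat, "F1", "F2", sample_individuals = ind),
    "at least 3 individuals"
  )
})
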