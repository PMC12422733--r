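test_that("age classification puts the boundary in the young class", {
  expect_equal(as.character(age_class(44.2)), "young")
  expect_equal(as.character(age_class(44.2000001)), "old")
  expect_equal(as.character(age_class(90)), "old")
  expect_equal(as.character(age_class(0)), "young")
  expect_error(age_class(-1), "nonnegative")
})

test_that("link classes cover the full sign-by-age truth table", {
  cases <- tidyr::expand_grid(
    sign = c(1, -1),
    gene_age = c("young", "old"),
    te_age = c("young", "old")
  )
  got <- as.character(
    link_class(0.5 * cases$sign, cases$gene_age, cases$te_age)
  )
  # young iff any endpoint young; P iff r > 0
  want <- paste0(
    ifelse(cases$sign > 0, "P-", "N-"),
    ifelse(cases$gene_age == "young" | cases$te_age == "young", "Y", "O")
  )
  expect_equal(got, want)
  expect_equal(as.character(link_class(0.6, "old", "old")), "P-O")
  expect_equal(as.character(link_class(-0.5, "old", "young")), "N-Y")
  expect_equal(as.character(link_class(-0.41, "young", "young")), "N-Y")
  expect_error(link_class(0, "old", "old"), "r = 0")
})

test_that("classify_links excludes undatable endpoints with a warning", {
  rec <- make_records(c("G1", "G2", "G3"), c("T1", "T2", "T3"),
                      r = c(0.5, -0.5, 0.6))
  ann <- tibble::tibble(
    feature_id = c("G1", "G2", "G3", "T1", "T2", "T3"),
    age_mya = c(10, 100, 50, 60, 30, NA)
  )
  expect_warning(out <- classify_links(rec, ann), "undated")
  expect_equal(nrow(out), 2)
  expect_equal(as.character(out$link_class), c("P-Y", "N-Y"))
})

test_that("family composition test flags a skewed family", {
  # Alu and L1 uniform over the four classes; SVA entirely N-Y
  n <- 270
  cycle_r <- rep(c(0.5, 0.5, -0.5, -0.5), 60)
  cycle_age <- rep(c("old", "young", "old", "young"), 60)
  rec <- make_records(paste0("G", 1:n), paste0("T", 1:n),
                      r = c(cycle_r, rep(-0.5, 30)))
  te_age <- c(cycle_age, rep("young", 30))
  ann <- tibble::tibble(
    feature_id = c(paste0("G", 1:n), paste0("T", 1:n)),
    age_mya = c(rep(100, n), ifelse(te_age == "young", 10, 100))
  )
  cl <- classify_links(rec, ann)
  fam <- setNames(c(rep("Alu", 120), rep("L1", 120), rep("SVA", 30)),
                  paste0("T", 1:n))
  res <- family_class_test(cl, fam, seed = 1)
  sva <- res[res$family == "SVA", ]
  expect_true(sva$flagged)
  # independent hand computation of the 2x4 chi-squared statistic
  tab <- rbind(c(0, 0, 0, 30), c(60, 60, 60, 60))
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  chi2_hand <- sum((tab - expected)^2 / expected)
  expect_equal(sva$chi2, chi2_hand, tolerance = 1e-8)
  expect_lt(sva$p, 0.001)
  # a family matching the background closely is not flagged
  expect_false(res$flagged[res$family == "Alu"])
  expect_false(res$flagged[res$family == "L1"])
})

test_that("sparse families fall back to a Monte-Carlo p", {
  rec <- make_records(paste0("G", 1:42), paste0("T", 1:42),
                      r = c(rep(0.5, 40), -0.5, -0.5))
  ann <- tibble::tibble(
    feature_id = c(paste0("G", 1:42), paste0("T", 1:42)),
    age_mya = 100
  )
  cl <- classify_links(rec, ann)
  fam <- setNames(c(rep("L1", 40), rep("ERVK", 2)), paste0("T", 1:42))
  res <- family_class_test(cl, fam, mc_reps = 2e4, seed = 2)
  expect_true(all(res$method == "monte-carlo"))
  # the two-table simulated p agrees with Fisher's exact on this 2x2
  tab <- rbind(c(40, 0), c(0, 2))
  exact <- fisher.test(tab)$p.value
  expect_equal(res$p[res$family == "ERVK"], exact, tolerance = 0.02)
})

test_that("per-family class tables sum to the global class table", {
  withr::local_seed(3)
  n <- 80
  rec <- make_records(paste0("G", 1:n), paste0("T", 1:n),
                      r = sample(c(-0.5, 0.5), n, TRUE))
  ann <- tibble::tibble(
    feature_id = c(paste0("G", 1:n), paste0("T", 1:n)),
    age_mya = sample(c(10, 100), 2 * n, TRUE)
  )
  cl <- classify_links(rec, ann)
  fam <- setNames(sample(c("Alu", "L1", "SVA"), n, TRUE), paste0("T", 1:n))
  res <- family_class_test(cl, fam, seed = 4)
  class_cols <- c("P-O", "P-Y", "N-O", "N-Y")
  per_family_total <- colSums(as.matrix(res[, class_cols]))
  global <- table(factor(cl$link_class, levels = class_cols))
  expect_equal(unname(per_family_total), as.vector(global))
})
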