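test_that("conserved null probability follows the length/library formula", {
  expect_equal(conserved_null_prob(1000, 1000, 1e6, 1e6, f = 1), 0.5)
  expect_equal(conserved_null_prob(1000, 1000, 1e6, 1e6, f = 3), 0.75)
  # lenA = 1000, lenB = 500, NB = 2 NA: the products cancel
  expect_equal(conserved_null_prob(1000, 500, 1e6, 2e6, f = 1), 0.5)
  expect_error(conserved_null_prob(1, 1, 1, 1, f = 0), "f must be")
})

test_that("vectorized exact binomial p matches binom.test", {
  withr::local_seed(7)
  for (i in 1:60) {
    n <- sample(c(1:50, sample(5000, 1)), 1)
    p <- runif(1, 0.01, 0.99)
    x <- rbinom(1, n, p)
    expect_equal(tecnet:::binom_two_sided_p(x, n, p),
                 binom.test(x, n, p)$p.value, tolerance = 1e-12)
  }
})

test_that("equal expression gives a scaling factor near 1", {
  withr::local_seed(1)
  mu <- rlnorm(300, log(200), 0.8)
  len <- runif(300, 500, 2000)
  sr <- estimate_scaling_factor(rpois(300, mu), rpois(300, mu),
                                len, len, 1e6, 1e6)
  expect_s3_class(sr, "scaling_result")
  expect_equal(sr$factor, 1, tolerance = 0.05)
  expect_true(sr$factor %in% sr$grid)
  # scaling-result invariant: selected point minimizes the objective
  expect_equal(abs(sr$empirical_t1[sr$grid == sr$factor] - sr$alpha),
               min(abs(sr$empirical_t1 - sr$alpha)))
})

test_that("doubled expression gives a scaling factor near 2", {
  withr::local_seed(2)
  mu <- rlnorm(300, log(200), 0.8)
  len <- runif(300, 500, 2000)
  sr <- estimate_scaling_factor(rpois(300, mu), rpois(300, 2 * mu),
                                len, len, 1e6, 1e6)
  expect_equal(sr$factor, 2, tolerance = 0.05)
})

test_that("scaling factor is recovered from Poisson simulations", {
  for (seed in 1:3) {
    withr::local_seed(seed)
    ng <- 500
    e <- rlnorm(ng, log(50), 1)
    len_a <- runif(ng, 500, 3000)
    len_b <- len_a * runif(ng, 0.9, 1.1)
    lib_a <- 1e6
    lib_b <- 2e6
    f_true <- 1.5
    scale_to <- function(mu, tot) mu / sum(mu) * tot
    xa <- rpois(ng, scale_to(e * len_a, 2e5))
    xb <- rpois(ng, f_true * (lib_b / lib_a) * scale_to(e * len_b, 2e5) *
                  sum(e * len_b) / sum(e * len_a))
    sr <- estimate_scaling_factor(xa, xb, len_a, len_b, lib_a, lib_b)
    expect_lt(abs(sr$factor / f_true - 1), 0.1)
  }
})

test_that("empirical type I error curve matches a naive per-feature loop", {
  withr::local_seed(3)
  ng <- 40
  xa <- rpois(ng, 100)
  xb <- rpois(ng, 150)
  len_a <- runif(ng, 500, 1500)
  len_b <- runif(ng, 500, 1500)
  sr <- estimate_scaling_factor(xa, xb, len_a, len_b, 5e5, 7e5,
                                grid_size = 21)
  naive <- vapply(sr$grid, function(f) {
    mean(vapply(seq_len(ng), function(i) {
      p0 <- f * 7e5 * len_b[i] / (5e5 * len_a[i] + f * 7e5 * len_b[i])
      binom.test(xb[i], xa[i] + xb[i], p0)$p.value < sr$alpha
    }, logical(1)))
  }, numeric(1))
  expect_equal(sr$empirical_t1, naive)
})

test_that("apply_scaling divides species-B values and preserves totals", {
  m <- tiny_matrix(4, 3)
  x <- te_counts(m, tiny_meta(colnames(m)))
  expect_equal(apply_scaling(x, 1)$counts, m)
  half <- apply_scaling(x, 2)
  expect_equal(half$counts["F1", "s1"], m["F1", "s1"] / 2)
  expect_equal(sum(half$counts), sum(m) / 2)
})

test_that("degenerate conserved sets error; all-zero features are dropped", {
  expect_error(
    estimate_scaling_factor(rpois(5, 10), rpois(5, 10),
                            rep(1000, 5), rep(1000, 5), 1e6, 1e6),
    "conserved features"
  )
  withr::local_seed(4)
  x <- c(rpois(30, 100), 0, 0)
  y <- c(rpois(30, 100), 0, 0)
  expect_warning(
    sr <- estimate_scaling_factor(x, y, rep(1000, 32), rep(1000, 32),
                                  1e6, 1e6),
    "all-zero"
  )
  expect_equal(sr$n_conserved, 30)
})

test_that("TE scaling uses only homologous superfamilies present in both", {
  withr::local_seed(5)
  ann <- tibble::tibble(
    feature_id = c(paste0("TE", 1:40), "SAT1"),
    kind = "TE",
    te_class = c(rep(c("Alu", "L1", "ERVK", "TcMar-Tigger"), 10),
                 "Satellite"),
    is_krab_znf = FALSE, length_bp = round(runif(41, 200, 5000)),
    age_mya = 50
  )
  cnt <- matrix(rpois(41 * 4, 100), 41, 4,
                dimnames = list(ann$feature_id, paste0("s", 1:4)))
  # satellite row and a TE absent in species B must be excluded
  b <- cnt[setdiff(rownames(cnt), "TE1"), , drop = FALSE]
  colnames(b) <- paste0("t", 1:4)
  sr <- estimate_te_scaling(cnt, b, ann)
  expect_equal(sr$n_conserved, 39) # 40 TEs - absent TE1; satellite excluded
  expect_equal(sr$factor, 1, tolerance = 0.1)
})

test_that("tidy and glance expose the calibration grid", {
  withr::local_seed(6)
  x <- rpois(50, 100)
  sr <- estimate_scaling_factor(x, x, rep(1000, 50), rep(1000, 50),
                                1e6, 1e6, grid_size = 11)
  td <- generics::tidy(sr)
  expect_equal(nrow(td), 11)
  expect_equal(sum(td$selected), 1)
  gl <- generics::glance(sr)
  expect_equal(gl$factor, sr$factor)
  expect_s3_class(ggplot2::autoplot(sr), "ggplot")
})
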