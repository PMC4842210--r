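test_that("nmt_normalize divides by the maximum absolute column mean", {
  m <- matrix(c(2, -4, 1), 3, 1, dimnames = list(NULL, "t"))
  expect_equal(as.numeric(nmt_normalize(m)), c(0.5, -1, 0.25))
  expect_equal(as.numeric(nmt_normalize(matrix(-7, 1, 1))), -1)

  set.seed(5)
  big <- matrix(rnorm(60), 10, 6)
  nm <- nmt_normalize(big)
  expect_true(all(nm >= -1 & nm <= 1))
  expect_true(all(apply(abs(nm), 2, max) == 1))
  # idempotence
  expect_equal(nmt_normalize(nm), nm)

  bad <- cbind(big, 0)
  expect_error(nmt_normalize(bad), "all-zero")
})

# exhaustive permutation oracle computing U by pairwise comparison on every
# label split (independent of the package's rank-based route)
mwu_perm_oracle <- function(x, y) {
  pooled <- c(x, y)
  n1 <- length(x)
  u_stat <- function(a, b)
    sum(outer(a, b, ">")) + 0.5 * sum(outer(a, b, "=="))
  u_obs <- u_stat(x, y)
  mu <- n1 * length(y) / 2
  splits <- utils::combn(length(pooled), n1)
  u_all <- apply(splits, 2, function(idx)
    u_stat(pooled[idx], pooled[-idx]))
  mean(abs(u_all - mu) >= abs(u_obs - mu) - 1e-9)
}

test_that("term_significance matches the exact permutation oracle", {
  # frozen: {1..5} vs {11..15} has the extreme split on both tails: 2/252
  res <- term_significance(1:5, 11:15)
  expect_equal(res$p_value, 2 / 252, tolerance = 1e-12)
  expect_true(res$significant)
  expect_equal(res$mean_ratio, 3 / 13)

  # identical groups are never significant
  same <- term_significance(c(5, 5, 5), c(5, 5, 5))
  expect_false(same$significant)

  # symmetry under argument swap
  set.seed(1)
  x <- rnorm(6); y <- rnorm(7)
  a <- term_significance(x, y); b <- term_significance(y, x)
  expect_equal(a$p_value, b$p_value)
  expect_equal(a$mean_ratio, 1 / b$mean_ratio)

  # property: exact path equals enumeration for sizes <= 7, with ties
  set.seed(77)
  for (k in 1:30) {
    n1 <- sample(3:7, 1); n2 <- sample(3:7, 1)
    x <- sample(1:6, n1, replace = TRUE)
    y <- sample(1:6, n2, replace = TRUE)
    expect_equal(mann_whitney_u(x, y)$p_value, mwu_perm_oracle(x, y),
                 tolerance = 1e-12)
  }
})

test_that("significance is invariant under monotone transforms of a term", {
  set.seed(8)
  x <- rnorm(10, 1); y <- rnorm(12, 2)
  p1 <- mann_whitney_u(x, y)$p_value
  expect_equal(mann_whitney_u(exp(x), exp(y))$p_value, p1)
  expect_equal(mann_whitney_u(x^3, y^3)$p_value, p1)
})

test_that("pearson matches closed form and the stats oracle", {
  x <- 1:10
  expect_equal(pearson(x, 2 * x + 1)$r, 1)
  expect_equal(pearson(x, -x)$r, -1)
  expect_equal(pearson(x, 2 * x + 1)$p_value, 0)

  set.seed(12)
  a <- rnorm(10); b <- a * 0.5 + rnorm(10)
  mine <- pearson(a, b)
  oracle <- stats::cor.test(a, b)
  expect_equal(mine$r, unname(oracle$estimate), tolerance = 1e-12)
  expect_equal(mine$p_value, oracle$p.value, tolerance = 1e-12)

  expect_error(pearson(rep(1, 5), 1:5), "zero variance")
  expect_error(pearson(1:4, 1:5), "mismatch")
})

test_that("significance_matrix has the right shape and flags", {
  set.seed(31)
  make_tab <- function(shift) {
    data.frame(label = rep(c("proper", "mirror"), each = 8),
               good = c(rnorm(8), rnorm(8) + shift),
               noise = rnorm(16),
               ref = 5.5)
  }
  tabs <- list(d1 = make_tab(4), d2 = make_tab(5), d3 = make_tab(3.5))
  sig <- significance_matrix(tabs)
  expect_equal(dim(sig$significant), c(3L, 3L))
  expect_equal(colnames(sig$significant), c("good", "noise", "ref"))
  expect_true(all(sig$significant[, "good"]))
  expect_false(any(sig$significant[, "ref"]))  # constant column
  expect_true(all(sig$p_value >= 0 & sig$p_value <= 1))

  expect_error(significance_matrix(list(d1 = data.frame(
    label = c("proper", "proper", "mirror"), t = 1:3))), ">= 3")
})

test_that("domain_summaries aggregates groups and significance counts", {
  tab <- data.frame(
    label = rep(c("proper", "mirror"), each = 4),
    rmsd_to_ref = c(2, 3, 2.5, 2.5, 2, 3, 2.5, 2.5),
    phi_plus_ratio = c(rep(0.05, 4), rep(0.95, 4)),
    rama = c(1, 2, 1, 2, 8, 9, 8, 9))
  tabs <- list(dA = tab)
  sig <- significance_matrix(tabs)
  summ <- domain_summaries(tabs, sig)
  expect_equal(summ$structural_difference, 1.0)  # equal group mean RMSD
  expect_equal(summ$phi_plus_ratio_proper, 0.05)
  expect_equal(summ$n_significant_terms, sum(sig$significant["dA", ]))
})
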