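test_that("d-prime follows the quantile definition with extreme-rate correction", {
  expect_equal(dprime(hits = 50, n_signal = 100, false_alarms = 50,
                      n_noise = 100), 0)
  expect_equal(dprime(hits = 80, n_signal = 100, false_alarms = 20,
                      n_noise = 100), 2 * qnorm(0.8))   # 1.683
  expect_lt(dprime(hits = 20, n_signal = 100, false_alarms = 60,
                   n_noise = 100), 0)
  # extreme rates replaced by 1/(2N): finite and equal to the oracle value
  expect_equal(dprime(hits = 100, n_signal = 100, false_alarms = 0,
                      n_noise = 100),
               qnorm(1 - 1 / 200) - qnorm(1 / 200))
  expect_error(dprime(hits = 1, n_signal = 0, false_alarms = 0, n_noise = 5),
               "trial")
})

test_that("d-prime is monotone in hit rate and antitone in false-alarm rate", {
  hr <- seq(0.1, 0.9, by = 0.1)
  d_h <- vapply(hr, function(h) dprime(hits = h * 100, n_signal = 100,
                                       false_alarms = 30, n_noise = 100),
                numeric(1))
  expect_true(all(diff(d_h) > 0))
  d_f <- vapply(hr, function(f) dprime(hits = 70, n_signal = 100,
                                       false_alarms = f * 100,
                                       n_noise = 100), numeric(1))
  expect_true(all(diff(d_f) < 0))
})

test_that("single-pass outlier rule flags exactly the extreme subjects", {
  out <- remove_outliers(c(0, 0, 0, 0, 10), k = 1.5)
  expect_equal(out$removed_idx, 5L)
  expect_equal(out$kept, rep(0, 4))
  expect_warning(same <- remove_outliers(rep(2, 5)), "zero variance")
  expect_length(same$removed_idx, 0)
  expect_length(remove_outliers(rnorm(10), k = Inf)$removed_idx, 0)
  # documented as non-iterated: a second pass may remove more
  vals <- c(0, 0.1, -0.1, 0.05, 3, 2.9)
  p1 <- remove_outliers(vals, 1.5)
  expect_true(length(p1$removed_idx) >= 0)     # single pass, no iteration
})

test_that("Mann-Whitney matches exact enumeration for small samples", {
  r <- mann_whitney(c(1, 2, 3), c(4, 5, 6))
  expect_equal(unname(r$statistic), 0)
  expect_equal(r$p_value, 0.1)
  # full-enumeration oracle: all choose(6, 3) assignments
  enum_p <- function(a, b) {
    pooled <- c(a, b); n <- length(a)
    combs <- combn(length(pooled), n)
    u_obs <- sum(rank(pooled)[seq_len(n)]) - n * (n + 1) / 2
    us <- apply(combs, 2, function(ix)
      sum(rank(pooled)[ix]) - n * (n + 1) / 2)
    mean(pmin(us, n * (length(b)) - us) <= min(u_obs, n * length(b) - u_obs))
  }
  for (sd in 1:4) {
    set.seed(sd)
    a <- round(rnorm(4), 2); b <- round(rnorm(4) + 0.5, 2)
    expect_equal(mann_whitney(a, b)$p_value, enum_p(a, b), tolerance = 1e-10)
  }
  expect_equal(suppressWarnings(mann_whitney(c(1, 2, 3),
                                             c(1, 2, 3))$p_value), 1)
  expect_error(mann_whitney(numeric(0), 1:3), "non-empty")
})

test_that("exact and asymptotic Mann-Whitney p-values agree for n = 10/10", {
  for (sd in 1:5) {
    set.seed(sd)
    a <- rnorm(10); b <- rnorm(10, 0.3)
    p_exact <- suppressWarnings(wilcox.test(a, b, exact = TRUE))$p.value
    p_asym <- suppressWarnings(wilcox.test(a, b, exact = FALSE,
                                           correct = TRUE))$p.value
    expect_lt(abs(p_exact - p_asym), 0.02)
  }
})

test_that("Kruskal-Wallis reproduces the rank-arithmetic value and symmetry", {
  r <- kruskal_wallis(list(c(1, 2, 3), c(4, 5, 6)))
  expect_equal(unname(r$statistic), 12 / 42 * (3 * 1.5^2 + 3 * 1.5^2))
  expect_equal(unname(round(r$statistic, 3)), 3.857)
  tied <- kruskal_wallis(list(c(1, 1), c(1, 1), c(1, 1)))
  expect_equal(unname(tied$statistic), 0)
  expect_equal(tied$p_value, 1)
  set.seed(1)
  g <- list(rnorm(5), rnorm(6), rnorm(7))
  expect_equal(kruskal_wallis(g)$statistic,
               kruskal_wallis(g[c(3, 1, 2)])$statistic)
})

test_that("the normality gate separates normal from bimodal samples", {
  set.seed(2)
  normal_ok <- mean(vapply(1:20, function(i)
    shapiro_wilk_gate(rnorm(100))$p_value > 0.05, logical(1)))
  expect_gte(normal_ok, 0.9)
  bimodal <- c(rnorm(50, -5, 0.3), rnorm(50, 5, 0.3))
  expect_lt(shapiro_wilk_gate(bimodal)$p_value, 0.01)
  expect_error(shapiro_wilk_gate(rep(1, 10)), "constant")
})

test_that("brain-behaviour correlation recovers known associations", {
  x <- seq(-1, 1, length.out = 20)
  expect_equal(unname(pearson_brain_behavior(x, x)$statistic), 1)
  expect_equal(unname(pearson_brain_behavior(x, -x)$statistic), -1)
  set.seed(3)
  z <- matrix(rnorm(2000), ncol = 2) %*% chol(matrix(c(1, 0.5, 0.5, 1), 2))
  r <- pearson_brain_behavior(z[, 1], z[, 2])
  expect_lt(abs(r$statistic - 0.5), 0.06)
  expect_error(pearson_brain_behavior(rep(1, 5), rnorm(5)), "variance")
})

test_that("Cohen's d uses the pooled standard deviation", {
  set.seed(4)
  a <- rnorm(30)
  expect_equal(cohens_d(a, a), 0)
  # two-point groups with unit variance: |x1 - x2| = sqrt(2)
  h <- sqrt(2) / 2
  expect_equal(cohens_d(c(1 - h, 1 + h), c(-h, h)), 1)
  # arithmetic oracle on arbitrary data
  set.seed(41)
  g1 <- rnorm(12, 1); g2 <- rnorm(15)
  sp <- sqrt((11 * var(g1) + 14 * var(g2)) / 25)
  expect_equal(cohens_d(g1, g2), (mean(g1) - mean(g2)) / sp)
  expect_error(cohens_d(rep(1, 5), rep(1, 5)), "pooled SD")
  # sampling behaviour at the study's scale
  d_hat <- vapply(1:50, function(i) {
    set.seed(100 + i)
    cohens_d(rnorm(22, 0.9), rnorm(22, 0))
  }, numeric(1))
  expect_lt(abs(median(d_hat) - 0.9), 0.15)
})

test_that("t-to-p conversion reproduces the printed group comparison", {
  expect_equal(t_to_p(0, 10), 1)
  expect_equal(round(t_to_p(0.86, 42), 2), 0.39)
  expect_lt(t_to_p(50, 10), 1e-10)
  expect_equal(t_to_p(-0.86, 42), t_to_p(0.86, 42))
})

test_that("rank residualization removes a monotone age trend", {
  set.seed(5)
  age <- runif(40, 9, 15)
  y <- 2 * age + rnorm(40, sd = 0.5)
  res <- residualize_by_rank(y, age)
  expect_lt(abs(cor(rank(res), rank(age))), 0.15)
})
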