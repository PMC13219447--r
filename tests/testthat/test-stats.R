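test_that("the unpaired t-test matches hand-computed values", {
  # identical groups
  same <- unpaired_t_test(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)

  # frozen closed-form case: pooled t on {1,2,3} vs {2,3,4}
  tt <- unpaired_t_test(c(1, 2, 3), c(2, 3, 4))
  expect_equal(tt$statistic, -1 / sqrt(2 / 3), tolerance = 1e-6) # -1.224745
  expect_equal(tt$df, 4)
  expect_equal(tt$p_value, 0.2878641, tolerance = 1e-6)
  expect_equal(tt$stars, "ns")

  # degenerate zero-variance groups
  zv <- unpaired_t_test(c(2, 2, 2), c(5, 5, 5))
  expect_true(is.infinite(zv$statistic))
  expect_equal(zv$p_value, 0)

  # symmetry under group exchange; affine invariance
  a <- c(1.2, 3.1, 2.2, 4.5); b <- c(2.0, 2.5, 5.1, 3.3)
  expect_equal(unpaired_t_test(a, b)$p_value, unpaired_t_test(b, a)$p_value)
  expect_equal(unpaired_t_test(2 * a + 3, 2 * b + 3)$p_value,
               unpaired_t_test(a, b)$p_value, tolerance = 1e-12)

  expect_error(unpaired_t_test(1, c(1, 2)), "at least 2")
})

test_that("type-I error under the null sits at the nominal level", {
  set.seed(71)
  reps <- 10000
  rej <- 0
  crit <- qt(0.975, df = 8)
  for (i in seq_len(reps)) {
    x <- rnorm(5); y <- rnorm(5)
    # pooled t computed directly for speed; identical to unpaired_t_test
    sp <- sqrt((4 * var(x) + 4 * var(y)) / 8)
    t <- (mean(x) - mean(y)) / (sp * sqrt(2 / 5))
    rej <- rej + (abs(t) > crit)
  }
  expect_lt(abs(rej / reps - 0.05), 0.01)
  # spot-check the shortcut against the package function
  set.seed(72)
  x <- rnorm(5); y <- rnorm(5)
  sp <- sqrt((4 * var(x) + 4 * var(y)) / 8)
  expect_equal(unpaired_t_test(x, y)$statistic,
               (mean(x) - mean(y)) / (sp * sqrt(2 / 5)), tolerance = 1e-12)
})

test_that("ANOVA with Tukey HSD matches an independent studentized-range oracle", {
  groups <- list(a = c(1.1, 2.3, 1.8, 2.9), b = c(3.7, 4.1, 5.0, 4.4),
                 c = c(1.9, 2.2, 3.1, 2.5))
  res <- anova_tukey(groups)
  expect_equal(sort(unname(tidy(res)$adj_p_value)), sort(unname(oracle_tukey_p(groups))),
               tolerance = 1e-6)

  # omnibus F against the classical formula
  N <- 12; k <- 3
  means <- vapply(groups, mean, numeric(1)); gm <- mean(unlist(groups))
  ssb <- sum(4 * (means - gm)^2)
  ssw <- sum(vapply(groups, function(g) sum((g - mean(g))^2), numeric(1)))
  expect_equal(glance(res)$statistic, (ssb / (k - 1)) / (ssw / (N - k)),
               tolerance = 1e-9)

  # identical groups: F = 0, all adjusted p = 1
  same <- anova_tukey(list(a = c(1, 2, 3), b = c(1, 2, 3), c = c(1, 2, 3)))
  expect_equal(glance(same)$statistic, 0)
  expect_true(all(tidy(same)$adj_p_value == 1))

  expect_error(anova_tukey(list(a = 1:3, b = 4:6)), "unpaired")
})

test_that("Tukey adjusted p agrees with a permutation null on a small fixture", {
  set.seed(81)
  groups <- list(a = c(1.0, 1.4, 0.8, 1.2), b = c(2.1, 2.6, 1.9, 2.3),
                 c = c(1.1, 1.5, 0.9, 1.3))
  res <- tidy(anova_tukey(groups))
  vals <- unlist(groups)
  n <- length(vals)
  idx <- rep(1:3, each = 4)
  # permutation null of the maximum standardized pairwise difference,
  # compared with the smallest Tukey-adjusted p (family-wise logic)
  obs_q <- function(v) {
    m <- tapply(v, idx, mean)
    s2 <- sum(tapply(v, idx, function(g) sum((g - mean(g))^2))) / (n - 3)
    max(abs(outer(m, m, "-"))) / sqrt(s2 / 2 * (2 / 4))
  }
  q0 <- obs_q(vals)
  perms <- 20000
  exceed <- 0
  for (i in seq_len(perms)) {
    exceed <- exceed + (obs_q(sample(vals)) >= q0)
  }
  p_perm <- exceed / perms
  expect_lt(abs(min(res$adj_p_value) - p_perm),
            3 * sqrt(p_perm * (1 - p_perm) / perms) + 0.01)
})

test_that("ANOVA F equals the squared pooled t for two groups", {
  set.seed(91)
  x <- rnorm(8, 1); y <- rnorm(8, 1.5)
  tt <- unpaired_t_test(x, y)
  df <- data.frame(value = c(x, y), group = rep(c("x", "y"), each = 8))
  F <- summary(aov(value ~ group, data = df))[[1]]["group", "F value"]
  expect_equal(tt$statistic^2, F, tolerance = 1e-10)
})

test_that("competitive fitness is the d10/d0 efficiency ratio", {
  expect_equal(competitive_fitness(0.5, 0.5)$fitness, 1)
  expect_equal(competitive_fitness(0.5, 0.25)$fitness, 0.5)
  expect_warning(f0 <- competitive_fitness(0, 0.5), "undefined")
  expect_true(is.na(f0$fitness))

  # exact inversion of the generator round trip
  sim <- simulate_competition(0.4, fitness = 0.8)
  expect_equal(competitive_fitness(sim$ko_d0, sim$ko_d10)$fitness,
               sim$ko_d10 / sim$ko_d0)
})

test_that("group summaries report n-1 standard deviations", {
  s <- summarize_groups(data.frame(group = rep(c("a", "b", "c"), c(3, 4, 1)),
                                   value = c(2, 2, 2, 1, 2, 3, 4, 9)))
  expect_equal(s$mean, c(2, 2.5, 9))
  expect_equal(s$sd[1], 0)
  expect_equal(s$sd[2], sd(1:4))
  expect_true(is.na(s$sd[3]))
})

test_that("p-values stay within [0, 1] across fuzzed inputs", {
  set.seed(101)
  for (i in 1:300) {
    n1 <- sample(2:10, 1); n2 <- sample(2:10, 1)
    x <- rnorm(n1, sd = runif(1, 0.01, 100))
    y <- rnorm(n2, sd = runif(1, 0.01, 100)) + runif(1, -50, 50)
    p <- unpaired_t_test(x, y)$p_value
    expect_true(p >= 0 && p <= 1)
  }
  for (i in 1:50) {
    g <- lapply(1:3, function(j) rnorm(sample(2:8, 1), mean = runif(1, -5, 5)))
    names(g) <- letters[1:3]
    ps <- c(glance(anova_tukey(g))$p_value, tidy(anova_tukey(g))$adj_p_value)
    expect_true(all(ps >= 0 & ps <= 1))
  }
})

test_that("significance stars follow the printed bins", {
  expect_equal(signif_stars(c(0.2, 0.05, 0.049, 0.009, 0.0009, 0.00009)),
               c("ns", "ns", "*", "**", "***", "****"))
})
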