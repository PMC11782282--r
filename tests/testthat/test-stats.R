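# independent brute-force oracle: two-sided Mann-Whitney p by direct
# enumeration over index subsets, written against the definition only
brute_force_mw_p <- function(a, b) {
  pooled <- c(a, b)
  na <- length(a)
  mu <- na * length(b) / 2
  ustat <- function(idx) {
    ga <- pooled[idx]; gb <- pooled[-idx]
    sum(outer(ga, gb, ">")) + 0.5 * sum(outer(ga, gb, "=="))
  }
  u_obs <- ustat(seq_len(na))
  sets <- utils::combn(length(pooled), na)
  us <- apply(sets, 2, ustat)
  mean(abs(us - mu) >= abs(u_obs - mu) - 1e-9)
}

test_that("Mann-Whitney U and exact p match enumeration and wilcox.test", {
  r <- mann_whitney_u(c(1, 2), c(3, 4))
  expect_equal(r$U, 0)
  expect_equal(r$p_value, 1 / 3, tolerance = 1e-12)
  expect_equal(r$method, "exact")

  ident <- mann_whitney_u(c(1, 2, 3), c(1, 2, 3))
  expect_equal(ident$U, 4.5)
  expect_equal(ident$p_value, 1)

  expect_equal(mann_whitney_u(c(5, 5), c(5, 5, 5))$p_value, 1)
  expect_error(mann_whitney_u(numeric(0), 1), "non-empty")

  # oracle equivalence over random small inputs, with and without ties
  set.seed(31)
  for (i in 1:12) {
    na <- sample(2:5, 1); nb <- sample(2:5, 1)
    a <- sample(1:6, na, replace = TRUE)       # ties likely
    b <- sample(1:6, nb, replace = TRUE)
    expect_equal(mann_whitney_u(a, b)$p_value, brute_force_mw_p(a, b),
                 tolerance = 1e-12)
  }
  # tie-free case also agrees with the standard exact test
  for (i in 1:6) {
    a <- rnorm(4); b <- rnorm(5)
    expect_equal(mann_whitney_u(a, b)$p_value,
                 wilcox.test(a, b, exact = TRUE)$p.value, tolerance = 1e-12)
  }
})

test_that("normal approximation agrees with the exact test at n = 20 + 20", {
  set.seed(32)
  worst <- 0
  for (i in 1:20) {
    a <- rnorm(20); b <- rnorm(20, 0.4)
    p_approx <- mann_whitney_u(a, b)$p_value
    p_exact <- wilcox.test(a, b, exact = TRUE)$p.value
    worst <- max(worst, abs(p_approx - p_exact))
  }
  expect_lt(worst, 0.02)
})

test_that("compare_groups runs per feature and subgroup_compare partitions the cohort", {
  set.seed(33)
  summaries <- tidyr::expand_grid(
    participant_id = sprintf("p%02d", 1:16),
    feature_label = c("red", "depth")) |>
    dplyr::mutate(
      group_label = rep(c("cvi", "control"), each = 2, length.out = 32),
      age_band = rep(rep(c("young", "old"), each = 2), length.out = 32),
      overall_mean = rnorm(32, 120, 15))
  cmp <- compare_groups(summaries)
  expect_equal(nrow(cmp), 2)
  expect_true(all(cmp$p_value > 0 & cmp$p_value <= 1))
  expect_true(all(cmp$U <= cmp$n_a * cmp$n_b))

  sub <- subgroup_compare(summaries, "age_band")
  expect_equal(nrow(sub), 4)
  whole <- subgroup_compare(dplyr::mutate(summaries, all = "all"), "all")
  expect_equal(whole$p_value, cmp$p_value)
  expect_equal(sum(sub$n_a[sub$feature_label == "red"]) +
                 sum(sub$n_b[sub$feature_label == "red"]), 16)

  tiny <- subgroup_compare(summaries[summaries$participant_id %in%
                                       sprintf("p%02d", 1:4), ], "age_band")
  expect_true(all(tiny$method == "insufficient-n"))
  expect_error(subgroup_compare(summaries, "no_such"), "unknown")
})

test_that("Spearman rho matches the closed form, the standard estimate, and flips sign", {
  r <- spearman_rho(c(1, 2, 3), c(3, 1, 2))
  expect_equal(r$rho, -0.5)                 # 1 - 6*6/(3*8)

  expect_equal(spearman_rho(1:6, (1:6)^3)$rho, 1)
  expect_equal(spearman_rho(1:5, c(2, 1, 4, 3, 5))$rho,
               cor(1:5, c(2, 1, 4, 3, 5), method = "spearman"))

  set.seed(34)
  x <- rnorm(12); y <- x + rnorm(12)
  a <- spearman_rho(x, y); b <- spearman_rho(x, -y)
  expect_equal(a$rho, -b$rho)
  expect_equal(a$p_value, b$p_value)
  # t-approximation against the standard test at n = 12
  ct <- suppressWarnings(cor.test(x, y, method = "spearman"))
  expect_equal(a$rho, unname(ct$estimate))

  # exact permutation p against cor.test's exact p (tie-free, n = 6)
  x6 <- rnorm(6); y6 <- rnorm(6)
  p_exact <- cor.test(x6, y6, method = "spearman", exact = TRUE)$p.value
  expect_equal(spearman_rho(x6, y6)$p_value, p_exact, tolerance = 1e-9)

  expect_warning(d <- spearman_rho(c(1, 1, 1), c(1, 2, 3)), "variance")
  expect_true(is.na(d$rho))
  expect_error(spearman_rho(1:2, 2:1), "at least 3")
})

test_that("correlate_items joins summaries with item scores over the mapping", {
  summaries <- tibble::tibble(
    participant_id = rep(sprintf("p%d", 1:6), 2),
    feature_label = rep(c("red", "complexity"), each = 6),
    overall_mean = c(10, 20, 30, 40, 50, 60, 5, 10, 20, 15, 30, 25))
  scores <- tibble::tibble(
    participant_id = rep(sprintf("p%d", 1:6), 2),
    item_label = rep(c("color preference",
                       "difficulties with visual complexity"), each = 6),
    score = c(1, 2, 3, 4, 5, 6, 1, 3, 2, 6, 4, 5))
  mapping <- tibble::tibble(
    feature_label = c("red", "complexity", "depth"),
    item_label = c("color preference", "difficulties with visual complexity",
                   "Score1"))
  out <- correlate_items(summaries, scores, mapping)
  expect_equal(nrow(out), 3)
  expect_equal(out$rho[out$feature_label == "red"], 1)
  expect_equal(out$method[out$feature_label == "depth"], "insufficient-n")
})

test_that("covariate regression recovers exact linear structure and names collinearity", {
  d <- tibble::tibble(age = c(1, 2, 3, 4, 5), y = 2 * c(1, 2, 3, 4, 5))
  fit <- covariate_regression(d, "y", "age")
  td <- suppressWarnings(tidy(fit))   # exact fit: summary warns
  expect_equal(td$estimate[td$term == "age"], 2, tolerance = 1e-12)
  expect_equal(suppressWarnings(glance(fit))$sigma, 0, tolerance = 1e-9)

  d0 <- tibble::tibble(y = c(3, 5, 7, 9))
  fit0 <- covariate_regression(d0, "y", "1")
  expect_equal(suppressWarnings(tidy(fit0))$estimate, mean(d0$y))

  set.seed(35)
  d2 <- tibble::tibble(x1 = rnorm(5), x2 = rnorm(5))
  d2$y <- d2$x1 + 2 * d2$x2
  fit2 <- covariate_regression(d2, "y", c("x1", "x2"))
  expect_equal(suppressWarnings(tidy(fit2))$estimate[-1], c(1, 2), tolerance = 1e-9)

  d3 <- dplyr::mutate(d2, x3 = x1 + x2)
  expect_error(covariate_regression(d3, "y", c("x1", "x2", "x3")), "x3")
  expect_error(covariate_regression(d2, "y", "nope"), "nope")
})

test_that("sample-size formula reproduces the design value and is monotone", {
  res <- sample_size_two_means(48, 43, 8, alpha = 0.05, power = 0.80)
  expect_equal(res$n_per_group, 40)
  expect_equal(res$n_total, 80)
  expect_equal(res$n_per_group_raw, 40.19, tolerance = 1e-3)
  expect_equal(res$n_per_group_ceiling, 41)

  # symmetric in the two means
  expect_equal(sample_size_two_means(43, 48, 8)$n_per_group, 40)

  # delta = sd: closed form 15.70 -> 16
  r2 <- sample_size_two_means(8, 0, 8)
  expect_equal(r2$n_per_group_raw, 15.70, tolerance = 1e-3)
  expect_equal(r2$n_per_group, 16)

  # inverse-monotone in |delta|, increasing in sd
  deltas <- c(2, 4, 6, 10)
  ns <- vapply(deltas, function(d) sample_size_two_means(d, 0, 8)$n_per_group_raw,
               numeric(1))
  expect_true(all(diff(ns) < 0))
  sds <- c(4, 6, 8, 12)
  ns2 <- vapply(sds, function(s) sample_size_two_means(5, 0, s)$n_per_group_raw,
                numeric(1))
  expect_true(all(diff(ns2) > 0))

  expect_error(sample_size_two_means(5, 5, 8), "infinite")
  expect_error(sample_size_two_means(48, 43, 0), "sd")
})
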