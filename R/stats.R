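#' Mann-Whitney U test for two independent groups
#'
#' The rank-sum statistic `U` is computed with midranks for ties. For small
#' samples (`n_a + n_b <= exact_cutoff`, default 12) the two-sided p-value
#' is exact: every assignment of the pooled values to the two groups is
#' enumerated and the p-value is the fraction of assignments whose `U` is
#' at least as far from its null mean `n_a n_b / 2` as the observed one
#' (ties handled naturally, no continuity shortcut). For larger samples the
#' normal approximation is used with tie-corrected variance and a 0.5
#' continuity correction.
#'
#' @param a,b Numeric vectors of values for the two groups.
#' @param feature_label Optional label carried into the result.
#' @param labels Length-2 character: names of groups `a` and `b`.
#' @param exact_cutoff Largest `n_a + n_b` for which the exact enumeration
#'   is used.
#' @return A one-row tibble of class `mw_test`: `feature_label`, `n_a`,
#'   `n_b`, `median_a`, `median_b`, `U` (for group `a`), `p_value`,
#'   `method` (`"exact"` or `"normal-approximation"`).
#' @examples
#' mann_whitney_u(c(1, 2), c(3, 4))  # exact p = 1/3
#' @export
mann_whitney_u <- function(a, b, feature_label = NA_character_,
                           labels = c("a", "b"), exact_cutoff = 12L) {
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  na <- length(a); nb <- length(b)
  if (na == 0L || nb == 0L) stop("both groups must be non-empty", call. = FALSE)
  pooled <- c(a, b)
  rk <- rank(pooled)                       # midranks
  U <- sum(rk[seq_len(na)]) - na * (na + 1) / 2
  mu <- na * nb / 2

  if (length(unique(pooled)) == 1L) {
    p <- 1; method <- "exact"
  } else if (na + nb <= exact_cutoff) {
    dev <- abs(U - mu)
    us <- u_enumeration(pooled, na)
    p <- mean(abs(us - mu) >= dev - 1e-9)
    method <- "exact"
  } else {
    n <- na + nb
    ties <- table(pooled)
    tie_term <- sum(ties^3 - ties) / (n * (n - 1))
    sigma2 <- na * nb / 12 * ((n + 1) - tie_term)
    if (sigma2 <= 0) {
      p <- 1
    } else {
      z <- (U - mu - sign(U - mu) * 0.5) / sqrt(sigma2)
      p <- min(1, 2 * stats::pnorm(-abs(z)))
    }
    method <- "normal-approximation"
  }
  out <- tibble::tibble(
    feature_label = feature_label, n_a = na, n_b = nb,
    median_a = stats::median(a), median_b = stats::median(b),
    U = U, p_value = p, method = method,
    label_a = labels[1], label_b = labels[2])
  class(out) <- c("mw_test", class(out))
  out
}

# all U statistics over the choose(n, na) assignments of pooled values to
# group a (midranks fixed by the pooled sample, so only the chosen index
# set matters)
u_enumeration <- function(pooled, na) {
  rk <- rank(pooled)
  sets <- utils::combn(length(pooled), na)
  colSums(matrix(rk[sets], nrow = na)) - na * (na + 1) / 2
}

#' Compare groups feature-by-feature
#'
#' Applies [mann_whitney_u()] to each feature in a participant summary
#' table (one row per participant x feature, the unit of analysis being
#' the participant's overall mean fixation saliency value).
#'
#' @param summaries Tibble with columns `feature_label`, `group_label` and
#'   a value column.
#' @param value Name of the value column (default `"overall_mean"`).
#' @param group Name of the grouping column (default `"group_label"`);
#'   must take exactly two levels.
#' @param adjust Add a Benjamini-Hochberg adjusted column `p_adj` across
#'   features? Off by default: the analysis plan specifies raw per-feature
#'   p-values.
#' @inheritParams mann_whitney_u
#' @return A tibble with one `mw_test` row per feature.
#' @export
compare_groups <- function(summaries, value = "overall_mean",
                           group = "group_label", adjust = FALSE,
                           exact_cutoff = 12L) {
  lv <- sort(unique(summaries[[group]]))
  if (length(lv) != 2L) {
    stop("compare_groups requires exactly two group levels, got: ",
         paste(lv, collapse = ", "), call. = FALSE)
  }
  out <- summaries |>
    dplyr::group_by(.data$feature_label) |>
    dplyr::group_modify(function(d, key) {
      mann_whitney_u(d[[value]][d[[group]] == lv[1]],
                     d[[value]][d[[group]] == lv[2]],
                     labels = lv, exact_cutoff = exact_cutoff)[-1]
    }) |>
    dplyr::ungroup()
  if (adjust) out$p_adj <- stats::p.adjust(out$p_value, method = "BH")
  out
}

#' Subgroup comparisons
#'
#' Repeats the per-feature group comparison within each level of a
#' subgroup label (e.g. excluding ophthalmologic comorbidity, or splitting
#' by age band). Subgroups with fewer than `min_n` participants per group
#' are reported with `p_value = NA` and method `"insufficient-n"`.
#'
#' @param summaries Participant x feature summary tibble that also carries
#'   the subgroup column.
#' @param subgroup Name of the subgroup column.
#' @param min_n Minimum participants per group within a subgroup.
#' @inheritParams compare_groups
#' @return Tibble of comparisons, one row per subgroup x feature.
#' @export
subgroup_compare <- function(summaries, subgroup, value = "overall_mean",
                             group = "group_label", min_n = 3L,
                             exact_cutoff = 12L) {
  if (!subgroup %in% names(summaries)) {
    stop("unknown subgroup column: ", subgroup, call. = FALSE)
  }
  lv <- sort(unique(summaries[[group]]))
  if (length(lv) != 2L) stop("requires exactly two group levels", call. = FALSE)
  summaries |>
    dplyr::group_by(.data$feature_label, subgroup_level = .data[[subgroup]]) |>
    dplyr::group_modify(function(d, key) {
      na <- sum(d[[group]] == lv[1]); nb <- sum(d[[group]] == lv[2])
      if (na < min_n || nb < min_n) {
        return(tibble::tibble(
          n_a = na, n_b = nb, median_a = NA_real_, median_b = NA_real_,
          U = NA_real_, p_value = NA_real_, method = "insufficient-n",
          label_a = lv[1], label_b = lv[2]))
      }
      mann_whitney_u(d[[value]][d[[group]] == lv[1]],
                     d[[value]][d[[group]] == lv[2]],
                     labels = lv, exact_cutoff = exact_cutoff)[-1]
    }) |>
    dplyr::ungroup()
}

#' Spearman rank correlation
#'
#' Midrank transform of both vectors followed by the product-moment
#' correlation of the ranks. For `n <= 8` the two-sided p-value is exact by
#' permutation enumeration of one margin; otherwise the t approximation
#' `t = rho * sqrt((n-2)/(1-rho^2))` on `n - 2` degrees of freedom.
#'
#' @param x,y Paired numeric vectors, `n >= 3` complete pairs.
#' @param feature_label,item_label Optional labels carried into the result
#'   (feature vs functional-vision item).
#' @return One-row tibble: `feature_label`, `item_label`, `n`, `rho`,
#'   `p_value`, `method`. Zero variance in either vector gives `rho = NA`
#'   with method `"degenerate"`.
#' @export
spearman_rho <- function(x, y, feature_label = NA_character_,
                         item_label = NA_character_) {
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3L) stop("spearman_rho requires at least 3 complete pairs", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    warning("zero variance: Spearman correlation undefined", call. = FALSE)
    return(tibble::tibble(feature_label = feature_label,
                          item_label = item_label, n = n, rho = NA_real_,
                          p_value = NA_real_, method = "degenerate"))
  }
  rx <- rank(x); ry <- rank(y)
  rho <- stats::cor(rx, ry)
  if (n <= 8L) {
    perms <- permutations_of(n)
    rhos <- apply(perms, 1L, function(p) stats::cor(rx, ry[p]))
    p <- mean(abs(rhos) >= abs(rho) - 1e-9)
    method <- "exact-permutation"
  } else {
    tstat <- rho * sqrt((n - 2) / (1 - rho^2))
    p <- 2 * stats::pt(-abs(tstat), df = n - 2)
    method <- "t-approximation"
  }
  tibble::tibble(feature_label = feature_label, item_label = item_label,
                 n = n, rho = rho, p_value = p, method = method)
}

permutations_of <- function(n) {
  if (n == 1L) return(matrix(1L, 1, 1))
  sub <- permutations_of(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(k) {
    cbind(k, sub + (sub >= k))
  }))
}

#' Correlate feature saliency summaries with functional-vision item scores
#'
#' Joins participant overall mean fixation saliency values with per-item
#' functional-vision scores and computes [spearman_rho()] for each
#' (feature, item) pair in the mapping table. The default mapping follows
#' the analysis plan: color maps to the color-preference item, field maps
#' to visual-field preference, complexity to difficulties-with-complexity,
#' luminance to need-for-light.
#'
#' @param summaries Participant x feature summary tibble
#'   (`participant_id`, `feature_label`, `overall_mean`).
#' @param scores Item-score tibble `participant_id, item_label, score`.
#' @param mapping Tibble `feature_label, item_label`; defaults to
#'   [default_feature_item_map()].
#' @return Tibble of correlation rows, one per mapped pair.
#' @export
correlate_items <- function(summaries, scores,
                            mapping = default_feature_item_map()) {
  purrr::pmap_dfr(mapping, function(feature_label, item_label) {
    s <- summaries[summaries$feature_label == feature_label, ]
    v <- scores[scores$item_label == item_label, ]
    j <- dplyr::inner_join(s[c("participant_id", "overall_mean")],
                           v[c("participant_id", "score")],
                           by = "participant_id")
    if (nrow(j) < 3L) {
      return(tibble::tibble(feature_label = feature_label,
                            item_label = item_label, n = nrow(j),
                            rho = NA_real_, p_value = NA_real_,
                            method = "insufficient-n"))
    }
    spearman_rho(j$overall_mean, j$score, feature_label, item_label)
  })
}

#' @rdname correlate_items
#' @export
default_feature_item_map <- function() {
  tibble::tribble(
    ~feature_label,     ~item_label,
    "red",              "color preference",
    "yellow",           "color preference",
    "green",            "color preference",
    "blue",             "color preference",
    "field_central",    "visual field preference",
    "field_peripheral", "visual field preference",
    "field_upper",      "visual field preference",
    "field_lower",      "visual field preference",
    "field_right",      "visual field preference",
    "field_left",       "visual field preference",
    "complexity",       "difficulties with visual complexity",
    "luminance",        "need for light")
}

#' Covariate regression of fixation saliency values
#'
#' Ordinary least-squares fit of a participant-level outcome on age and
#' binary comorbidity indicators (or any covariate set), with intercept.
#' Reports coefficients, standard errors and two-sided p-values. A
#' rank-deficient design is an error naming the collinear columns.
#'
#' @param data Participant-level tibble.
#' @param response Name of the outcome column.
#' @param covariates Character vector of covariate column names.
#' @return An object of class `covariate_fit` wrapping the `lm` fit;
#'   [tidy()] gives the coefficient table, [glance()] the fit summary.
#' @export
covariate_regression <- function(data, response, covariates) {
  miss <- setdiff(setdiff(c(response, covariates), "1"), names(data))
  if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "),
                         call. = FALSE)
  fml <- stats::reformulate(covariates, response = response)
  X <- stats::model.matrix(fml, data = data)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    bad <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    stop("design matrix is rank deficient; collinear column(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  fit <- stats::lm(fml, data = data)
  structure(list(fit = fit, response = response, covariates = covariates),
            class = "covariate_fit")
}

#' @export
print.covariate_fit <- function(x, ...) {
  cat("<covariate_fit> ", deparse(stats::formula(x$fit)), "\n")
  print(tidy(x))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @method tidy covariate_fit
#' @export
tidy.covariate_fit <- function(x, ...) {
  cf <- stats::coef(summary(x$fit))
  tibble::tibble(term = rownames(cf), estimate = unname(cf[, 1]),
                 std_error = unname(cf[, 2]), statistic = unname(cf[, 3]),
                 p_value = unname(cf[, 4]))
}

#' @method glance covariate_fit
#' @export
glance.covariate_fit <- function(x, ...) {
  s <- summary(x$fit)
  tibble::tibble(r_squared = s$r.squared, adj_r_squared = s$adj.r.squared,
                 sigma = s$sigma, df_residual = x$fit$df.residual,
                 n = length(stats::residuals(x$fit)))
}

#' @method tidy mw_test
#' @export
tidy.mw_test <- function(x, ...) tibble::as_tibble(x)

#' Sample size for comparing two means
#'
#' Closed-form normal-approximation sample size for a two-sided two-sample
#' comparison of means:
#' `n_per_group = 2 (z_{1-alpha/2} + z_{power})^2 sd^2 / delta^2`.
#' Reported unrounded and under two integer conventions; the headline
#' `n_per_group` uses nearest-integer rounding (`ceiling` is also given).
#' With group means 48 and 43, common SD 8, alpha 0.05 and power 0.80 this
#' gives 40.19 unrounded, i.e. 40 per group and 80 in total.
#'
#' An ARE-adjusted size for a Mann-Whitney analysis (dividing by the
#' asymptotic relative efficiency 3/pi of the rank test under normality)
#' is included as an optional column, since a rank test needs slightly
#' more observations for the same power.
#'
#' @param mean_a,mean_b Anticipated group means (fixation-saliency units).
#' @param sd Common standard deviation; must be positive.
#' @param alpha Two-sided significance level.
#' @param power Target power.
#' @return One-row tibble: `n_per_group_raw`, `n_per_group`, `n_total`,
#'   `n_per_group_ceiling`, `n_total_ceiling`, `n_per_group_mw` (ARE
#'   adjusted, ceiling), plus the inputs.
#' @examples
#' sample_size_two_means(48, 43, 8)  # 40 per group, 80 total
#' @export
sample_size_two_means <- function(mean_a, mean_b, sd, alpha = 0.05,
                                  power = 0.80) {
  if (sd <= 0) stop("sd must be positive", call. = FALSE)
  if (alpha <= 0 || alpha >= 1 || power <= 0 || power >= 1) {
    stop("alpha and power must lie strictly between 0 and 1", call. = FALSE)
  }
  delta <- mean_a - mean_b
  if (delta == 0) {
    stop("zero effect size: required sample size is infinite", call. = FALSE)
  }
  z <- stats::qnorm(1 - alpha / 2) + stats::qnorm(power)
  n_raw <- 2 * z^2 * sd^2 / delta^2
  n_near <- round(n_raw)
  n_ceil <- ceiling(n_raw)
  are <- 3 / pi
  tibble::tibble(
    mean_a = mean_a, mean_b = mean_b, sd = sd, alpha = alpha, power = power,
    n_per_group_raw = n_raw, n_per_group = n_near, n_total = 2 * n_near,
    n_per_group_ceiling = n_ceil, n_total_ceiling = 2 * n_ceil,
    n_per_group_mw = ceiling(n_raw / are))
}

#' Monte-Carlo power of the two-sample comparison
#'
#' Simulates replicate cohorts of two normal groups and reports the
#' fraction rejected by the two-sided Welch t test at level `alpha`. Used
#' to verify the closed-form sample-size calculation empirically.
#'
#' @param n_per_group Participants per group.
#' @param mean_a,mean_b,sd Normal population parameters.
#' @param alpha Two-sided level.
#' @param n_reps Number of replicates.
#' @param test `"t"` (Welch, vectorized) or `"mann-whitney"` (uses
#'   [mann_whitney_u()]; slower).
#' @return One-row tibble: `power` (proportion), `n_reps`, `analytic`
#'   (the `power.t.test` value for comparison when `test = "t"`).
#' @export
mc_power_two_sample <- function(n_per_group, mean_a, mean_b, sd,
                                alpha = 0.05, n_reps = 10000,
                                test = c("t", "mann-whitney")) {
  test <- match.arg(test)
  n <- n_per_group
  if (test == "t") {
    A <- matrix(stats::rnorm(n * n_reps, mean_a, sd), nrow = n)
    B <- matrix(stats::rnorm(n * n_reps, mean_b, sd), nrow = n)
    ma <- colMeans(A); mb <- colMeans(B)
    va <- colSums((A - rep(ma, each = n))^2) / (n - 1)
    vb <- colSums((B - rep(mb, each = n))^2) / (n - 1)
    se <- sqrt(va / n + vb / n)
    df <- (va / n + vb / n)^2 / ((va / n)^2 / (n - 1) + (vb / n)^2 / (n - 1))
    tstat <- (ma - mb) / se
    rej <- 2 * stats::pt(-abs(tstat), df) < alpha
    analytic <- stats::power.t.test(n = n, delta = abs(mean_a - mean_b),
                                    sd = sd, sig.level = alpha)$power
  } else {
    rej <- vapply(seq_len(n_reps), function(i) {
      a <- stats::rnorm(n, mean_a, sd); b <- stats::rnorm(n, mean_b, sd)
      mann_whitney_u(a, b)$p_value < alpha
    }, logical(1))
    analytic <- NA_real_
  }
  tibble::tibble(power = mean(rej), n_reps = n_reps, analytic = analytic)
}
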