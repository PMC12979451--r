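#' Published cut-off scores of the five childhood-trauma subscales
#'
#' Emotional abuse >= 13, physical abuse >= 10, sexual abuse >= 8, emotional
#' neglect >= 15, physical neglect >= 10. Meeting or exceeding the cut-off
#' on any one subscale classifies a respondent as maltreatment-exposed.
#'
#' @export
ctq_cutoffs <- c(EA = 13, PA = 10, SA = 8, EN = 15, PN = 10)

#' Classify childhood-maltreatment exposure from CTQ subscale scores
#'
#' Data-frame-first: expects columns `EA`, `PA`, `SA`, `EN`, `PN` (five-item
#' subscales, each scored 5–25) and appends a `maltreatment` column with
#' `"CM"` when any subscale meets or exceeds its published cut-off and
#' `"nCM"` when all five are strictly below.
#'
#' @param data Data frame with the five subscale columns.
#' @returns The input as a tibble with a `maltreatment` factor column.
#' @examples
#' classify_ctq(data.frame(EA = 13, PA = 5, SA = 5, EN = 5, PN = 5)) # CM
#' @export
classify_ctq <- function(data) {
  data <- tibble::as_tibble(data)
  missing <- setdiff(names(ctq_cutoffs), names(data))
  if (length(missing) > 0) {
    rlang::abort(sprintf("missing CTQ subscale column(s): %s.", paste(missing, collapse = ", ")))
  }
  scores <- as.matrix(data[names(ctq_cutoffs)])
  if (anyNA(scores)) rlang::abort("CTQ subscale scores contain missing values.")
  if (any(scores < 0)) rlang::abort("CTQ subscale scores must be nonnegative.")
  exposed <- rowSums(sweep(scores, 2, ctq_cutoffs, `>=`)) > 0
  data$maltreatment <- factor(ifelse(exposed, "CM", "nCM"), levels = c("CM", "nCM"))
  data
}

#' Two-sample permutation test on a group mean difference
#'
#' The test statistic is the absolute difference of group means (two-sided
#' by construction; any other exchangeable statistic can be plugged in).
#' Group labels are shuffled `n_perm` times and the p value uses the
#' add-one estimator p = (1 + #\{permuted >= observed\}) / (n_perm + 1), so
#' it can never be exactly zero and is bounded below by 1/(n_perm + 1).
#'
#' @param values_a,values_b Numeric samples for the two groups.
#' @param n_perm Number of label permutations (default 10000).
#' @param seed Integer seed; the caller's RNG state is untouched.
#' @param statistic Optional function `(a, b) -> scalar`; larger must mean
#'   more extreme. Default `abs(mean(a) - mean(b))`.
#' @returns One-row tibble: `observed_diff` (signed mean difference a - b),
#'   `statistic`, `p_value`, `n_perm`, `n_a`, `n_b`, `seed`.
#' @export
permutation_test <- function(values_a, values_b, n_perm = 10000, seed = 1,
                             statistic = NULL) {
  values_a <- as.numeric(values_a); values_b <- as.numeric(values_b)
  if (length(values_a) == 0 || length(values_b) == 0) {
    rlang::abort("both groups must be nonempty.")
  }
  if (n_perm < 1) rlang::abort("`n_perm` must be >= 1.")
  if (is.null(statistic)) statistic <- function(a, b) abs(mean(a) - mean(b))
  pooled <- c(values_a, values_b)
  na <- length(values_a); n <- length(pooled)
  obs <- statistic(values_a, values_b)
  perm <- withr::with_seed(seed, vapply(seq_len(n_perm), function(i) {
    idx <- sample.int(n, na)
    statistic(pooled[idx], pooled[-idx])
  }, numeric(1)))
  tibble::tibble(
    observed_diff = mean(values_a) - mean(values_b),
    statistic = obs,
    p_value = (1 + sum(perm >= obs)) / (n_perm + 1),
    n_perm = as.integer(n_perm),
    n_a = na, n_b = n - na,
    seed = as.integer(seed)
  )
}

#' Benjamini–Hochberg false discovery rate adjustment
#'
#' Step-up adjusted p values clipped to 1; never smaller than the raw
#' values. Thin validation layer over [stats::p.adjust()].
#'
#' @param p_values Numeric vector of p values in \[0, 1\].
#' @returns Adjusted p values in the original order.
#' @export
fdr_correct <- function(p_values) {
  p_values <- as.numeric(p_values)
  bad <- which(is.na(p_values) | p_values < 0 | p_values > 1)
  if (length(bad) > 0) {
    rlang::abort(sprintf("p value out of [0, 1] at position %d.", bad[1]))
  }
  stats::p.adjust(p_values, method = "BH")
}

#' Partial correlation with nuisance covariates regressed out
#'
#' Regresses `x` and `y` each on an intercept plus the covariate columns by
#' least squares and returns the Pearson correlation of the two residual
#' vectors, with a two-sided p value from the t distribution on
#' n - 2 - q degrees of freedom (q = number of covariate columns). This is
#' the standard way of adjusting a brain–behaviour correlation for age, sex
#' and education; sex should enter as a 0/1 indicator.
#'
#' @param x,y Numeric vectors of equal length.
#' @param covariates Numeric matrix or data frame of nuisance columns
#'   (may be NULL or zero-column for a plain correlation).
#' @returns One-row tibble: `r`, `p_value`, `df`, `n`, `n_covariates`.
#' @export
partial_correlation <- function(x, y, covariates = NULL) {
  x <- as.numeric(x); y <- as.numeric(y)
  n <- length(x)
  if (length(y) != n) rlang::abort("`x` and `y` must have equal length.")
  if (is.null(covariates)) covariates <- matrix(numeric(0), nrow = n, ncol = 0)
  covariates <- as.matrix(as.data.frame(covariates))
  if (nrow(covariates) != n) rlang::abort("covariates must have one row per observation.")
  mode(covariates) <- "numeric"
  # a constant column duplicates the intercept and carries no information
  if (ncol(covariates) > 0) {
    constant <- apply(covariates, 2, function(v) stats::sd(v) == 0)
    covariates <- covariates[, !constant, drop = FALSE]
  }
  design <- cbind(`(intercept)` = 1, covariates)
  qr_d <- qr(design)
  if (qr_d$rank < ncol(design)) {
    dropped <- colnames(design)[qr_d$pivot[-seq_len(qr_d$rank)]]
    rlang::abort(sprintf("covariate matrix is rank deficient; collinear column(s): %s.",
                         paste(dropped, collapse = ", ")))
  }
  res_x <- qr.resid(qr_d, x)
  res_y <- qr.resid(qr_d, y)
  q <- ncol(covariates)
  df <- n - 2 - q
  if (df < 1) rlang::abort("not enough observations for the covariate set.")
  # a variable fully explained by the covariates has no residual variation
  # left to correlate; floating-point noise in its residuals must not
  # masquerade as association
  if (stats::sd(res_x) < 1e-10 * max(stats::sd(x), 1) ||
      stats::sd(res_y) < 1e-10 * max(stats::sd(y), 1)) {
    r <- 0
  } else {
    r <- stats::cor(res_x, res_y)
  }
  t_stat <- r * sqrt(df / (1 - r^2))
  tibble::tibble(
    r = r,
    p_value = 2 * stats::pt(-abs(t_stat), df),
    df = df, n = n, n_covariates = q
  )
}

#' One-way ANOVA F statistic from per-group summaries
#'
#' Reconstructs the F statistic exactly from group means, standard
#' deviations and sizes: between-group sum of squares from the means,
#' within-group from the SDs. Useful for checking published demographic
#' tables where only summaries are printed.
#'
#' @param means,sds,ns Numeric vectors, one entry per group (>= 2 groups,
#'   all n >= 2).
#' @returns One-row tibble: `f_statistic`, `df_between`, `df_within`,
#'   `p_value`, `ms_within`.
#' @export
anova_from_summary <- function(means, sds, ns) {
  g <- length(means)
  if (g < 2 || length(sds) != g || length(ns) != g) {
    rlang::abort("`means`, `sds`, `ns` must be equal-length vectors over >= 2 groups.")
  }
  if (any(ns < 2)) rlang::abort("every group must have n >= 2.")
  n_total <- sum(ns)
  grand <- sum(ns * means) / n_total
  ssb <- sum(ns * (means - grand)^2)
  ssw <- sum((ns - 1) * sds^2)
  df1 <- g - 1; df2 <- n_total - g
  f_stat <- (ssb / df1) / (ssw / df2)
  tibble::tibble(
    f_statistic = f_stat, df_between = df1, df_within = df2,
    p_value = stats::pf(f_stat, df1, df2, lower.tail = FALSE),
    ms_within = ssw / df2
  )
}

#' Pooled-variance two-sample t statistic from summaries
#'
#' Two-tailed Student t with pooled variance; the sign follows m1 - m2.
#' When the pooled variance is zero with unequal means the statistic is
#' returned as signed `Inf` with p = 0.
#'
#' @param m1,s1,n1 Mean, SD and size of group 1 (n1 >= 2).
#' @param m2,s2,n2 Likewise for group 2.
#' @returns One-row tibble: `t_statistic`, `df`, `p_value`.
#' @export
two_sample_t_from_summary <- function(m1, s1, n1, m2, s2, n2) {
  if (n1 < 2 || n2 < 2) rlang::abort("both groups must have n >= 2.")
  df <- n1 + n2 - 2
  sp2 <- ((n1 - 1) * s1^2 + (n2 - 1) * s2^2) / df
  if (sp2 == 0) {
    t_stat <- if (m1 == m2) 0 else sign(m1 - m2) * Inf
  } else {
    t_stat <- (m1 - m2) / sqrt(sp2 * (1 / n1 + 1 / n2))
  }
  tibble::tibble(
    t_statistic = t_stat, df = df,
    p_value = 2 * stats::pt(-abs(t_stat), df)
  )
}

#' Pearson chi-squared test of independence
#'
#' Without continuity correction, as conventional for r x c contingency
#' tables larger than 2 x 2 (e.g. a sex-by-group table).
#'
#' @param counts Matrix of nonnegative counts; no zero row or column margin.
#' @returns One-row tibble: `chi_squared`, `df`, `p_value`.
#' @export
chi_squared_independence <- function(counts) {
  counts <- as.matrix(counts)
  if (any(counts < 0)) rlang::abort("counts must be nonnegative.")
  if (any(rowSums(counts) == 0) || any(colSums(counts) == 0)) {
    rlang::abort("contingency table has a zero marginal.")
  }
  res <- suppressWarnings(stats::chisq.test(counts, correct = FALSE))
  tibble::tibble(
    chi_squared = unname(res$statistic),
    df = unname(res$parameter),
    p_value = res$p.value
  )
}

#' Tukey HSD pairwise comparisons from per-group summaries
#'
#' Post-hoc pairwise p values after a one-way ANOVA, using the studentized
#' range distribution with the pooled within-group variance reconstructed
#' from the summaries (unequal group sizes handled by the Tukey–Kramer
#' harmonic form).
#'
#' @inheritParams anova_from_summary
#' @param group_labels Optional group names.
#' @returns Tibble with one row per pair: `group_1`, `group_2`, `diff`
#'   (mean_1 - mean_2), `q`, `p_adj`.
#' @export
tukey_hsd_from_summary <- function(means, sds, ns, group_labels = NULL) {
  g <- length(means)
  if (g < 3) rlang::abort("Tukey HSD needs >= 3 groups.")
  if (is.null(group_labels)) group_labels <- paste0("group_", seq_len(g))
  fit <- anova_from_summary(means, sds, ns)
  pairs <- utils::combn(g, 2)
  purrr::map_dfr(seq_len(ncol(pairs)), function(c_idx) {
    i <- pairs[1, c_idx]; j <- pairs[2, c_idx]
    se <- sqrt(fit$ms_within / 2 * (1 / ns[i] + 1 / ns[j]))
    q <- abs(means[i] - means[j]) / se
    tibble::tibble(
      group_1 = group_labels[i], group_2 = group_labels[j],
      diff = means[i] - means[j], q = q,
      p_adj = stats::ptukey(q, nmeans = g, df = fit$df_within, lower.tail = FALSE)
    )
  })
}

#' Reconstruct a demographic table's test statistics from printed summaries
#'
#' Takes a tidy long table of per-group summaries (`variable`, `group`,
#' `n`, `mean`, `sd`, plus `test` naming `"anova"` or `"t"` per variable)
#' and an optional sex-count table (`group`, `female`, `male`) and
#' recomputes each row's test statistic: one-way ANOVA F across all groups,
#' pooled two-sample t for two-group rows, and the chi-squared statistic for
#' the sex distribution.
#'
#' @param continuous Data frame of per-group summaries as above.
#' @param sex_counts Optional data frame with columns `group`, `female`,
#'   `male`.
#' @returns Tibble: `variable`, `test`, `statistic`, `p_value`.
#' @export
reconstruct_summary_statistics <- function(continuous, sex_counts = NULL) {
  continuous <- tibble::as_tibble(continuous)
  need <- c("variable", "group", "n", "mean", "sd", "test")
  missing <- setdiff(need, names(continuous))
  if (length(missing) > 0) {
    rlang::abort(sprintf("summary table lacks column(s): %s.", paste(missing, collapse = ", ")))
  }
  rows <- continuous |>
    dplyr::group_by(.data$variable) |>
    dplyr::group_modify(function(d, key) {
      test <- d$test[1]
      if (test == "anova") {
        fit <- anova_from_summary(d$mean, d$sd, d$n)
        tibble::tibble(test = "anova", statistic = fit$f_statistic, p_value = fit$p_value)
      } else if (test == "t") {
        if (nrow(d) != 2) rlang::abort("a t-test row needs exactly 2 groups.")
        fit <- two_sample_t_from_summary(d$mean[1], d$sd[1], d$n[1],
                                         d$mean[2], d$sd[2], d$n[2])
        tibble::tibble(test = "t", statistic = fit$t_statistic, p_value = fit$p_value)
      } else {
        rlang::abort(sprintf("unknown test '%s' for variable '%s'.", test, key$variable))
      }
    }) |>
    dplyr::ungroup()
  if (!is.null(sex_counts)) {
    counts <- rbind(sex_counts$female, sex_counts$male)
    fit <- chi_squared_independence(counts)
    rows <- dplyr::bind_rows(
      tibble::tibble(variable = "sex", test = "chi_squared",
                     statistic = fit$chi_squared, p_value = fit$p_value),
      rows
    )
  }
  rows
}
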