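#' Mean and sample standard deviation
#'
#' Cohort cells are reported as mean +/- SD. The SD uses the n-1
#' denominator; for a single observation it is undefined and returned as
#' `NA`.
#'
#' @param values non-empty numeric vector.
#' @return Named list with `mean`, `sd` (NA when n = 1) and `n`.
#' @export
summarize_values <- function(values) {
  values <- as.numeric(values)
  if (length(values) == 0 || anyNA(values)) {
    stop("values must be a non-empty numeric vector without NA",
         call. = FALSE)
  }
  list(mean = mean(values),
       sd = if (length(values) > 1) stats::sd(values) else NA_real_,
       n = length(values))
}

# Validate a group list for variance-based tests.
.check_groups <- function(groups) {
  if (!is.list(groups) || length(groups) < 2) {
    stop("at least 2 groups are required", call. = FALSE)
  }
  if (is.null(names(groups)) || any(names(groups) == "")) {
    stop("groups must be named", call. = FALSE)
  }
  groups <- lapply(groups, as.numeric)
  ns <- lengths(groups)
  if (any(ns < 2)) {
    stop("every group needs n >= 2 for variance-based tests",
         call. = FALSE)
  }
  if (any(vapply(groups, anyNA, logical(1)))) {
    stop("group values must be finite", call. = FALSE)
  }
  groups
}

#' One-way analysis of variance
#'
#' Classical fixed-effects one-way ANOVA: `F = MSB / MSW` on (k-1, N-k)
#' degrees of freedom, fitted with `stats::lm`/`stats::anova`. Degenerate
#' inputs are resolved before fitting: identical values in every cell give
#' `F = 0, p = 1`; zero within-group variance with unequal means has no
#' finite F and raises an error.
#'
#' @param groups named list of numeric vectors, one per group, each n >= 2.
#' @return List with `f`, `p`, `df_between`, `df_within`, `ms_within` (the
#'   pooled error mean square reused by [pairwise_tests()]).
#' @export
one_way_anova <- function(groups) {
  groups <- .check_groups(groups)
  all_vals <- unlist(groups, use.names = FALSE)
  k <- length(groups)
  n_tot <- length(all_vals)
  if (all(all_vals == all_vals[1])) {
    return(list(f = 0, p = 1, df_between = k - 1L,
                df_within = n_tot - k, ms_within = 0))
  }
  within_ss <- sum(vapply(groups, function(g) sum((g - mean(g))^2),
                          numeric(1)))
  if (within_ss == 0) {
    stop("zero within-group variance with unequal group means: ",
         "F is not defined", call. = FALSE)
  }
  g <- factor(rep(names(groups), lengths(groups)), levels = names(groups))
  fit <- stats::anova(stats::lm(all_vals ~ g))
  list(f = fit[["F value"]][1], p = fit[["Pr(>F)"]][1],
       df_between = fit[["Df"]][1], df_within = fit[["Df"]][2],
       ms_within = fit[["Mean Sq"]][2])
}

#' Pairwise group comparisons (Fisher LSD or Bonferroni)
#'
#' Fisher least-significant-difference t tests: each pair is compared with
#' `t = (mean_i - mean_j) / sqrt(MSW * (1/n_i + 1/n_j))` against Student's t
#' on the pooled within-group degrees of freedom from the one-way ANOVA.
#' Unadjusted p values by default (`method = "lsd"`);
#' `method = "bonferroni"` multiplies by the number of pairs.
#'
#' @param groups named list of numeric vectors, one per group, each n >= 2.
#' @param method `"lsd"` (default) or `"bonferroni"`.
#' @return Data frame with one row per unordered pair: `group1`, `group2`,
#'   `t`, `p`.
#' @export
pairwise_tests <- function(groups, method = c("lsd", "bonferroni")) {
  method <- match.arg(method)
  groups <- .check_groups(groups)
  aov_res <- one_way_anova(groups)
  msw <- aov_res$ms_within
  dfw <- aov_res$df_within
  nms <- names(groups)
  pairs <- utils::combn(nms, 2)
  res <- apply(pairs, 2, function(pr) {
    g1 <- groups[[pr[1]]]; g2 <- groups[[pr[2]]]
    se <- sqrt(msw * (1 / length(g1) + 1 / length(g2)))
    if (se == 0) {
      t <- if (mean(g1) == mean(g2)) 0 else {
        stop("zero pooled variance with unequal means: t is not defined",
             call. = FALSE)
      }
      p <- 1
    } else {
      t <- (mean(g1) - mean(g2)) / se
      p <- 2 * stats::pt(abs(t), df = dfw, lower.tail = FALSE)
    }
    c(t = t, p = p)
  })
  p <- res["p", ]
  if (method == "bonferroni") p <- pmin(p * ncol(pairs), 1)
  data.frame(group1 = pairs[1, ], group2 = pairs[2, ],
             t = res["t", ], p = as.numeric(p),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Paired two-tailed t test
#'
#' `t = mean(d) / (sd(d) / sqrt(n))` on `n - 1` degrees of freedom for the
#' per-patient differences `d = pre - post`, via `stats::t.test`. All-zero
#' differences give `t = 0, p = 1`; zero-variance differences with nonzero
#' mean have no finite t and raise an error.
#'
#' @param pre,post equal-length numeric vectors (n >= 2), one value per
#'   patient.
#' @return List with `t`, `p`, `df`, `mean_diff`.
#' @export
paired_t <- function(pre, post) {
  pre <- as.numeric(pre); post <- as.numeric(post)
  if (length(pre) != length(post) || length(pre) < 2) {
    stop("pre and post must have equal length >= 2", call. = FALSE)
  }
  if (anyNA(pre) || anyNA(post)) {
    stop("scores must be finite", call. = FALSE)
  }
  d <- pre - post
  if (stats::sd(d) == 0) {
    if (mean(d) == 0) {
      return(list(t = 0, p = 1, df = length(d) - 1L, mean_diff = 0))
    }
    stop("zero-variance differences with nonzero mean: t is not defined",
         call. = FALSE)
  }
  ht <- stats::t.test(pre, post, paired = TRUE)
  list(t = unname(ht$statistic), p = ht$p.value,
       df = unname(ht$parameter), mean_diff = unname(ht$estimate))
}

#' Two-tailed significance flag
#'
#' `TRUE` when p is strictly below 0.050, the conventional two-tailed
#' threshold.
#'
#' @param p p value(s) in \[0, 1\].
#' @return Logical vector.
#' @export
significance_flag <- function(p) {
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1)) {
    stop("p must lie in [0, 1]", call. = FALSE)
  }
  p < 0.050
}
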