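#' Two-sided Mann-Whitney U test
#'
#' Rank-sum comparison of two independent samples. The exact null
#' distribution is enumerated when `n_x * n_y <= 400` and the data are
#' tie-free; otherwise the normal approximation with tie correction (no
#' continuity correction, so the two-group Kruskal-Wallis identity H = z^2
#' holds exactly) is used.
#'
#' @param x,y Numeric samples, both nonempty.
#' @return One-row tibble: `statistic` (U for `x`), `p_value`, `n_x`, `n_y`,
#'   `method`.
#' @export
mann_whitney <- function(x, y) {
  if (length(x) == 0 || length(y) == 0) {
    abort("both samples must be nonempty", class = "dkclust_validation_error")
  }
  ties <- anyDuplicated(c(x, y)) > 0
  exact <- !ties && length(x) * length(y) <= 400
  ht <- suppressWarnings(wilcox.test(x, y, exact = exact, correct = FALSE))
  tibble::tibble(
    statistic = unname(ht$statistic), p_value = ht$p.value,
    n_x = length(x), n_y = length(y),
    method = if (exact) "exact" else "normal approximation"
  )
}

#' Kruskal-Wallis rank test across groups
#'
#' Nonparametric one-way analysis of variance on ranks with tie correction;
#' p-value from the chi-square approximation with (g - 1) degrees of
#' freedom.
#'
#' @param groups List of numeric samples (>= 2 groups, each nonempty).
#' @return One-row tibble: `statistic` (H), `df`, `p_value`, group sizes as
#'   a list column.
#' @export
kruskal_wallis <- function(groups) {
  if (length(groups) < 2 || any(lengths(groups) == 0)) {
    abort("need >= 2 nonempty groups", class = "dkclust_validation_error")
  }
  all_vals <- unlist(groups)
  if (length(unique(all_vals)) == 1) {
    abort("all observations identical; H is undefined under tie correction",
          class = "dkclust_degenerate_error")
  }
  ht <- kruskal.test(groups)
  tibble::tibble(statistic = unname(ht$statistic),
                 df = unname(ht$parameter),
                 p_value = ht$p.value,
                 n = list(lengths(groups)))
}

#' Dunn's post-hoc pairwise tests with Sidak correction
#'
#' Rank-based pairwise z-tests on the pooled ranks (tie-corrected), run
#' after a Kruskal-Wallis test. Each pair's raw two-sided p is adjusted as
#' `1 - (1 - p)^m` (Sidak, m = number of pairs, capped at 1); the
#' per-comparison significance level `1 - (1 - alpha)^(1/m)` is also
#' reported.
#'
#' @param groups Named (or unnamed) list of numeric samples, >= 2 groups.
#' @param alpha Familywise significance level, default 0.05.
#' @return Tibble with one row per pair: `group1`, `group2`, `z`, `p_value`,
#'   `p_sidak`, `significant`; attribute `per_comparison_alpha`.
#' @export
dunn_sidak_posthoc <- function(groups, alpha = 0.05) {
  g <- length(groups)
  if (g < 2) abort("need >= 2 groups", class = "dkclust_validation_error")
  nms <- names(groups) %||% paste0("group", seq_len(g))
  sizes <- lengths(groups)
  pooled <- unlist(groups)
  N <- length(pooled)
  r <- rank(pooled)
  grp <- rep(seq_len(g), sizes)
  rbar <- tapply(r, grp, mean)
  tie_tab <- table(pooled)
  tie_term <- sum(tie_tab^3 - tie_tab) / (12 * (N - 1))
  pairs <- utils::combn(g, 2)
  m <- ncol(pairs)
  res <- purrr::map_dfr(seq_len(m), function(j) {
    i1 <- pairs[1, j]; i2 <- pairs[2, j]
    se <- sqrt((N * (N + 1) / 12 - tie_term) * (1 / sizes[i1] + 1 / sizes[i2]))
    z <- (rbar[[i1]] - rbar[[i2]]) / se
    p <- 2 * pnorm(-abs(z))
    tibble::tibble(group1 = nms[i1], group2 = nms[i2], z = z, p_value = p,
                   p_sidak = min(1, 1 - (1 - p)^m))
  })
  lvl <- 1 - (1 - alpha)^(1 / m)
  res$significant <- res$p_value <= lvl
  attr(res, "per_comparison_alpha") <- lvl
  res
}

#' Cohen's d effect size
#'
#' Standardized mean difference `(mean(x) - mean(y)) / s_pooled`, with the
#' pooled variance `((n1-1) s1^2 + (n2-1) s2^2) / (n1 + n2 - 2)`.
#'
#' @param x,y Numeric samples with positive pooled SD.
#' @return A single number.
#' @export
cohens_d <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  if (n1 < 2 || n2 < 2) abort("need >= 2 values per sample", class = "dkclust_validation_error")
  sp <- sqrt(((n1 - 1) * var(x) + (n2 - 1) * var(y)) / (n1 + n2 - 2))
  if (!is.finite(sp) || sp == 0) {
    abort("pooled SD is zero; d undefined", class = "dkclust_degenerate_error")
  }
  (mean(x) - mean(y)) / sp
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment, monotone-enforced, capped at 1,
#' returned in the input order.
#'
#' @param p_values Numeric vector of p-values in \[0, 1\].
#' @return Adjusted p-values, same order.
#' @export
bh_adjust <- function(p_values) {
  if (anyNA(p_values) || any(p_values < 0 | p_values > 1)) {
    abort("p-values must be in [0, 1]", class = "dkclust_validation_error")
  }
  p.adjust(p_values, method = "BH")
}

#' Nonparametric group comparison of diffusion parameters
#'
#' For each parameter column, runs Kruskal-Wallis across the tissue groups
#' followed by Dunn-Sidak pairwise post-hoc tests and Cohen's d per pair —
#' the ROI-level comparison of mean D and K between healthy, tumor and
#' peritumor tissue.
#'
#' @param df Tibble with a `roi` grouping column and numeric parameter
#'   columns (e.g. one row per subject-ROI with mean `D` and `K`).
#' @param parameters Character vector of parameter column names.
#' @param alpha Familywise level for the post-hoc tests.
#' @return Tibble: `parameter`, `comparison`, `kw_p`, `z`, `p_value`,
#'   `p_sidak`, `cohens_d`, `significant`.
#' @export
group_stats <- function(df, parameters = c("D", "K"), alpha = 0.05) {
  stopifnot("roi" %in% names(df))
  purrr::map_dfr(parameters, function(par) {
    groups <- split(df[[par]], df$roi)
    groups <- groups[lengths(groups) > 0]
    kw <- kruskal_wallis(groups)
    ph <- dunn_sidak_posthoc(groups, alpha = alpha)
    ph$cohens_d <- purrr::map2_dbl(ph$group1, ph$group2, function(a, b)
      cohens_d(groups[[a]], groups[[b]]))
    tibble::tibble(parameter = par,
                   comparison = paste(ph$group1, "vs", ph$group2),
                   kw_p = kw$p_value, z = ph$z, p_value = ph$p_value,
                   p_sidak = ph$p_sidak, cohens_d = ph$cohens_d,
                   significant = ph$significant)
  })
}
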