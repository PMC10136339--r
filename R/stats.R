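#' Wilcoxon signed-rank test with effect size
#'
#' Paired two-sided signed-rank test. Zero differences are dropped; ranks of
#' tied absolute differences are averaged. By default (`method = "normal"`)
#' the Z statistic uses the normal approximation with continuity correction
#' and tie-corrected variance, and the effect size is r = |Z|/sqrt(n)
#' with `n` the number of pairs supplied (before dropping zeros).
#' `method = "exact"` enumerates all sign assignments of the ranks (feasible
#' for small n) and reports the exact two-sided p.
#'
#' @param paired_a,paired_b numeric vectors of equal length (n >= 5 for the
#'   normal approximation).
#' @param method `"normal"` or `"exact"`.
#' @return List with `statistic` (W+, sum of positive ranks), `z`, `p_value`,
#'   `effect_size_r`, `n` (pairs supplied), `n_used` (nonzero differences).
#' @examples
#' # the effect size formula: r = Z / sqrt(n)
#' abs(2.67) / sqrt(9)  # 0.89
#' @export
wilcoxon_signed_rank <- function(paired_a, paired_b,
                                 method = c("normal", "exact")) {
  method <- match.arg(method)
  stopifnot(length(paired_a) == length(paired_b))
  n_pairs <- length(paired_a)
  d <- paired_a - paired_b
  d <- d[d != 0]
  m <- length(d)
  if (m == 0) stop("all paired differences are zero; test degenerate")
  if (method == "normal" && m < 5)
    warning("fewer than 5 nonzero differences; normal approximation is crude")
  r <- rank(abs(d))
  w_pos <- sum(r[d > 0])
  mu <- m * (m + 1) / 4
  if (method == "exact") {
    if (m > 16) stop("exact enumeration limited to 16 nonzero differences")
    # all 2^m sign assignments of the ranks
    w_all <- vapply(seq_len(2^m) - 1L, function(mask) {
      sum(r[bitwAnd(bitwShiftR(mask, seq_len(m) - 1L), 1L) == 1L])
    }, numeric(1))
    p <- mean(abs(w_all - mu) >= abs(w_pos - mu) - 1e-12)
    sigma <- sqrt(m * (m + 1) * (2 * m + 1) / 24 - tie_correction(r))
    z <- (w_pos - mu) / sigma
  } else {
    sigma <- sqrt(m * (m + 1) * (2 * m + 1) / 24 - tie_correction(r))
    if (sigma == 0) stop("zero variance (all ranks tied out)")
    cc <- sign(w_pos - mu) * 0.5  # continuity correction toward the mean
    z <- (w_pos - mu - cc) / sigma
    p <- 2 * stats::pnorm(-abs(z))
  }
  list(statistic = w_pos, z = z, p_value = min(p, 1),
       effect_size_r = abs(z) / sqrt(n_pairs),
       n = n_pairs, n_used = m, method = method)
}

#' Effect size of a Z statistic
#'
#' The standardised effect size of a nonparametric paired test:
#' r = |Z|/sqrt(n), with `n` the sample size (number of pairs).
#'
#' @param z Z statistic.
#' @param n sample size.
#' @return Effect size r.
#' @examples
#' effect_size_r(2.67, 9)  # 0.89
#' @export
effect_size_r <- function(z, n) {
  stopifnot(n >= 1)
  abs(z) / sqrt(n)
}

tie_correction <- function(r) {
  tab <- table(r)
  sum(tab^3 - tab) / 48
}

#' One-way ANOVA with Bonferroni-corrected pairwise comparisons
#'
#' Standard fixed-effects one-way F test across groups, followed (when more
#' than two groups are given) by pairwise pooled-variance two-sample t tests
#' whose p values are multiplied by the number of comparisons and capped at 1.
#'
#' @param groups named list of numeric vectors (>= 2 groups, each n >= 2).
#' @return List with `f`, `df`, `overall_p`, and `pairwise` (data frame:
#'   `group1`, `group2`, `t`, `p_adjusted`).
#' @export
anova_bonferroni <- function(groups) {
  stopifnot(is.list(groups), length(groups) >= 2,
            all(vapply(groups, length, 1L) >= 2))
  if (is.null(names(groups)))
    names(groups) <- paste0("group", seq_along(groups))
  y <- unlist(groups, use.names = FALSE)
  g <- factor(rep(names(groups), lengths(groups)), levels = names(groups))
  if (all(vapply(groups, stats::var, 1) == 0) &&
      stats::var(vapply(groups, mean, 1)) == 0)
    return(list(f = 0, df = c(length(groups) - 1, length(y) - length(groups)),
                overall_p = 1, pairwise = NULL))
  fit <- stats::aov(y ~ g)
  s <- summary(fit)[[1]]
  f <- s[["F value"]][1]
  p <- s[["Pr(>F)"]][1]
  pairs <- utils::combn(names(groups), 2)
  ncomp <- ncol(pairs)
  pw <- data.frame(group1 = pairs[1, ], group2 = pairs[2, ],
                   t = NA_real_, p_adjusted = NA_real_)
  for (k in seq_len(ncomp)) {
    tt <- stats::t.test(groups[[pairs[1, k]]], groups[[pairs[2, k]]],
                        var.equal = TRUE)
    pw$t[k] <- unname(tt$statistic)
    pw$p_adjusted[k] <- min(tt$p.value * ncomp, 1)
  }
  list(f = f, df = c(s[["Df"]][1], s[["Df"]][2]), overall_p = p,
       pairwise = pw)
}

#' Kolmogorov-Smirnov normality test (Lilliefors corrected)
#'
#' Tests a sample against the normal law. Because the mean and SD are
#' estimated from the sample itself, the Lilliefors-corrected p value is
#' reported rather than the naive one-sample KS p (which would be strongly
#' conservative).
#'
#' @param sample numeric vector, n >= 5, non-constant.
#' @return List with `statistic` (the KS distance) and `p_value`.
#' @export
ks_normality <- function(sample) {
  stopifnot(length(sample) >= 5)
  if (stats::sd(sample) == 0) stop("constant sample")
  lt <- nortest::lillie.test(sample)
  list(statistic = unname(lt$statistic), p_value = lt$p.value)
}
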