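#' One-way ANOVA gated pairwise t-tests
#'
#' One-way ANOVA across groups; pairwise two-tailed t-tests (pooled variance
#' by default) are computed only when the ANOVA p-value is below
#' `gate_alpha`, mirroring the usual "test subgroups only if group
#' differences exist" protocol.
#'
#' @param values numeric vector.
#' @param groups group label per value (at least 2 groups with 2+ values).
#' @param gate_alpha ANOVA gate (default 0.05).
#' @param var_equal pooled-variance t-tests (default `TRUE`); `FALSE` = Welch.
#' @return list with `F`, `df`, `p` and `pairwise` (a data.frame, or `NULL`
#'   when the gate was not passed).
#' @export
anova_then_ttests <- function(values, groups, gate_alpha = 0.05,
                              var_equal = TRUE) {
  keep <- !is.na(values) & !is.na(groups)
  values <- values[keep]; groups <- factor(groups[keep])
  if (nlevels(groups) < 2L) stop("need at least 2 groups")
  if (any(table(groups) < 2L)) stop("every group needs at least 2 values")
  if (stats::var(values) == 0) stop("all values identical; F is undefined")
  fit <- stats::oneway.test(values ~ groups, var.equal = TRUE)
  res <- list(F = unname(fit$statistic),
              df = unname(fit$parameter),
              p = fit$p.value,
              pairwise = NULL)
  if (!is.na(res$p) && res$p < gate_alpha) {
    lev <- levels(groups)
    pairs <- utils::combn(lev, 2L)
    pw <- data.frame(group_a = pairs[1L, ], group_b = pairs[2L, ],
                     t = NA_real_, df = NA_real_, p = NA_real_,
                     stringsAsFactors = FALSE)
    for (j in seq_len(ncol(pairs))) {
      a <- values[groups == pairs[1L, j]]
      b <- values[groups == pairs[2L, j]]
      if (stats::sd(c(a, b)) == 0) {
        pw$t[j] <- 0; pw$df[j] <- length(a) + length(b) - 2; pw$p[j] <- 1
        next
      }
      tt <- stats::t.test(a, b, var.equal = var_equal)
      pw$t[j] <- unname(tt$statistic)
      pw$df[j] <- unname(tt$parameter)
      pw$p[j] <- tt$p.value
    }
    res$pairwise <- pw
  }
  res
}

#' "N-1" chi-squared test on a 2x2 table
#'
#' The Pearson chi-squared statistic scaled by `(N-1)/N` (the small-sample
#' variant recommended for 2x2 comparisons of two proportions), with the
#' p-value from the chi-squared distribution with 1 degree of freedom.
#' Layout: rows are outcomes (e.g. ENS category I vs not-I), columns are
#' conditions.
#'
#' @param a,b,c_,d_ the four cell counts: `a`,`b` first row, `c_`,`d_`
#'   second row.
#' @return list with `statistic` and `p`.
#' @export
n1_chisq_2x2 <- function(a, b, c_, d_) {
  tab <- c(a, b, c_, d_)
  if (any(tab < 0) || any(tab != round(tab))) stop("counts must be non-negative integers")
  n <- sum(tab)
  if (n < 2) stop("need a total count of at least 2")
  if (any(c(a + b, c_ + d_, a + c_, b + d_) == 0)) {
    stop("zero margin; the chi-squared statistic is undefined")
  }
  pearson <- (a * d_ - b * c_)^2 * n /
    ((a + b) * (c_ + d_) * (a + c_) * (b + d_))
  stat <- pearson * (n - 1) / n
  list(statistic = stat, p = stats::pchisq(stat, df = 1L, lower.tail = FALSE))
}

#' Neuron density per 100 micrometres of gut
#'
#' Normalizes an enteric neuron count to the measured gut length:
#' `count / gut_length_um * 100`.
#'
#' @param neuron_count non-negative neuron count(s).
#' @param gut_length_um gut length(s) in micrometres, strictly positive.
#' @return neurons per 100 um.
#' @export
neuron_density <- function(neuron_count, gut_length_um) {
  if (any(gut_length_um <= 0)) stop("gut length must be positive")
  if (any(neuron_count < 0)) stop("neuron count must be non-negative")
  neuron_count / gut_length_um * 100
}

#' Dunnett many-to-one comparisons by Monte Carlo
#'
#' Compares every treatment group with the control group under the
#' equal-variance one-way layout. Family-wise adjusted p-values are computed
#' against the Monte-Carlo null distribution of the maximum absolute
#' Dunnett t statistic (shared control mean and pooled variance are
#' resampled, preserving the comparisons' correlation).
#'
#' @param values numeric vector.
#' @param groups group label per value.
#' @param control control group label.
#' @param n_mc Monte-Carlo draws (default 1e5).
#' @param seed integer seed.
#' @return data.frame with `group`, `t`, `p_adjusted`.
#' @export
dunnett_vs_control <- function(values, groups, control, n_mc = 1e5,
                               seed = 1L) {
  groups <- as.character(groups)
  if (!control %in% groups) stop("control label '", control, "' not present")
  lev <- unique(groups)
  if (any(table(groups) < 2L)) stop("every group needs at least 2 values")
  trt <- setdiff(lev, control)
  n <- vapply(lev, function(g) sum(groups == g), integer(1L))
  names(n) <- lev
  mu <- vapply(lev, function(g) mean(values[groups == g]), numeric(1L))
  names(mu) <- lev
  df <- length(values) - length(lev)
  s2 <- sum((values - mu[groups])^2) / df
  t_obs <- (mu[trt] - mu[control]) /
    sqrt(s2 * (1 / n[trt] + 1 / n[control]))

  set.seed(seed)
  k <- length(trt)
  z_ctrl <- stats::rnorm(n_mc) / sqrt(n[control])
  z_trt <- matrix(stats::rnorm(n_mc * k), n_mc, k)
  z_trt <- sweep(z_trt, 2L, sqrt(n[trt]), "/")
  s_null <- sqrt(stats::rchisq(n_mc, df) / df)
  t_null <- (z_trt - z_ctrl) /
    sweep(matrix(s_null, n_mc, k), 2L, sqrt(1 / n[trt] + 1 / n[control]), "*")
  max_abs <- apply(abs(t_null), 1L, max)
  p_adj <- vapply(abs(t_obs), function(ti) mean(max_abs >= ti), numeric(1L))
  data.frame(group = trt, t = unname(t_obs), p_adjusted = unname(p_adj),
             stringsAsFactors = FALSE)
}
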