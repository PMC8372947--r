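ENS_CLASSES <- c("ENS_GDNF", "ENS_noGDNF", "intestine")

check_study <- function(mat, classes) {
  mat <- as.matrix(mat)
  if (!is.numeric(mat)) stop("expression matrix must be numeric (log2 scale)")
  if (length(classes) != ncol(mat)) {
    stop("one class label per sample (column) is required")
  }
  mat
}

#' Variation and missingness gene filter
#'
#' A gene is retained when at least `fc_frac` of its non-missing values lie
#' at least `fc_thresh`-fold (in either direction) from the gene's median,
#' and less than `missing_max` of samples are missing. Genes with all values
#' missing are excluded.
#'
#' @param mat genes x samples matrix of log2 expression (NA allowed).
#' @param fc_frac minimum fraction of samples beyond the fold-change band
#'   (default 0.20).
#' @param fc_thresh linear fold change defining the band (default 1.5).
#' @param missing_max maximum tolerated missing fraction (default 0.50).
#' @return logical vector over genes (rows), `TRUE` = retained.
#' @export
filter_genes <- function(mat, fc_frac = 0.20, fc_thresh = 1.5,
                         missing_max = 0.50) {
  mat <- as.matrix(mat)
  band <- log2(fc_thresh)
  n <- ncol(mat)
  apply(mat, 1L, function(x) {
    obs <- !is.na(x)
    if (!any(obs)) return(FALSE)
    if (sum(!obs) / n >= missing_max) return(FALSE)
    med <- stats::median(x[obs])
    mean(abs(x[obs] - med) >= band) >= fc_frac
  })
}

#' Quantile normalization
#'
#' Replaces every sample's sorted non-missing values by the across-sample
#' mean of order statistics; tied values receive the mean of their tied
#' ranks' targets and missing values stay missing (interpolated quantile
#' targets are used when samples differ in missingness). Delegates to
#' [limma::normalizeQuantiles()].
#'
#' @param mat genes x samples matrix of log2 expression.
#' @return normalized matrix of the same shape, NA pattern preserved.
#' @export
quantile_normalize <- function(mat) {
  mat <- as.matrix(mat)
  n_obs <- colSums(!is.na(mat))
  if (any(n_obs < 2L)) {
    stop("sample(s) with fewer than 2 non-missing values: ",
         paste(colnames(mat)[n_obs < 2L], collapse = ", "))
  }
  out <- limma::normalizeQuantiles(mat, ties = TRUE)
  dimnames(out) <- dimnames(mat)
  out
}

#' Per-gene pooled within-class residual variance
#'
#' Complete-case within each class; returns the per-gene residual variance
#' `s2` and residual degrees of freedom `m = sum_c (n_c - 1)`.
#'
#' @param mat genes x samples log2 matrix.
#' @param classes per-sample class labels.
#' @return list with numeric vectors `s2` and `m` (one entry per gene).
#' @export
residual_variances <- function(mat, classes) {
  mat <- check_study(mat, classes)
  ss <- matrix(0, nrow(mat), 1L)
  m <- matrix(0, nrow(mat), 1L)
  for (cl in unique(classes)) {
    x <- mat[, classes == cl, drop = FALSE]
    nobs <- rowSums(!is.na(x))
    mu <- rowMeans(x, na.rm = TRUE)
    dev2 <- (x - mu)^2
    ss <- ss + ifelse(nobs > 0L, rowSums(dev2, na.rm = TRUE), 0)
    m <- m + pmax(nobs - 1L, 0L)
  }
  s2 <- ifelse(m > 0, ss / m, NA_real_)
  list(s2 = as.numeric(s2), m = as.numeric(m))
}

#' Fit the random variance model
#'
#' Fits the inverse-gamma variance prior of the random variance model:
#' per-gene precisions `1/sigma^2 ~ Gamma(a, b)` (shape `a`, scale `b`), so
#' that the observed residual variances satisfy `s2 * a * b ~ F(m, 2a)`.
#' `(a, b)` maximize the F likelihood, by numeric optimization from a
#' moment-based start; convergence tolerance 1e-8 on the log-likelihood.
#'
#' @param s2 per-gene residual variances (positive; non-positive or missing
#'   values are dropped).
#' @param m residual degrees of freedom, scalar or per-gene vector.
#' @return object of class `rvm_fit` with elements `a`, `b`, `loglik`,
#'   `n_genes`.
#' @export
fit_rvm <- function(s2, m) {
  keep <- !is.na(s2) & s2 > 0 & !is.na(rep_len(m, length(s2))) &
    rep_len(m, length(s2)) >= 1
  s2 <- s2[keep]
  m <- rep_len(m, length(keep))[keep]
  if (length(s2) < 2L) stop("need at least 2 positive residual variances")
  if (stats::var(log(s2)) == 0) stop("all residual variances are equal; the variance prior is unidentifiable")
  if (length(s2) < 50L) {
    warning("fewer than 50 genes; random variance model fit may be unstable")
  }
  # moment start: var(log s2) ~ trigamma(m/2) + trigamma(a);
  # E[log(a b s2)] = digamma(m/2) - log(m/2) - digamma(a) + log(a)
  vlog <- stats::var(log(s2))
  a0 <- limma::trigammaInverse(max(vlog - mean(trigamma(m / 2)), 0.02))
  log_b0 <- mean(digamma(m / 2) - log(m / 2)) - digamma(a0) + log(a0) -
    mean(log(s2)) - log(a0)
  negll <- function(theta) {
    a <- exp(theta[1L]); b <- exp(theta[2L])
    x <- a * b * s2
    -sum(stats::df(x, df1 = m, df2 = 2 * a, log = TRUE) + log(a * b))
  }
  opt <- stats::optim(c(log(a0), log_b0), negll, method = "Nelder-Mead",
                      control = list(reltol = 1e-10, maxit = 2000))
  if (opt$convergence != 0L) {
    stop("random variance model fit did not converge (code ",
         opt$convergence, ", value ", format(opt$value), ")")
  }
  structure(list(a = exp(opt$par[1L]), b = exp(opt$par[2L]),
                 loglik = -opt$value, n_genes = length(s2)),
            class = "rvm_fit")
}

#' @export
print.rvm_fit <- function(x, ...) {
  cat("Random variance model fit: a =", format(x$a, digits = 4),
      ", b =", format(x$b, digits = 4),
      " (", x$n_genes, "genes, logLik", format(x$loglik, digits = 6), ")\n")
  invisible(x)
}

# t statistics for one A-vs-B split, vectorized over genes.
# Returns t (NA when either class has < 2 non-missing values per gene).
rvm_t_core <- function(mat, is_a, is_b, fit) {
  xa <- mat[, is_a, drop = FALSE]
  xb <- mat[, is_b, drop = FALSE]
  na_ <- rowSums(!is.na(xa))
  nb_ <- rowSums(!is.na(xb))
  ma <- rowMeans(xa, na.rm = TRUE)
  mb <- rowMeans(xb, na.rm = TRUE)
  ssa <- rowSums((xa - ma)^2, na.rm = TRUE)
  ssb <- rowSums((xb - mb)^2, na.rm = TRUE)
  m <- na_ + nb_ - 2
  ok <- na_ >= 2L & nb_ >= 2L
  s2 <- ifelse(ok, (ssa + ssb) / m, NA_real_)
  if (is.null(fit)) {
    shrunk <- s2
    dfree <- m
  } else {
    shrunk <- (m * s2 + 2 / fit$b) / (m + 2 * fit$a)
    dfree <- m + 2 * fit$a
  }
  t <- (ma - mb) / sqrt(shrunk * (1 / na_ + 1 / nb_))
  t[!ok] <- NA_real_
  list(t = t, df = ifelse(ok, dfree, NA_real_), diff = ma - mb,
       n_a = na_, n_b = nb_)
}

#' Random-variance-model moderated two-sample t-test
#'
#' Per gene: pooled residual variance `s2` with `m = n_A + n_B - 2`
#' complete-case degrees of freedom, shrunken variance
#' `(m*s2 + 2/b) / (m + 2a)`, `t = (mean_A - mean_B) / sqrt(shrunk * (1/n_A
#' + 1/n_B))` on `m + 2a` degrees of freedom. With `fit = NULL` the ordinary
#' pooled t-test is computed (the `a -> 0`, `1/b -> 0` limit). Genes with
#' fewer than 2 non-missing values in either class are skipped (NA).
#'
#' @param mat genes x samples log2 matrix.
#' @param classes per-sample class labels.
#' @param contrast character vector `c(class_A, class_B)`; fold change and t
#'   are signed A minus B.
#' @param fit an [fit_rvm()] object, or `NULL` for the unmoderated test.
#' @return data.frame with columns `gene_id`, `t`, `df`, `fold_change`
#'   (linear, `2^(mean_A - mean_B)`), `p` (two-sided parametric), `n_a`, `n_b`.
#' @export
rvm_ttest <- function(mat, classes, contrast, fit) {
  mat <- check_study(mat, classes)
  stopifnot(length(contrast) == 2L)
  if (!all(contrast %in% classes)) {
    stop("contrast class(es) absent from the study: ",
         paste(setdiff(contrast, classes), collapse = ", "))
  }
  res <- rvm_t_core(mat, classes == contrast[1L], classes == contrast[2L], fit)
  data.frame(
    gene_id = if (is.null(rownames(mat))) as.character(seq_len(nrow(mat))) else rownames(mat),
    t = res$t, df = res$df, fold_change = 2^res$diff,
    p = 2 * stats::pt(-abs(res$t), df = res$df),
    n_a = res$n_a, n_b = res$n_b,
    stringsAsFactors = FALSE
  )
}

#' Permutation p-values for a class contrast
#'
#' Class labels of the two contrast classes are permuted identically across
#' genes; per gene `p = (1 + #\{permutations with |t*| >= |t|\}) / (B + 1)`
#' (add-one estimator, never zero). When the number of distinct label
#' assignments is at most `B`, all assignments are enumerated instead and
#' the p-value is the exact fraction (the observed assignment included).
#'
#' @param mat,classes,contrast,fit as in [rvm_ttest()].
#' @param B number of random permutations (default 1000).
#' @param seed integer seed for reproducibility.
#' @param method `"auto"` (exhaustive when the number of distinct
#'   assignments is at most `B`), or force `"exhaustive"` / `"mc"`.
#' @return data.frame with `gene_id`, `perm_p` and attribute `exhaustive`.
#' @export
permutation_p <- function(mat, classes, contrast, fit, B = 1000, seed = 1L,
                          method = c("auto", "exhaustive", "mc")) {
  method <- match.arg(method)
  if (B < 1) stop("B must be >= 1")
  mat <- check_study(mat, classes)
  obs <- rvm_t_core(mat, classes == contrast[1L], classes == contrast[2L], fit)
  t_obs <- abs(obs$t)
  in_contrast <- which(classes %in% contrast)
  sub <- mat[, in_contrast, drop = FALSE]
  n_a <- sum(classes[in_contrast] == contrast[1L])
  n <- length(in_contrast)
  n_assign <- choose(n, n_a)

  count <- rep(0, nrow(mat))
  valid <- rep(0, nrow(mat))
  tally <- function(idx_a) {
    is_a <- seq_len(n) %in% idx_a
    t_star <- abs(rvm_t_core(sub, is_a, !is_a, fit)$t)
    cmp <- !is.na(t_star) & !is.na(t_obs)
    count[cmp & t_star >= t_obs] <<- count[cmp & t_star >= t_obs] + 1
    valid[cmp] <<- valid[cmp] + 1
  }
  exhaustive <- switch(method, auto = n_assign <= B,
                       exhaustive = TRUE, mc = FALSE)
  if (exhaustive && n_assign > 1e5) {
    stop("too many distinct assignments (", n_assign, ") to enumerate")
  }
  if (exhaustive) {
    combos <- utils::combn(n, n_a)
    for (j in seq_len(ncol(combos))) tally(combos[, j])
    p <- ifelse(valid > 0, count / valid, NA_real_)
  } else {
    set.seed(seed)
    for (j in seq_len(B)) tally(sample.int(n, n_a))
    p <- ifelse(valid > 0, (1 + count) / (valid + 1), NA_real_)
  }
  p[is.na(t_obs)] <- NA_real_
  out <- data.frame(
    gene_id = if (is.null(rownames(mat))) as.character(seq_len(nrow(mat))) else rownames(mat),
    perm_p = p, stringsAsFactors = FALSE
  )
  attr(out, "exhaustive") <- exhaustive
  out
}

#' Call ENS genes from a filtered, normalized study
#'
#' An ENS gene is higher expressed in isolated ENS cells than in the
#' comparator (whole intestine / other intestinal cells) in the required
#' contrasts: fold change at least `fc_min`, permutation p below `alpha`,
#' direction ENS-higher. Under `rule = "both"` (default) both the
#' GDNF-treated and untreated ENS classes must pass; `rule = "any"` accepts
#' either.
#'
#' @param mat genes x samples log2 matrix (filtered and normalized).
#' @param classes per-sample labels among `ENS_GDNF`, `ENS_noGDNF` and the
#'   comparator.
#' @param fit an [fit_rvm()] object (see [residual_variances()]).
#' @param fc_min minimum linear fold change (default 1.5).
#' @param alpha nominal per-test significance level (default 0.05; no
#'   multiple-testing correction is applied).
#' @param B,seed permutation settings, see [permutation_p()].
#' @param rule `"both"` or `"any"` contrast requirement.
#' @param comparator comparator class label (default `"intestine"`).
#' @return data.frame with per-contrast fold changes, t statistics and
#'   permutation p-values, and the logical `is_ens_gene` call.
#' @export
call_ens_genes <- function(mat, classes, fit, fc_min = 1.5, alpha = 0.05,
                           B = 1000, seed = 1L, rule = c("both", "any"),
                           comparator = "intestine") {
  rule <- match.arg(rule)
  mat <- check_study(mat, classes)
  for (cl in c("ENS_GDNF", "ENS_noGDNF", comparator)) {
    if (sum(classes == cl) < 2L) {
      stop("class ", cl, " needs at least 2 samples")
    }
  }
  one <- function(ens_class, seed_off) {
    tt <- rvm_ttest(mat, classes, c(ens_class, comparator), fit)
    pp <- permutation_p(mat, classes, c(ens_class, comparator), fit,
                        B = B, seed = seed + seed_off)
    data.frame(fold_change = tt$fold_change, t = tt$t, perm_p = pp$perm_p)
  }
  c1 <- one("ENS_GDNF", 0L)
  c2 <- one("ENS_noGDNF", 1L)
  pass <- function(cc) {
    !is.na(cc$perm_p) & cc$fold_change >= fc_min & cc$perm_p < alpha &
      cc$fold_change > 1
  }
  is_ens <- if (rule == "both") pass(c1) & pass(c2) else pass(c1) | pass(c2)
  data.frame(
    gene_id = if (is.null(rownames(mat))) as.character(seq_len(nrow(mat))) else rownames(mat),
    fc_gdnf = c1$fold_change, t_gdnf = c1$t, perm_p_gdnf = c1$perm_p,
    fc_nogdnf = c2$fold_change, t_nogdnf = c2$t, perm_p_nogdnf = c2$perm_p,
    is_ens_gene = is_ens, stringsAsFactors = FALSE
  )
}

#' ENS-gene pipeline: normalize, filter, fit, test, call
#'
#' Runs the full calling protocol on a raw log2 matrix: quantile
#' normalization of the complete matrix (normalization happens at import,
#' before any gene is dropped, because it assumes the bulk of genes is
#' unchanged), then the variation / missingness filter, the
#' random-variance-model fit on the pooled filtered matrix, moderated
#' t-tests with permutation p-values for both ENS contrasts, and the
#' ENS-gene call.
#'
#' @inheritParams call_ens_genes
#' @param average_duplicates average rows sharing a gene id before filtering
#'   (replicate spots).
#' @param ... passed to [call_ens_genes()].
#' @return list with elements `calls` (per-gene results over retained genes),
#'   `retained` (logical filter over input genes), `fit` (the `rvm_fit`).
#' @export
ens_pipeline <- function(mat, classes, fc_min = 1.5, alpha = 0.05,
                         B = 1000, seed = 1L, average_duplicates = TRUE, ...) {
  mat <- check_study(mat, classes)
  if (average_duplicates && !is.null(rownames(mat)) &&
      anyDuplicated(rownames(mat))) {
    mat <- do.call(rbind, lapply(split(seq_len(nrow(mat)), rownames(mat)),
                                 function(i) colMeans(mat[i, , drop = FALSE],
                                                      na.rm = TRUE)))
    mat[is.nan(mat)] <- NA_real_
  }
  mat <- quantile_normalize(mat)
  retained <- filter_genes(mat)
  sub <- mat[retained, , drop = FALSE]
  rv <- residual_variances(sub, classes)
  fit <- fit_rvm(rv$s2, rv$m)
  calls <- call_ens_genes(sub, classes, fit, fc_min = fc_min, alpha = alpha,
                          B = B, seed = seed, ...)
  list(calls = calls, retained = retained, fit = fit)
}
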