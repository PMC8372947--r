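test_that("variation/missingness filter implements the stated rule", {
  mat <- rbind(
    flat = rep(5, 10),                      # no variation -> dropped
    up = c(rep(5, 7), rep(8, 3)),           # 30% beyond 1.5-fold -> kept
    holey = c(rep(NA, 6), 1, 9, 1, 9),      # 60% missing -> dropped
    gone = rep(NA_real_, 10)                # all missing -> dropped
  )
  keep <- filter_genes(mat)
  expect_identical(unname(keep), c(FALSE, TRUE, FALSE, FALSE))

  # random genes: retained set equals direct evaluation of the rule
  set.seed(3)
  rnd <- matrix(rnorm(1000 * 12, sd = 1.2), 1000, 12)
  rnd[sample(length(rnd), 1500)] <- NA
  got <- filter_genes(rnd)
  want <- apply(rnd, 1, function(x) {
    if (all(is.na(x))) return(FALSE)
    if (mean(is.na(x)) >= 0.5) return(FALSE)
    mean(abs(x[!is.na(x)] - median(x, na.rm = TRUE)) >= log2(1.5)) >= 0.2
  })
  expect_identical(got, want)
})

test_that("quantile normalization maps samples onto mean order statistics", {
  m <- cbind(a = c(1, 2, 3), b = c(4, 5, 6))
  qn <- quantile_normalize(m)
  expect_equal(unname(qn[, "a"]), c(2.5, 3.5, 4.5))
  expect_equal(unname(qn[, "b"]), c(2.5, 3.5, 4.5))

  # identical samples are a fixed point
  same <- cbind(s1 = c(2, 7, 4), s2 = c(2, 7, 4))
  expect_equal(quantile_normalize(same), same)

  # complete samples share one sorted vector afterwards; NAs stay put
  set.seed(8)
  big <- matrix(rnorm(600), 100, 6)
  big[3, 2] <- NA
  qn <- quantile_normalize(big)
  expect_true(is.na(qn[3, 2]))
  full <- setdiff(1:6, 2)
  sorted <- apply(qn[, full], 2, sort)
  expect_true(all(abs(sorted - sorted[, 1]) < 1e-9))

  bad <- cbind(ok = 1:5, thin = c(1, NA, NA, NA, NA))
  expect_error(quantile_normalize(bad), "fewer than 2")
})

simulate_model_variances <- function(n, a, b, m, seed) {
  set.seed(seed)
  sigma2 <- 1 / rgamma(n, shape = a, scale = b)
  sigma2 * rchisq(n, df = m) / m
}

test_that("random variance model fit recovers planted prior parameters", {
  s2 <- simulate_model_variances(3000, a = 2.0, b = 1.5, m = 8, seed = 21)
  fit <- fit_rvm(s2, m = 8)
  expect_lt(abs(fit$a - 2.0) / 2.0, 0.10)
  expect_lt(abs(fit$b - 1.5) / 1.5, 0.10)

  # scaling all variances by c leaves a invariant and scales b by 1/c
  fit4 <- fit_rvm(4 * s2, m = 8)
  expect_equal(fit4$a, fit$a, tolerance = 1e-4)
  expect_equal(fit4$b, fit$b / 4, tolerance = 1e-4)

  expect_error(fit_rvm(s2[1], m = 8), "at least 2")
  expect_error(fit_rvm(rep(1, 100), m = 8), "unidentifiable")
})

test_that("random variance model fit agrees with an independent F-distribution fitter", {
  s2 <- simulate_model_variances(4000, a = 3.0, b = 0.8, m = 6, seed = 5)
  fit <- fit_rvm(s2, m = 6)
  # limma parameterizes the same model as s2 ~ s0^2 F(m, df0):
  # df0 = 2a, s0^2 = 1/(a b)
  ext <- limma::fitFDist(s2, df1 = 6)
  # different estimators (full ML here, moment-based moderation there):
  # agreement to a few percent is the expectation
  expect_equal(fit$a, ext$df2 / 2, tolerance = 0.08)
  expect_equal(1 / (fit$a * fit$b), ext$scale, tolerance = 0.08)
})

test_that("moderated t-test matches its closed form and classical limit", {
  set.seed(2)
  mat <- matrix(rnorm(50 * 8), 50, 8)
  classes <- rep(c("A", "B"), each = 4)
  fit <- structure(list(a = 2, b = 1.5), class = "rvm_fit")
  res <- rvm_ttest(mat, classes, c("A", "B"), fit)
  # closed form on one gene
  x <- mat[7, 1:4]; y <- mat[7, 5:8]
  s2 <- (sum((x - mean(x))^2) + sum((y - mean(y))^2)) / 6
  shrunk <- (6 * s2 + 2 / 1.5) / (6 + 2 * 2)
  expect_equal(res$t[7], (mean(x) - mean(y)) / sqrt(shrunk * 0.5),
               tolerance = 1e-12)
  expect_equal(res$df[7], 6 + 4)
  expect_equal(res$fold_change[7], 2^(mean(x) - mean(y)), tolerance = 1e-12)

  # equal class means give t = 0 and fold change 1
  flat <- matrix(rep(c(1, 2, 3, 4), each = 8), nrow = 4, byrow = TRUE)
  r0 <- rvm_ttest(flat, classes, c("A", "B"), fit)
  expect_equal(r0$t, rep(0, 4))
  expect_equal(r0$fold_change, rep(1, 4))

  # prior limit a -> 0, 1/b -> 0 recovers the ordinary pooled t
  tiny <- structure(list(a = 1e-12, b = 1e12), class = "rvm_fit")
  rlim <- rvm_ttest(mat, classes, c("A", "B"), tiny)
  tref <- apply(mat, 1, function(v) {
    unname(t.test(v[1:4], v[5:8], var.equal = TRUE)$statistic)
  })
  expect_equal(rlim$t, tref, tolerance = 1e-6)

  # genes with < 2 complete values per class are skipped
  mat[1, 1:3] <- NA
  rna <- rvm_ttest(mat, classes, c("A", "B"), fit)
  expect_true(is.na(rna$t[1]))
  expect_error(rvm_ttest(mat, classes, c("A", "Z"), fit), "absent")
})

test_that("permutation p-values follow the add-one convention and exhaustive enumeration", {
  set.seed(9)
  classes <- rep(c("A", "B"), each = 3)
  fit <- structure(list(a = 1.5, b = 1), class = "rvm_fit")

  # strong separation in a large assignment space (10v10, ~184k splits):
  # no random permutation reproduces the observed split, so the add-one
  # estimator bottoms out at 1/(B+1)
  cls10 <- rep(c("A", "B"), each = 10)
  strong <- matrix(rep(c(rep(10, 10), rep(0, 10)), 3), 3, 20, byrow = TRUE) +
    matrix(rnorm(60, sd = 0.01), 3, 20)
  p_mc <- permutation_p(strong, cls10, c("A", "B"), fit, B = 99,
                        seed = 4, method = "mc")
  expect_equal(p_mc$perm_p, rep(1 / 100, 3))

  # a constant gene never beats any permutation: p = 1 under MC
  null1 <- matrix(c(5, 5, 5, 5, 5, 5, 1, 9, 2, 8, 3, 7), 2, 6, byrow = TRUE)
  pn <- permutation_p(null1, classes, c("A", "B"), fit, B = 50, seed = 2,
                      method = "mc")
  expect_equal(pn$perm_p[1], 1)

  # 3-vs-3 exhaustive (20 assignments) vs large-B Monte-Carlo within 0.02
  set.seed(31)
  toy <- matrix(rnorm(8 * 6), 8, 6) +
    cbind(matrix(1.5, 8, 3), matrix(0, 8, 3))
  p_ex <- permutation_p(toy, classes, c("A", "B"), fit, method = "exhaustive")
  p_big <- permutation_p(toy, classes, c("A", "B"), fit, B = 4000,
                         seed = 7, method = "mc")
  expect_lt(max(abs(p_ex$perm_p - p_big$perm_p)), 0.02)
  expect_true(attr(p_ex, "exhaustive"))
  expect_false(attr(p_big, "exhaustive"))
  expect_error(permutation_p(toy, classes, c("A", "B"), fit, B = 0), "B must")
})

test_that("ENS-gene calling enforces direction, fold change and the both-contrast rule", {
  # 4 samples/class so the exhaustive permutation p can undercut alpha
  npc <- 4L
  classes <- rep(c("ENS_GDNF", "ENS_noGDNF", "intestine"), each = npc)
  base <- matrix(8, 4, 3L * npc)
  # g1: up in both ENS classes; g2: up in intestine; g3: up only with GDNF;
  # g4: flat
  base[1, classes != "intestine"] <- 10
  base[2, classes == "intestine"] <- 10
  base[3, classes == "ENS_GDNF"] <- 10
  set.seed(12)
  mat <- base + matrix(rnorm(length(base), sd = 0.05), nrow(base))
  rownames(mat) <- paste0("g", 1:4)
  fit <- structure(list(a = 2, b = 2), class = "rvm_fit")
  calls <- call_ens_genes(mat, classes, fit, B = 1000, seed = 3)
  expect_true(calls$is_ens_gene[1])
  expect_false(calls$is_ens_gene[2])  # wrong direction
  expect_false(calls$is_ens_gene[3])  # only one contrast up
  expect_false(calls$is_ens_gene[4])  # no signal
  # the any-rule admits the single-contrast gene
  any_calls <- call_ens_genes(mat, classes, fit, B = 1000, seed = 3,
                              rule = "any")
  expect_true(any_calls$is_ens_gene[3])
  expect_error(call_ens_genes(mat[, 1:9], rep(c("ENS_GDNF", "intestine"),
                                              c(6, 3)), fit),
               "at least 2")
})

test_that("pipeline recovers planted ENS genes on an easy synthetic study", {
  cfg <- sim_config(seed = 33, n_genes = 600L, ens_fold_change = 4,
                    expr_noise_sd = 0.25)
  ann <- simulate_gene_annotation(cfg)
  ex <- simulate_expression(cfg, ann$genes)
  res <- ens_pipeline(ex$mat, ex$classes, B = 1000, seed = 33)
  called <- res$calls$gene_id[res$calls$is_ens_gene]
  truth_ids <- rownames(ex$mat)[ex$truth]
  recall <- mean(truth_ids %in% called)
  fp <- setdiff(called, truth_ids)
  # small study (~90 planted genes, exhaustive 5v5 permutations): a slightly
  # lower bar than the full-scale recovery run
  expect_gt(recall, 0.8)
  expect_lt(length(fp) / max(1, sum(!ex$truth)), 0.05)
})
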