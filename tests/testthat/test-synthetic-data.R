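small_cfg <- function(...) {
  args <- utils::modifyList(
    list(seed = 1, n_controls = 30L, n_cases_per_group = c(8L, 6L, 6L),
         n_genes = 200L),
    list(...))
  do.call(sim_config, args)
}

test_that("configuration invariants are enforced", {
  expect_s3_class(sim_config(), "sim_config")
  expect_error(sim_config(frac_ccr = 1.2), "fraction")
  expect_error(sim_config(snp_freqs = c(0, 0.2, 0.3, 0.4, 0.1, 0.2)),
               "strictly inside")
  expect_error(sim_config(phenotype_probs = rbind(a = c(0.5, 0.2, 0.2, 0.05,
                                                        0.04))),
               "summing to 1")
  expect_error(sim_config(genome = data.frame(chrom = "c", length = -5)),
               "positive")
  expect_error(sim_config(ens_fold_change = 0.5), ">= 1")
})

test_that("generators are deterministic under a fixed seed and independent streams", {
  cfg <- small_cfg(seed = 99)
  a <- simulate_cnv_cohorts(cfg)
  b <- simulate_cnv_cohorts(cfg)
  expect_identical(a, b)
  expect_identical(simulate_gene_annotation(cfg),
                   simulate_gene_annotation(cfg))
  expect_identical(simulate_genotypes(cfg, paste0("s", 1:10)),
                   simulate_genotypes(cfg, paste0("s", 1:10)))
  expect_identical(simulate_phenotype_counts(cfg),
                   simulate_phenotype_counts(cfg))
  # a different seed changes the data
  expect_false(identical(a, simulate_cnv_cohorts(small_cfg(seed = 100))))
})

test_that("emitted CNV intervals lie inside the genome with known states", {
  cfg <- small_cfg(seed = 3)
  res <- simulate_cnv_cohorts(cfg)
  cols <- intersect(names(res$cases), names(res$controls))
  all_calls <- rbind(res$cases[cols], res$controls[cols])
  expect_true(all(all_calls$start >= 0))
  expect_true(all(all_calls$start < all_calls$end))
  lens <- setNames(cfg$genome$length, cfg$genome$chrom)
  expect_true(all(all_calls$end <= lens[all_calls$chrom]))
  expect_true(all(all_calls$state %in% c("loss", "gain", "homozygous_loss",
                                         "hemizygous_loss")))
  expect_true(all(all_calls$end - all_calls$start >= cfg$min_cnv_size))
})

test_that("degenerate cohorts and symmetric size parameters behave as expected", {
  none <- simulate_cnv_cohorts(small_cfg(seed = 2,
                                         n_cases_per_group = c(0L, 0L, 0L)))
  expect_equal(nrow(none$cases), 0L)
  expect_gt(nrow(none$controls), 0L)

  # multiplier 1 with identical per-group parameters: group mean log-sizes
  # agree within sampling error (pooled over seeds)
  sizes1 <- c(); sizes4 <- c()
  for (s in 1:6) {
    r <- simulate_cnv_cohorts(small_cfg(seed = 600 + s,
                                        planted_loss_size_multiplier = 1))
    pick <- function(d, g) log10(d$end - d$start)[d$group == g &
                                                    state_class(d$state) == "loss"]
    sizes1 <- c(sizes1, pick(r$cases, 1L))
    sizes4 <- c(sizes4, pick(r$controls, 4L))
  }
  expect_lt(abs(mean(sizes1) - mean(sizes4)), 0.1)
})

test_that("the planted loss-size multiplier separates group 1 from controls", {
  wins <- 0L
  for (s in 1:20) {
    r <- simulate_cnv_cohorts(small_cfg(seed = 700 + s,
                                        planted_loss_size_multiplier = 10))
    m1 <- mean(log10(r$cases$end - r$cases$start)[
      r$cases$group == 1L & state_class(r$cases$state) == "loss"])
    m4 <- mean(log10(r$controls$end - r$controls$start)[
      state_class(r$controls$state) == "loss" & !r$controls$planted_copy])
    if (isTRUE(m1 > m4)) wins <- wins + 1L
  }
  expect_gte(wins, 19L)
})

test_that("planted common CNVs classify as common and the rest stay rare", {
  cfg <- small_cfg(seed = 8, frac_common = 0.3)
  r <- simulate_cnv_cohorts(cfg)
  cls <- classify_rare(r$cases[names(r$cases) != "planted_common"],
                       r$controls, cfg$n_controls)
  planted <- r$cases$planted_common
  expect_true(all(!cls$is_rare[planted]))
  # non-planted calls are overwhelmingly rare (coincidental 75% coverage by
  # a control sample is possible but unusual)
  expect_gt(mean(cls$is_rare[!planted]), 0.9)
})

test_that("gene annotation plants CCR flags, intervals and orthologue rates", {
  cfg <- small_cfg(seed = 4)
  ann <- simulate_gene_annotation(cfg)
  g <- ann$genes
  expect_equal(nrow(g), cfg$n_genes)
  # non-overlapping sorted intervals per chromosome
  for (ch in unique(g$chrom)) {
    sub <- g[g$chrom == ch, ]
    expect_true(all(sub$start[-1] >= head(sub$end, -1)))
  }
  # planted metrics agree with the CCR rule exactly
  flag <- is_ccr(g$pli, g$mis_z, g$syn_z, g$del_single, g$dup_single,
                 g$cnv_score, g$control_del_events, g$control_dup_events)
  expect_identical(flag, g$ccr_true)
  # boundary fractions
  all_ccr <- simulate_gene_annotation(small_cfg(seed = 4, frac_ccr = 1))
  expect_true(all(all_ccr$genes$ccr_true))
  no_ccr <- simulate_gene_annotation(small_cfg(seed = 4, frac_ccr = 0))
  expect_true(!any(no_ccr$genes$ccr_true))
  # orthologue rate is binomial around its target
  big <- simulate_gene_annotation(sim_config(seed = 5, n_genes = 1000L,
                                             frac_zebrafish_orth = 0.8))
  n_zf <- sum(!is.na(big$genes$zebrafish_orthologues))
  expect_lt(abs(n_zf - 800), 4 * sqrt(1000 * 0.8 * 0.2))
  # orthologue map covers exactly the mapped genes
  expect_setequal(
    unique(ann$orthologue_map$gene_id[ann$orthologue_map$species == "mouse"]),
    g$gene_id[!is.na(g$mouse_orthologue)])
})

test_that("expression generator plants the fold change with missing values", {
  cfg <- small_cfg(seed = 6, frac_missing = 0.1)
  ann <- simulate_gene_annotation(cfg)
  ex <- simulate_expression(cfg, ann$genes)
  expect_equal(ncol(ex$mat), 3L * cfg$n_samples_per_class)
  expect_equal(nrow(ex$mat), sum(!is.na(ann$genes$mouse_orthologue)))
  expect_lt(abs(mean(is.na(ex$mat)) - 0.1), 0.025)
  # planted offset appears in both ENS classes
  ens_cols <- ex$classes != "intestine"
  d <- rowMeans(ex$mat[, ens_cols], na.rm = TRUE) -
    rowMeans(ex$mat[, !ens_cols], na.rm = TRUE)
  expect_equal(mean(d[ex$truth]), log2(cfg$ens_fold_change), tolerance = 0.1)
  expect_equal(mean(d[!ex$truth]), 0, tolerance = 0.1)
  expect_error(simulate_expression(small_cfg(n_samples_per_class = 1L),
                                   ann$genes), "at least 2")
})

test_that("genotype generator respects Hardy-Weinberg expectations", {
  cfg <- sim_config(seed = 7, snp_freqs = rep(0.5, 6))
  g <- simulate_genotypes(cfg, paste0("s", 1:2000))
  counts <- as.matrix(g[-1])
  expect_true(all(counts %in% 0:2))
  expect_equal(unname(colMeans(counts)), rep(1.0, 6), tolerance = 0.08)
  expect_error(simulate_genotypes(cfg, "s1", freqs = rep(0, 6)),
               "strictly inside")
})

test_that("phenotype counts are multinomial per condition", {
  sure <- sim_config(seed = 9, phenotype_probs = rbind(ctrl = c(1, 0, 0, 0, 0)))
  tab <- simulate_phenotype_counts(sure, n_larvae = 40L)
  expect_equal(tab$cat_I, 40L)
  expect_equal(tab$cat_II + tab$cat_III + tab$cat_IV + tab$cat_V, 0L)

  even <- sim_config(seed = 10,
                     phenotype_probs = rbind(ctrl = rep(0.2, 5)))
  big <- simulate_phenotype_counts(even, n_larvae = 5000L)
  cnts <- as.integer(big[1, -1])
  sdm <- sqrt(5000 * 0.2 * 0.8)
  expect_true(all(abs(cnts - 1000) <= 3 * sdm))
  expect_equal(sum(cnts), 5000L)

  zero <- simulate_phenotype_counts(even, n_larvae = 0L)
  expect_true(all(as.integer(zero[1, -1]) == 0L))
})
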