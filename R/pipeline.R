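#' Published per-group rare-CNV event counts
#'
#' Returns the shipped bookkeeping table of rare-CNV event counts per case
#' group and state, as reported by the study the pipeline emulates.
#'
#' @return data.frame with columns `group`, `state`, `count`.
#' @export
rare_cnv_group_counts <- function() {
  path <- system.file("extdata", "rare_cnv_group_counts.tsv",
                      package = "hscrcnv", mustWork = TRUE)
  utils::read.delim(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
}

#' Attach CCR and ENS flags to a gene table
#'
#' Sets `is_ccr` from the gene's constraint metric columns via [is_ccr()],
#' and `is_ens_gene` either from a per-gene ENS call table (NA for genes
#' absent from it, i.e. unevaluable) or from a supplied logical vector.
#'
#' @param genes gene data.frame with constraint metric columns.
#' @param ens_calls data.frame with `gene_id` and `is_ens_gene` (e.g. from
#'   [call_ens_genes()]), or a logical vector over rows of `genes`.
#' @param ... thresholds passed to [is_ccr()].
#' @return `genes` with `is_ccr` and `is_ens_gene` set.
#' @export
annotate_genes <- function(genes, ens_calls, ...) {
  genes$is_ccr <- is_ccr(
    pli = genes$pli, mis_z = genes$mis_z,
    syn_z = if ("syn_z" %in% names(genes)) genes$syn_z else NA_real_,
    del_single = genes$del_single, dup_single = genes$dup_single,
    cnv_score = genes$cnv_score,
    control_del_events = if ("control_del_events" %in% names(genes))
      genes$control_del_events else 0L,
    control_dup_events = if ("control_dup_events" %in% names(genes))
      genes$control_dup_events else 0L, ...)
  if (is.logical(ens_calls)) {
    stopifnot(length(ens_calls) == nrow(genes))
    genes$is_ens_gene <- ens_calls
  } else {
    idx <- match(genes$gene_id, ens_calls$gene_id)
    genes$is_ens_gene <- ens_calls$is_ens_gene[idx]
  }
  genes
}

# Leave-own-sample-out rarity classification of control calls: every sample
# trivially matches its own calls, so self-matches are removed from the
# tally and the denominator shrinks by one individual.
classify_rare_loo <- function(controls, control_n, ...) {
  res <- classify_rare(controls, controls, control_n, ...)
  dots <- list(...)
  cutoff <- if (!is.null(dots$freq_cutoff)) dots$freq_cutoff else 0.00026
  res$matched_controls <- pmax(res$matched_controls - 1L, 0L)
  res$control_n <- control_n - 1L
  res$frequency <- res$matched_controls / res$control_n
  res$is_rare <- res$frequency < cutoff
  res
}

#' Group burden comparisons over a per-sample burden table
#'
#' Applies the ANOVA-gated pairwise t-test protocol to each burden endpoint
#' (CNV count, summed sizes, ENS / CCR / ENS-and-CCR gene counts, all calls
#' and losses only).
#'
#' @param burden per-sample table from [ccr_ens_burden()].
#' @param endpoints endpoint columns to test.
#' @param gate_alpha ANOVA gate (default 0.05).
#' @return data.frame: one row per endpoint and group pair with the ANOVA F
#'   and p and the pairwise t and p (NA when the gate was not passed).
#' @export
burden_group_tests <- function(burden,
                               endpoints = c("n_rare", "sum_size",
                                             "sum_loss_size", "n_ens",
                                             "n_ens_loss", "n_ccr",
                                             "n_ccr_loss", "n_ens_ccr",
                                             "n_ens_ccr_loss"),
                               gate_alpha = 0.05) {
  out <- list()
  for (ep in endpoints) {
    res <- tryCatch(
      anova_then_ttests(burden[[ep]], burden$group, gate_alpha = gate_alpha),
      error = function(e) NULL)
    if (is.null(res)) next
    if (is.null(res$pairwise)) {
      out[[length(out) + 1L]] <- data.frame(
        endpoint = ep, anova_F = res$F, anova_p = res$p,
        group_a = NA_character_, group_b = NA_character_,
        t = NA_real_, p = NA_real_, stringsAsFactors = FALSE)
    } else {
      pw <- res$pairwise
      out[[length(out) + 1L]] <- data.frame(
        endpoint = ep, anova_F = res$F, anova_p = res$p,
        group_a = pw$group_a, group_b = pw$group_b, t = pw$t, p = pw$p,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

#' Synthetic cohort CNV burden pipeline
#'
#' Runs the CNV arm of the analysis on one synthetic cohort: simulates case
#' and control CNVs and gene annotation, classifies rarity (cases against
#' the control cohort; control calls leave-own-sample-out), flags genes as
#' CCR from their planted constraint metrics and as ENS genes from the
#' planted truth (or a supplied ENS call table), computes the per-sample
#' burden profile, and tests every endpoint across groups.
#'
#' @param config a [sim_config()].
#' @param ens_calls optional ENS call table passed to [annotate_genes()];
#'   default uses the planted truth.
#' @param min_overlap,freq_cutoff rarity settings, see [classify_rare()].
#' @return list with `calls` (cases and controls with rarity columns),
#'   `genes`, `burden` and `tests`.
#' @export
run_burden_pipeline <- function(config, ens_calls = NULL,
                                min_overlap = 0.75, freq_cutoff = 0.00026) {
  cohort <- simulate_cnv_cohorts(config)
  ann <- simulate_gene_annotation(config)
  genes <- annotate_genes(
    ann$genes,
    if (is.null(ens_calls)) ann$genes$ens_true else ens_calls)

  cases <- classify_rare(cohort$cases[names(cohort$cases) != "planted_common"],
                         cohort$controls, config$n_controls,
                         min_overlap = min_overlap, freq_cutoff = freq_cutoff)
  controls <- classify_rare_loo(cohort$controls, config$n_controls,
                                min_overlap = min_overlap,
                                freq_cutoff = freq_cutoff)
  calls <- rbind(cases, controls)
  roster <- list()
  for (g in 1:3) {
    ng <- config$n_cases_per_group[g]
    if (ng > 0L) {
      roster[[g]] <- data.frame(
        sample_id = sprintf("case_g%d_%03d", g, seq_len(ng)),
        group = g, stringsAsFactors = FALSE)
    }
  }
  roster[[4L]] <- data.frame(
    sample_id = sprintf("ctrl_%04d", seq_len(config$n_controls)),
    group = 4L, stringsAsFactors = FALSE)
  samples <- do.call(rbind, roster)
  burden <- ccr_ens_burden(calls, genes, samples)
  tests <- burden_group_tests(burden)
  list(calls = calls, genes = genes, burden = burden, tests = tests)
}
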