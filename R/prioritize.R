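#' Select candidate genes
#'
#' Emits one row per (patient, gene) pair where the CNV is rare and
#' loss-like, the gene overlaps it, the gene is an ENS gene and a CCR, and
#' at least one zebrafish orthologue exists. Genes whose ENS status could
#' not be evaluated (`is_ens_gene` NA, e.g. no mouse orthologue or no
#' probes) are excluded from candidacy but returned in the `unevaluable`
#' attribute. Duplicate pairs from overlapping CNVs of one patient are
#' deduplicated; rows are sorted by patient then genomic position.
#'
#' @param rarity_calls output of [classify_rare()].
#' @param genes gene data.frame with `is_ens_gene`, `is_ccr` (logical,
#'   NA = unevaluable ENS status) and `zebrafish_orthologues` (NA or
#'   `;`-separated ids).
#' @param rsnc_by_sample optional data.frame `sample_id`, `rsnc` attached to
#'   each candidate row.
#' @return data.frame of candidates: patient, gene, gene interval, CNV
#'   interval/state, and `patient_rsnc` when supplied; attribute
#'   `unevaluable` lists (patient, gene) pairs with undetermined ENS status
#'   in rare losses.
#' @export
select_candidates <- function(rarity_calls, genes, rsnc_by_sample = NULL) {
  needed <- c("is_ens_gene", "is_ccr", "zebrafish_orthologues")
  missing_cols <- setdiff(needed, names(genes))
  if (length(missing_cols) > 0L) {
    stop("gene annotation incomplete; missing column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  if (anyNA(genes$is_ccr)) {
    stop("is_ccr must be determined (TRUE/FALSE) for every gene")
  }
  if (!"is_rare" %in% names(rarity_calls)) {
    stop("rarity_calls must come from classify_rare()")
  }
  losses <- rarity_calls[rarity_calls$is_rare &
                           state_class(rarity_calls$state) == "loss", ,
                         drop = FALSE]
  out <- list(); unev <- list()
  for (i in seq_len(nrow(losses))) {
    g <- genes_in_cnv(losses$chrom[i], losses$start[i], losses$end[i], genes)
    if (nrow(g) == 0L) next
    na_ens <- is.na(g$is_ens_gene)
    if (any(na_ens)) {
      unev[[length(unev) + 1L]] <- data.frame(
        patient = losses$sample_id[i], gene_id = g$gene_id[na_ens],
        stringsAsFactors = FALSE)
    }
    hit <- !na_ens & g$is_ens_gene & g$is_ccr &
      !is.na(g$zebrafish_orthologues) & nzchar(g$zebrafish_orthologues)
    if (!any(hit)) next
    g <- g[hit, , drop = FALSE]
    out[[length(out) + 1L]] <- data.frame(
      patient = losses$sample_id[i], gene_id = g$gene_id, symbol = g$symbol,
      chrom = g$chrom, gene_start = g$start, gene_end = g$end,
      cnv_start = losses$start[i], cnv_end = losses$end[i],
      cnv_state = losses$state[i],
      zebrafish_orthologues = g$zebrafish_orthologues,
      stringsAsFactors = FALSE)
  }
  cand <- if (length(out) > 0L) do.call(rbind, out) else
    data.frame(patient = character(), gene_id = character(),
               symbol = character(), chrom = character(),
               gene_start = numeric(), gene_end = numeric(),
               cnv_start = numeric(), cnv_end = numeric(),
               cnv_state = character(), zebrafish_orthologues = character(),
               stringsAsFactors = FALSE)
  cand <- cand[!duplicated(cand[c("patient", "gene_id")]), , drop = FALSE]
  cand <- cand[order(cand$patient, cand$chrom, cand$gene_start), , drop = FALSE]
  rownames(cand) <- NULL
  if (!is.null(rsnc_by_sample)) {
    cand$patient_rsnc <-
      rsnc_by_sample$rsnc[match(cand$patient, rsnc_by_sample$sample_id)]
  }
  attr(cand, "unevaluable") <-
    if (length(unev) > 0L) unique(do.call(rbind, unev)) else
      data.frame(patient = character(), gene_id = character(),
                 stringsAsFactors = FALSE)
  cand
}

#' Assemble the cohort report
#'
#' Writes the per-sample burden table, the group-statistics table, the
#' candidate-gene table and a run-metadata JSON (thresholds, seed,
#' package version) into a directory. Deterministic: identical inputs give
#' byte-identical files.
#'
#' @param dir output directory (created if absent).
#' @param burden per-sample burden table from [ccr_ens_burden()].
#' @param group_stats data.frame of group comparison statistics (one row per
#'   tested endpoint).
#' @param candidates candidate table from [select_candidates()].
#' @param thresholds named list of thresholds/settings echoed into the JSON.
#' @param seed the master seed used for the run.
#' @return invisibly, the paths written.
#' @export
cohort_report <- function(dir, burden, group_stats, candidates,
                          thresholds = list(), seed = NA_integer_) {
  stages <- list(burden = burden, group_stats = group_stats,
                 candidates = candidates)
  absent <- names(stages)[vapply(stages, is.null, logical(1L))]
  if (length(absent) > 0L) {
    stop("missing pipeline stage output(s): ", paste(absent, collapse = ", "))
  }
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(
    burden = file.path(dir, "burden_per_sample.tsv"),
    group_stats = file.path(dir, "group_statistics.tsv"),
    candidates = file.path(dir, "candidate_genes.tsv"),
    metadata = file.path(dir, "run_metadata.json")
  )
  utils::write.table(burden, paths[["burden"]], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(group_stats, paths[["group_stats"]], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(candidates, paths[["candidates"]], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  meta <- list(
    package = "hscrcnv",
    version = as.character(utils::packageVersion("hscrcnv")),
    seed = seed, thresholds = thresholds,
    n_samples = nrow(burden), n_candidates = nrow(candidates)
  )
  jsonlite::write_json(meta, paths[["metadata"]], auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  invisible(paths)
}

#' Worked candidate-selection example from the published metrics table
#'
#' Loads the shipped table of printed per-patient candidate metrics (patient,
#' non-coding risk score, gene symbol, constraint scores and CNV region) and
#' rebuilds a selection fixture from it: each patient's printed region
#' becomes a rare CN loss, and each listed gene becomes a gene record with
#' its printed constraint metrics, ENS status and a zebrafish orthologue set
#' per the table's definition. Gene intervals inside the printed regions are
#' not published, so synthetic intervals are placed evenly inside each
#' region (interval positions do not affect selection).
#'
#' @return list with `calls` (rare losses with rarity columns), `genes`
#'   (annotated gene records), `rsnc` (per-patient scores) and `metrics`
#'   (the raw table).
#' @export
load_candidate_example <- function() {
  path <- system.file("extdata", "candidate_gene_metrics.tsv",
                      package = "hscrcnv", mustWork = TRUE)
  metrics <- utils::read.delim(path, sep = "\t", header = TRUE,
                               stringsAsFactors = FALSE)
  regions <- unique(metrics[c("patient", "chrom", "start_1based", "end_1based")])
  calls <- data.frame(
    sample_id = regions$patient, chrom = regions$chrom,
    start = regions$start_1based - 1, end = as.numeric(regions$end_1based),
    state = "loss", inheritance = "unknown", group = 1L,
    matched_controls = 0L, control_n = 19584L, frequency = 0,
    is_rare = TRUE, stringsAsFactors = FALSE)

  genes <- list()
  for (r in seq_len(nrow(regions))) {
    sel <- metrics$patient == regions$patient[r] &
      metrics$chrom == regions$chrom[r]
    sub <- metrics[sel, , drop = FALSE]
    lo <- regions$start_1based[r] - 1
    hi <- regions$end_1based[r]
    k <- nrow(sub)
    w <- (hi - lo) / (k + 1)
    genes[[r]] <- data.frame(
      gene_id = sub$gene, symbol = sub$gene, chrom = sub$chrom,
      start = floor(lo + w * seq_len(k) - w / 4),
      end = floor(lo + w * seq_len(k) + w / 4),
      pli = sub$pli, mis_z = sub$mis_z, syn_z = NA_real_,
      del_single = sub$del_single, dup_single = NA_real_,
      cnv_score = sub$cnv_score,
      is_ens_gene = TRUE,
      zebrafish_orthologues = paste0(tolower(sub$gene), "_zf"),
      stringsAsFactors = FALSE)
  }
  genes <- do.call(rbind, genes)
  genes$is_ccr <- is_ccr(genes$pli, genes$mis_z, genes$syn_z,
                         genes$del_single, genes$dup_single, genes$cnv_score)
  rsnc_tab <- unique(data.frame(sample_id = metrics$patient,
                                rsnc = metrics$rsnc,
                                stringsAsFactors = FALSE))
  list(calls = calls, genes = genes, rsnc = rsnc_tab, metrics = metrics)
}
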