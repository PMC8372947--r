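validate_genes <- function(genes) {
  stopifnot(is.data.frame(genes))
  required <- c("gene_id", "symbol", "chrom", "start", "end")
  missing_cols <- setdiff(required, names(genes))
  if (length(missing_cols) > 0L) {
    stop("gene table is missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  if (any(genes$start >= genes$end)) stop("gene interval with start >= end")
  genes
}

#' Read gene models from a BED file
#'
#' Accepts BED4/BED6 (0-based half-open); the name field is used as both
#' gene id and symbol.
#'
#' @param path path to a BED file (no header).
#' @return data.frame with columns `gene_id`, `symbol`, `chrom`, `start`, `end`.
#' @export
read_gene_bed <- function(path) {
  raw <- utils::read.delim(path, sep = "\t", header = FALSE,
                           stringsAsFactors = FALSE)
  if (ncol(raw) < 4L) stop("BED file needs at least 4 columns (chrom, start, end, name)")
  validate_genes(data.frame(
    gene_id = as.character(raw[[4L]]), symbol = as.character(raw[[4L]]),
    chrom = as.character(raw[[1L]]), start = as.numeric(raw[[2L]]),
    end = as.numeric(raw[[3L]]), stringsAsFactors = FALSE
  ))
}

#' Genes overlapping a CNV
#'
#' Returns the genes whose interval overlaps the CNV by at least 1 bp
#' (half-open coordinates, so an abutting gene sharing only the CNV end
#' coordinate is excluded), in genomic order.
#'
#' @param chrom,start,end the CNV interval (0-based half-open).
#' @param genes gene data.frame (see [read_gene_bed()]).
#' @return the overlapping rows of `genes`, sorted by start.
#' @export
genes_in_cnv <- function(chrom, start, end, genes) {
  genes <- validate_genes(genes)
  hit <- genes$chrom == chrom & genes$start < end & genes$end > start
  out <- genes[hit, , drop = FALSE]
  out[order(out$start, out$end, out$gene_id), , drop = FALSE]
}

#' Constrained coding region (CCR) rule
#'
#' A gene is a CCR when it is intolerant to sequence variation
#' (`pli >= pli_min`, or a missense or synonymous z-score `>= z_min`) or
#' dosage sensitive (deletion, duplication and CNV intolerance scores all
#' `>= dosage_min`), and is not recurrently impacted by deletions or
#' duplications in unaffected controls (each event count
#' `<= max_control_events`). Missing metrics make the corresponding clause
#' false (never NA), so a gene with no metrics at all is undetermined and
#' returns `FALSE`.
#'
#' @param pli probability of loss-of-function intolerance, in \[0, 1\].
#' @param mis_z,syn_z missense / synonymous constraint z-scores.
#' @param del_single,dup_single,cnv_score dosage intolerance scores.
#' @param control_del_events,control_dup_events counts of deletion /
#'   duplication events observed in unaffected controls (default 0).
#' @param pli_min,z_min,dosage_min,max_control_events rule thresholds.
#' @return logical vector.
#' @export
is_ccr <- function(pli, mis_z = NA_real_, syn_z = NA_real_,
                   del_single = NA_real_, dup_single = NA_real_,
                   cnv_score = NA_real_,
                   control_del_events = 0L, control_dup_events = 0L,
                   pli_min = 0.85, z_min = 3.0, dosage_min = 1.0,
                   max_control_events = 1L) {
  n <- max(length(pli), length(mis_z), length(syn_z), length(del_single))
  rec <- function(x, default = NA_real_) {
    if (length(x) == 0L) x <- default
    rep_len(x, n)
  }
  pli <- rec(pli); mis_z <- rec(mis_z); syn_z <- rec(syn_z)
  del_single <- rec(del_single); dup_single <- rec(dup_single)
  cnv_score <- rec(cnv_score)
  control_del_events <- rec(control_del_events, 0L)
  control_dup_events <- rec(control_dup_events, 0L)
  ge <- function(x, thr) !is.na(x) & x >= thr
  constrained <- ge(pli, pli_min) | ge(mis_z, z_min) | ge(syn_z, z_min) |
    (ge(del_single, dosage_min) & ge(dup_single, dosage_min) &
       ge(cnv_score, dosage_min))
  not_recurrent <- ge(-control_del_events, -max_control_events) &
    ge(-control_dup_events, -max_control_events)
  constrained & not_recurrent
}

#' Per-sample CNV burden profiles
#'
#' For each cohort sample, counts rare CNVs and their summed size (all calls
#' and losses only), and the number of ENS genes, CCR genes and ENS-and-CCR
#' genes impacted by rare CNVs (again all calls and losses only). A gene hit
#' by two CNVs of one sample is counted once per event.
#'
#' @param rarity_calls output of [classify_rare()] (needs `is_rare`).
#' @param genes gene data.frame carrying logical `is_ens_gene` and `is_ccr`
#'   columns (set by the annotation passes).
#' @param samples data.frame with columns `sample_id` and `group` listing the
#'   full cohort (samples without calls get all-zero rows).
#' @return per-sample data.frame of burden statistics.
#' @export
ccr_ens_burden <- function(rarity_calls, genes, samples) {
  genes <- validate_genes(genes)
  if (!all(c("is_ens_gene", "is_ccr") %in% names(genes)) ||
      anyNA(genes$is_ccr) || anyNA(genes$is_ens_gene)) {
    stop("genes must carry complete is_ens_gene and is_ccr flags; ",
         "run the expression and constraint annotation passes first")
  }
  if (!"is_rare" %in% names(rarity_calls)) {
    stop("rarity_calls must come from classify_rare()")
  }
  stopifnot(all(c("sample_id", "group") %in% names(samples)))
  rare <- rarity_calls[rarity_calls$is_rare, , drop = FALSE]

  out <- data.frame(
    sample_id = samples$sample_id, group = samples$group,
    n_rare = 0L, sum_size = 0, sum_loss_size = 0,
    n_ens = 0L, n_ccr = 0L, n_ens_ccr = 0L,
    n_ens_loss = 0L, n_ccr_loss = 0L, n_ens_ccr_loss = 0L,
    stringsAsFactors = FALSE
  )
  if (nrow(rare) == 0L) return(out)
  idx <- match(rare$sample_id, out$sample_id)
  if (anyNA(idx)) {
    stop("call sample(s) absent from the cohort roster: ",
         paste(unique(rare$sample_id[is.na(idx)]), collapse = ", "))
  }
  for (i in seq_len(nrow(rare))) {
    j <- idx[i]
    g <- genes_in_cnv(rare$chrom[i], rare$start[i], rare$end[i], genes)
    size <- rare$end[i] - rare$start[i]
    n_ens <- sum(g$is_ens_gene)
    n_ccr <- sum(g$is_ccr)
    n_both <- sum(g$is_ens_gene & g$is_ccr)
    out$n_rare[j] <- out$n_rare[j] + 1L
    out$sum_size[j] <- out$sum_size[j] + size
    out$n_ens[j] <- out$n_ens[j] + n_ens
    out$n_ccr[j] <- out$n_ccr[j] + n_ccr
    out$n_ens_ccr[j] <- out$n_ens_ccr[j] + n_both
    if (state_class(rare$state[i]) == "loss") {
      out$sum_loss_size[j] <- out$sum_loss_size[j] + size
      out$n_ens_loss[j] <- out$n_ens_loss[j] + n_ens
      out$n_ccr_loss[j] <- out$n_ccr_loss[j] + n_ccr
      out$n_ens_ccr_loss[j] <- out$n_ens_ccr_loss[j] + n_both
    }
  }
  out
}
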