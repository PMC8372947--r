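validate_risk_model <- function(model) {
  stopifnot(is.data.frame(model))
  required <- c("snp_id", "risk_allele", "odds_ratio")
  missing_cols <- setdiff(required, names(model))
  if (length(missing_cols) > 0L) {
    stop("risk model is missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  if (anyDuplicated(model$snp_id)) stop("duplicate snp_id in risk model")
  if (any(!is.finite(model$odds_ratio)) || any(model$odds_ratio <= 0)) {
    stop("odds ratios must be positive")
  }
  model
}

#' Read a risk-SNP model table
#'
#' TSV with columns `snp_id`, `risk_allele`, `odds_ratio` and optionally
#' `risk_allele_freq` (needed for the `impute_2pq_mean` missing policy).
#'
#' @param path path to the TSV.
#' @return validated risk model data.frame.
#' @export
read_risk_model <- function(path) {
  validate_risk_model(utils::read.delim(path, sep = "\t", header = TRUE,
                                        stringsAsFactors = FALSE))
}

#' Non-coding risk score (RSnc)
#'
#' Weighted polygenic score over predisposing risk haplotypes:
#' `RSnc = sum_i ln(OR_i) * count_i`, summing the per-SNP log odds ratio
#' times the sample's risk-allele count (0, 1 or 2). Haplotype-combination
#' interaction bonuses are not modeled.
#'
#' @param genotypes data.frame with a `sample_id` column and one column of
#'   risk-allele counts per SNP (column names = `snp_id`), NA allowed.
#' @param model risk model (see [read_risk_model()]); every genotyped SNP
#'   column must appear in it.
#' @param missing how to handle a missing genotype: `"zero"` (contributes
#'   0), `"impute_2pq_mean"` (contributes `ln(OR) * 2 * freq`, the expected
#'   count under Hardy-Weinberg; requires `risk_allele_freq` in the model),
#'   or `"fail"` (error).
#' @return data.frame with columns `sample_id`, `rsnc`.
#' @export
rsnc <- function(genotypes, model,
                 missing = c("zero", "impute_2pq_mean", "fail")) {
  missing <- match.arg(missing)
  model <- validate_risk_model(model)
  stopifnot("sample_id" %in% names(genotypes))
  snp_cols <- setdiff(names(genotypes), "sample_id")
  unknown <- setdiff(snp_cols, model$snp_id)
  if (length(unknown) > 0L) {
    stop("genotyped SNP(s) absent from the risk model: ",
         paste(unknown, collapse = ", "))
  }
  counts <- as.matrix(genotypes[snp_cols])
  if (any(!counts %in% c(0, 1, 2, NA))) {
    stop("risk-allele counts must be 0, 1, 2 or missing")
  }
  lnor <- log(model$odds_ratio)[match(snp_cols, model$snp_id)]
  if (anyNA(counts)) {
    if (missing == "fail") {
      stop("missing genotype(s) with missing policy 'fail'")
    }
    if (missing == "impute_2pq_mean") {
      if (!"risk_allele_freq" %in% names(model)) {
        stop("impute_2pq_mean requires a risk_allele_freq column in the model")
      }
      freq <- model$risk_allele_freq[match(snp_cols, model$snp_id)]
      fill <- matrix(2 * freq, nrow(counts), ncol(counts), byrow = TRUE)
      counts[is.na(counts)] <- fill[is.na(counts)]
    } else {
      counts[is.na(counts)] <- 0
    }
  }
  data.frame(sample_id = genotypes$sample_id,
             rsnc = as.numeric(counts %*% lnor),
             stringsAsFactors = FALSE)
}

#' Group summaries and pairwise t-tests of RSnc
#'
#' Per-group mean and standard deviation plus pairwise pooled-variance
#' two-tailed t-tests. Groups with fewer than 2 samples are excluded from
#' testing (reported with NA sd handling as usual).
#'
#' @param scores numeric vector of per-sample scores.
#' @param groups group label per sample.
#' @param var_equal pooled variance (default `TRUE`); `FALSE` gives Welch.
#' @return list with `summary` (group, n, mean, sd) and `pairwise`
#'   (group_a, group_b, t, df, p) data.frames.
#' @export
group_rsnc_summary <- function(scores, groups, var_equal = TRUE) {
  stopifnot(length(scores) == length(groups))
  keep <- !is.na(scores) & !is.na(groups)
  scores <- scores[keep]; groups <- as.character(groups[keep])
  lev <- unique(groups)
  summ <- data.frame(
    group = lev,
    n = vapply(lev, function(g) sum(groups == g), integer(1L)),
    mean = vapply(lev, function(g) mean(scores[groups == g]), numeric(1L)),
    sd = vapply(lev, function(g) stats::sd(scores[groups == g]), numeric(1L)),
    stringsAsFactors = FALSE
  )
  testable <- summ$group[summ$n >= 2L]
  if (length(testable) < length(lev)) {
    message("group(s) with < 2 samples excluded from pairwise testing: ",
            paste(setdiff(lev, testable), collapse = ", "))
  }
  pairs <- if (length(testable) >= 2L) utils::combn(testable, 2L) else
    matrix(character(), 2L, 0L)
  pw <- data.frame(group_a = character(), group_b = character(),
                   t = numeric(), df = numeric(), p = numeric(),
                   stringsAsFactors = FALSE)
  for (j in seq_len(ncol(pairs))) {
    a <- scores[groups == pairs[1L, j]]
    b <- scores[groups == pairs[2L, j]]
    if (stats::sd(c(a, b)) == 0) {
      pw[j, ] <- list(pairs[1L, j], pairs[2L, j], 0, length(a) + length(b) - 2, 1)
      next
    }
    tt <- stats::t.test(a, b, var.equal = var_equal)
    pw[j, ] <- list(pairs[1L, j], pairs[2L, j],
                    unname(tt$statistic), unname(tt$parameter), tt$p.value)
  }
  list(summary = summ, pairwise = pw)
}
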