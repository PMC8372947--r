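#' Simulation configuration
#'
#' Builds and validates the configuration for the synthetic-data generator.
#' Defaults emulate the structure of the study cohort the pipeline was
#' designed for: three case groups (23 / 15 / 20 samples) and 326 controls,
#' CNV sizes log10-normal with median 100 kb and a 20 kb detection floor,
#' large planted losses in case group 1, transcript-level gene density
#' (~1 gene per 50 kb), ENS-enriched expression in two ENS classes versus an
#' intestine class, Hardy-Weinberg genotypes at six risk SNPs, and
#' multinomial phenotype categories I-V.
#'
#' @param seed integer master seed; each generator derives its own stream
#'   from it (fixed offsets), so regenerating one input does not perturb the
#'   others.
#' @param n_controls control cohort size.
#' @param n_cases_per_group integer vector of the three case group sizes.
#' @param control_cnv_rate mean CNVs per sample (Poisson), all groups.
#' @param size_params data.frame with columns `group` (1-4), `state_class`
#'   (`"loss"`/`"gain"`), `mu`, `sigma`: per-group log10-size parameters.
#'   Default: mu 5, sigma 0.4 everywhere.
#' @param planted_loss_size_multiplier multiplier applied to group-1 loss
#'   sizes (default 10; set to 1 for a null cohort).
#' @param min_cnv_size detection floor in bp (default 2e4).
#' @param frac_common fraction of case CNVs copied (with jittered endpoints
#'   preserving >= 75\% mutual overlap) into control samples so they classify
#'   as common.
#' @param n_common_copies number of distinct control samples receiving a
#'   copy of each planted common CNV (default 4, ~1\% carrier frequency in
#'   the default cohort, so the copies are also common among the controls
#'   themselves).
#' @param genome data.frame with columns `chrom`, `length`.
#' @param n_genes number of gene/transcript models tiled over the genome.
#' @param frac_ccr fraction of genes planted as constrained coding regions.
#' @param frac_ens fraction of genes planted as ENS-enriched.
#' @param frac_mouse_orth,frac_zebrafish_orth fractions of genes with a
#'   mouse / zebrafish orthologue.
#' @param n_samples_per_class expression samples per class.
#' @param ens_fold_change planted linear fold change of ENS genes in both
#'   ENS classes versus intestine (>= 1).
#' @param expr_noise_sd Gaussian noise sd on the log2 scale.
#' @param frac_missing missing-at-random rate in the expression matrix.
#' @param snp_ids,snp_freqs,snp_ors the six risk SNPs: identifiers,
#'   risk-allele frequencies in (0,1), odds ratios > 0.
#' @param phenotype_probs matrix (conditions x 5 categories) of category
#'   probabilities, rows summing to 1; rownames are condition labels.
#' @param n_larvae_per_condition larvae per condition.
#' @return validated list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_controls = 326L,
                       n_cases_per_group = c(23L, 15L, 20L),
                       control_cnv_rate = 2,
                       size_params = NULL,
                       planted_loss_size_multiplier = 10,
                       min_cnv_size = 2e4,
                       frac_common = 0.2,
                       n_common_copies = 4L,
                       genome = data.frame(
                         chrom = c("chr1", "chr2"),
                         length = c(6e7, 4e7),
                         stringsAsFactors = FALSE),
                       n_genes = 2000L,
                       frac_ccr = 0.15,
                       frac_ens = 0.25,
                       frac_mouse_orth = 0.6,
                       frac_zebrafish_orth = 0.8,
                       n_samples_per_class = 5L,
                       ens_fold_change = 4,
                       expr_noise_sd = 0.25,
                       frac_missing = 0.05,
                       snp_ids = c("rs2506030", "rs7069590", "rs2435357",
                                   "rs7005606", "rs11766001", "rs80227144"),
                       snp_freqs = c(0.25, 0.45, 0.25, 0.40, 0.10, 0.05),
                       snp_ors = c(1.7, 1.6, 3.9, 1.7, 1.4, 2.0),
                       phenotype_probs = rbind(
                         control = c(0.90, 0.05, 0.03, 0.01, 0.01),
                         targeted = c(0.50, 0.20, 0.15, 0.10, 0.05)),
                       n_larvae_per_condition = 60L) {
  if (is.null(size_params)) {
    size_params <- expand.grid(group = 1:4,
                               state_class = c("loss", "gain"),
                               stringsAsFactors = FALSE)
    size_params$mu <- 5
    size_params$sigma <- 0.4
  }
  cfg <- list(seed = as.integer(seed), n_controls = as.integer(n_controls),
              n_cases_per_group = as.integer(n_cases_per_group),
              control_cnv_rate = control_cnv_rate, size_params = size_params,
              planted_loss_size_multiplier = planted_loss_size_multiplier,
              min_cnv_size = min_cnv_size, frac_common = frac_common,
              n_common_copies = as.integer(n_common_copies),
              genome = genome, n_genes = as.integer(n_genes),
              frac_ccr = frac_ccr, frac_ens = frac_ens,
              frac_mouse_orth = frac_mouse_orth,
              frac_zebrafish_orth = frac_zebrafish_orth,
              n_samples_per_class = as.integer(n_samples_per_class),
              ens_fold_change = ens_fold_change,
              expr_noise_sd = expr_noise_sd, frac_missing = frac_missing,
              snp_ids = snp_ids, snp_freqs = snp_freqs, snp_ors = snp_ors,
              phenotype_probs = phenotype_probs,
              n_larvae_per_condition = as.integer(n_larvae_per_condition))
  fracs <- c(frac_common = cfg$frac_common, frac_ccr = cfg$frac_ccr,
             frac_ens = cfg$frac_ens, frac_mouse_orth = cfg$frac_mouse_orth,
             frac_zebrafish_orth = cfg$frac_zebrafish_orth,
             frac_missing = cfg$frac_missing)
  bad <- fracs < 0 | fracs > 1
  if (any(bad)) stop("fraction(s) outside [0,1]: ",
                     paste(names(fracs)[bad], collapse = ", "))
  if (any(cfg$genome$length <= 0)) stop("chromosome lengths must be positive")
  if (length(cfg$n_cases_per_group) != 3L || any(cfg$n_cases_per_group < 0)) {
    stop("n_cases_per_group must be 3 non-negative counts")
  }
  if (cfg$planted_loss_size_multiplier <= 0) stop("size multiplier must be positive")
  if (cfg$ens_fold_change < 1) stop("ens_fold_change must be >= 1")
  if (cfg$expr_noise_sd <= 0) stop("expr_noise_sd must be positive")
  if (any(cfg$snp_freqs <= 0 | cfg$snp_freqs >= 1)) {
    stop("allele frequencies must lie strictly inside (0,1)")
  }
  if (any(cfg$snp_ors <= 0)) stop("odds ratios must be positive")
  pp <- as.matrix(cfg$phenotype_probs)
  if (ncol(pp) != 5L || any(pp < 0) ||
      any(abs(rowSums(pp) - 1) > 1e-9)) {
    stop("each condition's phenotype probabilities must be 5 values in ",
         "[0,1] summing to 1")
  }
  structure(cfg, class = "sim_config")
}

# fixed per-generator seed offsets (counter-based streams off one master seed)
SIM_STREAMS <- c(cnv = 101L, genes = 202L, expr = 303L,
                 geno = 404L, pheno = 505L)

sim_seed <- function(config, stream) {
  (config$seed + SIM_STREAMS[[stream]]) %% .Machine$integer.max
}

#' Simulate case and control CNV cohorts
#'
#' Each sample draws a Poisson number of CNVs; states are losses and gains
#' (a small homozygous-loss fraction), sizes log10-normal per group and
#' state class with a detection floor, and group-1 losses scaled by the
#' planted multiplier. A fraction of case CNVs is copied into random control
#' samples with jittered endpoints preserving >= 75\% mutual overlap, so
#' those calls classify as common; the case copies are flagged in the
#' `planted_common` truth column.
#'
#' @param config a [sim_config()].
#' @return list with `cases` and `controls` CNV call data.frames; cases
#'   carry the `planted_common` truth column and controls the matching
#'   `planted_copy` flag on the copies.
#' @export
simulate_cnv_cohorts <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(sim_seed(config, "cnv"))
  genome <- config$genome
  sp <- config$size_params

  draw_calls <- function(sample_id, group) {
    k <- stats::rpois(1L, config$control_cnv_rate)
    if (k == 0L) return(NULL)
    state <- sample(c("loss", "gain", "homozygous_loss"), k,
                    replace = TRUE, prob = c(0.48, 0.48, 0.04))
    cls <- state_class(state)
    rows <- match(paste(pmin(group, 4L), cls),
                  paste(sp$group, sp$state_class))
    size <- 10^stats::rnorm(k, mean = sp$mu[rows], sd = sp$sigma[rows])
    mult <- ifelse(group == 1L & cls == "loss",
                   config$planted_loss_size_multiplier, 1)
    size <- pmax(round(size * mult), config$min_cnv_size)
    # a CNV cannot exceed its chromosome: truncate the size distribution at
    # the largest chromosome (whole-chromosome aneuploidy is out of scope)
    size <- pmin(size, max(genome$length) - 1)
    if (any(size < config$min_cnv_size) || max(genome$length) <= config$min_cnv_size) {
      stop("CNV size floor ", config$min_cnv_size,
           " does not fit the genome")
    }
    chrom <- character(k); start <- numeric(k)
    for (i in seq_len(k)) {
      fits <- genome$length > size[i]
      chrom[i] <- sample(genome$chrom[fits], 1L,
                         prob = genome$length[fits])
      len <- genome$length[genome$chrom == chrom[i]]
      start[i] <- floor(stats::runif(1L, 0, len - size[i]))
    }
    data.frame(sample_id = sample_id, chrom = chrom, start = start,
               end = start + size, state = state, inheritance = "unknown",
               group = group, stringsAsFactors = FALSE)
  }

  cases <- list(); controls <- list()
  for (g in 1:3) {
    ng <- config$n_cases_per_group[g]
    if (ng > 0L) {
      for (i in seq_len(ng)) {
        cases[[length(cases) + 1L]] <-
          draw_calls(sprintf("case_g%d_%03d", g, i), g)
      }
    }
  }
  for (i in seq_len(config$n_controls)) {
    controls[[length(controls) + 1L]] <-
      draw_calls(sprintf("ctrl_%04d", i), 4L)
  }
  cases <- do.call(rbind, cases)
  controls <- do.call(rbind, controls)
  empty <- function() {
    data.frame(sample_id = character(), chrom = character(),
               start = numeric(), end = numeric(), state = character(),
               inheritance = character(), group = integer(),
               planted_common = logical(), stringsAsFactors = FALSE)
  }
  if (is.null(controls)) {
    controls <- empty()[, 1:7]
  }
  controls$planted_copy <- rep(FALSE, nrow(controls))
  if (is.null(cases)) {
    cases <- empty()
  } else {
    cases$planted_common <- stats::runif(nrow(cases)) < config$frac_common
    planted <- which(cases$planted_common)
    if (length(planted) > 0L && config$n_controls > 0L) {
      n_cp <- min(config$n_common_copies, config$n_controls)
      copies <- list()
      for (p in planted) {
        size <- cases$end[p] - cases$start[p]
        len <- genome$length[genome$chrom == cases$chrom[p]]
        carriers <- sample.int(config$n_controls, n_cp)
        for (s in carriers) {
          copies[[length(copies) + 1L]] <- data.frame(
            sample_id = sprintf("ctrl_%04d", s),
            chrom = cases$chrom[p],
            start = max(0, cases$start[p] +
                          round(stats::runif(1L, -0.1, 0.1) * size)),
            end = min(len, cases$end[p] +
                        round(stats::runif(1L, -0.1, 0.1) * size)),
            state = cases$state[p], inheritance = "unknown", group = 4L,
            planted_copy = TRUE, stringsAsFactors = FALSE)
        }
      }
      controls <- rbind(controls, do.call(rbind, copies))
    }
  }
  list(cases = cases, controls = controls)
}

#' Simulate gene models, constraint metrics and orthologue map
#'
#' Tiles `n_genes` non-overlapping gene intervals over the genome
#' (proportionally per chromosome), plants a `frac_ccr` fraction with
#' constraint metrics passing the CCR rule (the rest failing it), a
#' `frac_ens` fraction as ENS-enriched truth, and assigns mouse and
#' zebrafish orthologues at the configured rates (zebrafish sometimes as
#' a/b duplicate pairs).
#'
#' @param config a [sim_config()].
#' @return list with `genes` (intervals, metrics, truth columns `ccr_true`,
#'   `ens_true`, `mouse_orthologue`, `zebrafish_orthologues`) and
#'   `orthologue_map` (long data.frame gene_id / species / orthologue).
#' @export
simulate_gene_annotation <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  if (config$n_genes < 1L) stop("n_genes must be >= 1")
  set.seed(sim_seed(config, "genes"))
  genome <- config$genome
  total <- sum(genome$length)
  n_per <- pmax(1L, round(config$n_genes * genome$length / total))
  n_per[length(n_per)] <- config$n_genes - sum(n_per[-length(n_per)])

  rows <- list()
  gi <- 0L
  for (ci in seq_len(nrow(genome))) {
    w <- genome$length[ci] / n_per[ci]
    for (i in seq_len(n_per[ci])) {
      gi <- gi + 1L
      s <- floor((i - 1) * w + 0.25 * w)
      rows[[gi]] <- data.frame(
        gene_id = sprintf("g%05d", gi), symbol = sprintf("G%05d", gi),
        chrom = genome$chrom[ci], start = s, end = s + floor(0.5 * w),
        stringsAsFactors = FALSE)
    }
  }
  genes <- do.call(rbind, rows)
  n <- nrow(genes)
  genes$ccr_true <- stats::runif(n) < config$frac_ccr
  genes$ens_true <- stats::runif(n) < config$frac_ens

  ccr <- genes$ccr_true
  genes$pli <- ifelse(ccr, stats::runif(n, 0.85, 1), stats::runif(n, 0, 0.5))
  genes$mis_z <- ifelse(ccr, stats::runif(n, 0, 5), stats::runif(n, -1, 2.5))
  genes$syn_z <- ifelse(ccr, stats::runif(n, -1, 2), stats::runif(n, -1, 2.5))
  genes$del_single <- ifelse(ccr, stats::runif(n, -2, 2), stats::runif(n, -3, 0.5))
  genes$dup_single <- ifelse(ccr, stats::runif(n, -2, 2), stats::runif(n, -3, 0.5))
  genes$cnv_score <- ifelse(ccr, stats::runif(n, -2, 2), stats::runif(n, -3, 0.5))
  genes$control_del_events <- 0L
  genes$control_dup_events <- 0L

  genes$mouse_orthologue <- ifelse(stats::runif(n) < config$frac_mouse_orth,
                                   paste0("Mm_", genes$symbol), NA_character_)
  has_zf <- stats::runif(n) < config$frac_zebrafish_orth
  dup_zf <- has_zf & stats::runif(n) < 0.3
  zf_base <- paste0(tolower(genes$symbol))
  genes$zebrafish_orthologues <- ifelse(
    has_zf, ifelse(dup_zf, paste0(zf_base, "a;", zf_base, "b"), zf_base),
    NA_character_)

  maps <- list()
  for (i in which(!is.na(genes$mouse_orthologue))) {
    maps[[length(maps) + 1L]] <- data.frame(
      gene_id = genes$gene_id[i], species = "mouse",
      orthologue = genes$mouse_orthologue[i], stringsAsFactors = FALSE)
  }
  for (i in which(!is.na(genes$zebrafish_orthologues))) {
    for (o in strsplit(genes$zebrafish_orthologues[i], ";", fixed = TRUE)[[1L]]) {
      maps[[length(maps) + 1L]] <- data.frame(
        gene_id = genes$gene_id[i], species = "zebrafish",
        orthologue = o, stringsAsFactors = FALSE)
    }
  }
  list(genes = genes, orthologue_map = do.call(rbind, maps))
}

#' Simulate an ENS/intestine expression study
#'
#' Generates a log2-scale expression matrix over the genes that have a mouse
#' orthologue (only those are evaluable on the emulated mouse arrays), with
#' classes `ENS_GDNF`, `ENS_noGDNF` and `intestine`. Planted ENS genes get a
#' `log2(ens_fold_change)` offset in both ENS classes; Gaussian noise and
#' missing-at-random values are added per the configuration.
#'
#' @param config a [sim_config()].
#' @param genes the `genes` table from [simulate_gene_annotation()].
#' @return list with `mat` (genes x samples log2 matrix, rownames =
#'   gene ids), `classes` (per-sample labels) and `truth` (logical planted
#'   ENS status per row).
#' @export
simulate_expression <- function(config, genes) {
  stopifnot(inherits(config, "sim_config"))
  if (config$n_samples_per_class < 2L) {
    stop("need at least 2 samples per class")
  }
  set.seed(sim_seed(config, "expr"))
  rows <- genes[!is.na(genes$mouse_orthologue), , drop = FALSE]
  n <- nrow(rows)
  npc <- config$n_samples_per_class
  classes <- rep(ENS_CLASSES, each = npc)
  baseline <- stats::runif(n, 4, 12)
  offset <- outer(ifelse(rows$ens_true, log2(config$ens_fold_change), 0),
                  as.numeric(classes %in% c("ENS_GDNF", "ENS_noGDNF")))
  noise <- matrix(stats::rnorm(n * length(classes), sd = config$expr_noise_sd),
                  n, length(classes))
  mat <- baseline + offset + noise
  if (config$frac_missing > 0) {
    mat[matrix(stats::runif(length(mat)) < config$frac_missing,
               n, length(classes))] <- NA_real_
  }
  rownames(mat) <- rows$gene_id
  colnames(mat) <- paste(classes, rep(seq_len(npc), times = 3L), sep = "_s")
  list(mat = mat, classes = classes, truth = rows$ens_true)
}

#' Default risk-SNP model from a configuration
#'
#' @param config a [sim_config()].
#' @return risk model data.frame (`snp_id`, `risk_allele`, `odds_ratio`,
#'   `risk_allele_freq`).
#' @export
default_risk_model <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  data.frame(snp_id = config$snp_ids, risk_allele = "T",
             odds_ratio = config$snp_ors,
             risk_allele_freq = config$snp_freqs,
             stringsAsFactors = FALSE)
}

#' Simulate Hardy-Weinberg risk-SNP genotypes
#'
#' Per-SNP risk-allele counts in \{0, 1, 2\} drawn Binomial(2, freq).
#'
#' @param config a [sim_config()].
#' @param sample_ids character vector of sample identifiers.
#' @param freqs risk-allele frequencies (default `config$snp_freqs`); must
#'   lie strictly inside (0,1).
#' @return wide data.frame: `sample_id` plus one count column per SNP.
#' @export
simulate_genotypes <- function(config, sample_ids,
                               freqs = config$snp_freqs) {
  stopifnot(inherits(config, "sim_config"))
  if (any(freqs <= 0 | freqs >= 1)) {
    stop("allele frequencies must lie strictly inside (0,1)")
  }
  if (length(freqs) != length(config$snp_ids)) {
    stop("one frequency per SNP is required")
  }
  set.seed(sim_seed(config, "geno"))
  n <- length(sample_ids)
  out <- data.frame(sample_id = sample_ids, stringsAsFactors = FALSE)
  for (j in seq_along(config$snp_ids)) {
    out[[config$snp_ids[j]]] <- stats::rbinom(n, 2L, freqs[j])
  }
  out
}

#' Simulate zebrafish phenotype category counts
#'
#' Multinomial counts over ENS categories I-V per condition.
#'
#' @param config a [sim_config()].
#' @param n_larvae larvae per condition (default from config).
#' @return data.frame: `condition`, `cat_I` .. `cat_V`.
#' @export
simulate_phenotype_counts <- function(config,
                                      n_larvae = config$n_larvae_per_condition) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(sim_seed(config, "pheno"))
  pp <- as.matrix(config$phenotype_probs)
  counts <- t(apply(pp, 1L, function(p) {
    as.integer(stats::rmultinom(1L, n_larvae, p))
  }))
  out <- data.frame(condition = rownames(pp), counts,
                    stringsAsFactors = FALSE, row.names = NULL)
  names(out)[-1L] <- c("cat_I", "cat_II", "cat_III", "cat_IV", "cat_V")
  out
}
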