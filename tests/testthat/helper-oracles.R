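# Brute-force per-base oracles on small toy genomes (<= 10 kb), used to
# cross-check the interval machinery independently of IRanges.

# fraction of [qs, qe) covered by the union of intervals, counting base pairs
bp_overlap_fraction <- function(qs, qe, starts, ends) {
  if (length(starts) == 0L) return(0)
  covered <- logical(qe - qs)
  for (i in seq_along(starts)) {
    lo <- max(starts[i], qs); hi <- min(ends[i], qe)
    if (lo < hi) covered[(lo - qs + 1):(hi - qs)] <- TRUE
  }
  mean(covered)
}

# per-sample per-base rarity oracle mirroring the classifier's contract
bp_classify_rare <- function(cases, controls, control_n,
                             min_overlap = 0.75, freq_cutoff = 0.00026) {
  cls <- function(s) ifelse(s %in% c("loss", "homozygous_loss",
                                     "hemizygous_loss"), "loss", "gain")
  out <- logical(nrow(cases))
  matched <- integer(nrow(cases))
  for (i in seq_len(nrow(cases))) {
    n_match <- 0L
    for (sid in unique(controls$sample_id)) {
      sub <- controls[controls$sample_id == sid &
                        controls$chrom == cases$chrom[i] &
                        cls(controls$state) == cls(cases$state[i]), ,
                      drop = FALSE]
      if (nrow(sub) == 0L) next
      frac <- bp_overlap_fraction(cases$start[i], cases$end[i],
                                  sub$start, sub$end)
      if (frac >= min_overlap) n_match <- n_match + 1L
    }
    matched[i] <- n_match
    out[i] <- (n_match / control_n) < freq_cutoff
  }
  list(is_rare = out, matched = matched)
}

# per-base gene/CNV intersection oracle
bp_genes_in_cnv <- function(chrom, start, end, genes) {
  hits <- character(0)
  for (i in seq_len(nrow(genes))) {
    if (genes$chrom[i] != chrom) next
    shared <- length(intersect(seq(genes$start[i], genes$end[i] - 1),
                               seq(start, end - 1)))
    if (shared >= 1L) hits <- c(hits, genes$gene_id[i])
  }
  hits
}

# random toy cohort on a single <= 10 kb chromosome
random_toy_cohort <- function(seed, genome_len = 10000L,
                              n_ctrl_samples = 8L, n_case_calls = 5L) {
  set.seed(seed)
  rand_calls <- function(sid, k, group) {
    size <- sample(100:3000, k, replace = TRUE)
    start <- vapply(size, function(s) sample.int(genome_len - s, 1L) - 1L,
                    integer(1L))
    data.frame(sample_id = sid, chrom = "toy", start = start,
               end = start + size,
               state = sample(c("loss", "gain", "homozygous_loss"), k,
                              replace = TRUE),
               inheritance = "unknown", group = group,
               stringsAsFactors = FALSE)
  }
  controls <- do.call(rbind, lapply(seq_len(n_ctrl_samples), function(s) {
    rand_calls(paste0("c", s), sample(1:4, 1L), 4L)
  }))
  cases <- rand_calls("case1", n_case_calls, 1L)
  # plant a guaranteed match: duplicate the first case call into a control
  dup <- cases[1L, ]
  dup$sample_id <- "c1"
  dup$group <- 4L
  list(cases = cases, controls = rbind(controls, dup))
}

random_toy_genes <- function(seed, genome_len = 10000L, n_genes = 12L) {
  set.seed(seed + 5000L)
  size <- sample(50:800, n_genes, replace = TRUE)
  start <- vapply(size, function(s) sample.int(genome_len - s, 1L) - 1L,
                  integer(1L))
  data.frame(gene_id = paste0("g", seq_len(n_genes)),
             symbol = paste0("G", seq_len(n_genes)),
             chrom = "toy", start = start, end = start + size,
             stringsAsFactors = FALSE)
}
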