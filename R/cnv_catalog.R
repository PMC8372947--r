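CNV_STATES <- c("loss", "gain", "homozygous_loss", "hemizygous_loss")
CNV_INHERITANCE <- c("de_novo", "maternal", "paternal", "unknown")
LOSS_STATES <- c("loss", "homozygous_loss", "hemizygous_loss")

#' Map a copy-number state to its matching class
#'
#' All loss states (`loss`, `homozygous_loss`, `hemizygous_loss`) pool into a
#' single "loss" class for control matching; gains match gains only.
#'
#' @param state character vector of CNV states.
#' @return character vector, `"loss"` or `"gain"`.
#' @export
state_class <- function(state) {
  ifelse(state %in% LOSS_STATES, "loss", "gain")
}

validate_cnv_calls <- function(calls) {
  stopifnot(is.data.frame(calls))
  required <- c("sample_id", "chrom", "start", "end", "state")
  missing_cols <- setdiff(required, names(calls))
  if (length(missing_cols) > 0L) {
    stop("CNV table is missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  if (!"inheritance" %in% names(calls)) {
    calls$inheritance <- rep("unknown", nrow(calls))
  }
  if (!"group" %in% names(calls)) calls$group <- rep(NA_integer_, nrow(calls))
  bad_state <- setdiff(unique(calls$state), CNV_STATES)
  if (length(bad_state) > 0L) {
    stop("unknown CNV state(s): ", paste(bad_state, collapse = ", "))
  }
  bad_inh <- setdiff(unique(calls$inheritance), CNV_INHERITANCE)
  if (length(bad_inh) > 0L) {
    stop("unknown inheritance value(s): ", paste(bad_inh, collapse = ", "))
  }
  if (any(calls$start >= calls$end)) {
    bad <- which(calls$start >= calls$end)[1L]
    stop("interval with start >= end at row ", bad)
  }
  if (any(calls$start < 0)) stop("negative start coordinate")
  calls$start <- as.numeric(calls$start)
  calls$end <- as.numeric(calls$end)
  calls[c(required, "inheritance", "group")]
}

#' Read a CNV call table
#'
#' Reads a TSV of CNV calls with columns `sample`/`sample_id`, `chrom`,
#' `start`, `end`, `state` and optionally `inheritance` and `group`.
#' Coordinates are stored 0-based half-open internally. Tables whose printed
#' coordinates are 1-based inclusive (the usual tabular convention, e.g.
#' "chr2:40,624,267-40,646,501") are converted by `dialect = "onebased"`.
#'
#' @param path path to a tab-separated file with a header line.
#' @param dialect `"bed0"` (0-based half-open, stored as-is) or `"onebased"`
#'   (1-based inclusive; converted to `(start-1, end)`).
#' @return data.frame of validated calls with columns `sample_id`, `chrom`,
#'   `start`, `end`, `state`, `inheritance`, `group`.
#' @export
read_cnv_table <- function(path, dialect = c("bed0", "onebased")) {
  dialect <- match.arg(dialect)
  raw <- utils::read.delim(path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE,
                           colClasses = NA, check.names = FALSE)
  if (nrow(raw) == 0L) {
    return(validate_cnv_calls(data.frame(
      sample_id = character(), chrom = character(),
      start = numeric(), end = numeric(), state = character(),
      stringsAsFactors = FALSE
    )))
  }
  if ("sample" %in% names(raw) && !"sample_id" %in% names(raw)) {
    names(raw)[names(raw) == "sample"] <- "sample_id"
  }
  for (col in c("start", "end")) {
    if (!col %in% names(raw)) stop("CNV table is missing column: ", col)
    val <- suppressWarnings(as.numeric(gsub(",", "", raw[[col]])))
    if (anyNA(val)) {
      stop("malformed ", col, " at line ", which(is.na(val))[1L] + 1L,
           " of ", path)
    }
    raw[[col]] <- val
  }
  if (dialect == "onebased") raw$start <- raw$start - 1
  validate_cnv_calls(raw)
}

#' Write a CNV call table
#'
#' Inverse of [read_cnv_table()]; round-trips losslessly for both dialects.
#'
#' @param calls validated CNV call data.frame.
#' @param path output path.
#' @param dialect coordinate dialect to write (see [read_cnv_table()]).
#' @export
write_cnv_table <- function(calls, path, dialect = c("bed0", "onebased")) {
  dialect <- match.arg(dialect)
  calls <- validate_cnv_calls(calls)
  out <- calls
  if (dialect == "onebased") out$start <- out$start + 1
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Fraction of a query interval covered by a set of intervals
#'
#' Computes |query intersect union(covering)| / size(query) on 0-based
#' half-open coordinates. The union is taken first so that tiled or
#' overlapping covering intervals are not double counted.
#'
#' @param q_start,q_end query interval (0-based half-open).
#' @param starts,ends covering intervals on the same chromosome.
#' @return a value in \[0, 1\]; 0 for an empty covering set.
#' @export
overlap_fraction <- function(q_start, q_end, starts, ends) {
  stopifnot(length(q_start) == 1L, length(q_end) == 1L, q_start < q_end)
  if (length(starts) == 0L) return(0)
  cov <- IRanges::reduce(IRanges::IRanges(start = starts + 1L, end = ends))
  q <- IRanges::IRanges(start = q_start + 1L, end = q_end)
  hit <- IRanges::intersect(cov, q)
  sum(IRanges::width(hit)) / (q_end - q_start)
}

#' Classify case CNVs as rare or common against a control cohort
#'
#' A case call is matched by a control sample when that sample carries calls
#' of the same state class (losses pooled, gains separate) whose union covers
#' at least `min_overlap` of the case call. The call frequency is the number
#' of matched control samples divided by `control_n` (the control cohort
#' size, which may exceed the number of samples with calls); a call is rare
#' when its frequency is below `freq_cutoff`.
#'
#' @param cases CNV call data.frame (query calls).
#' @param controls CNV call data.frame for the control cohort.
#' @param control_n control cohort size (individuals), `>=` number of
#'   distinct control samples.
#' @param min_overlap minimum covered fraction of the case call (default 0.75).
#' @param freq_cutoff rarity threshold on control frequency (default 0.00026,
#'   i.e. 0.026\%).
#' @param reciprocal if `TRUE`, additionally require that the case call cover
#'   `min_overlap` of the union of the matching sample's overlapping calls.
#' @return `cases` with added columns `matched_controls`, `control_n`,
#'   `frequency`, `is_rare`.
#' @export
classify_rare <- function(cases, controls, control_n,
                          min_overlap = 0.75, freq_cutoff = 0.00026,
                          reciprocal = FALSE) {
  cases <- validate_cnv_calls(cases)
  controls <- validate_cnv_calls(controls)
  if (length(control_n) != 1L || is.na(control_n) || control_n < 1) {
    stop("control_n must be a positive count")
  }
  n_ctrl_samples <- length(unique(controls$sample_id))
  if (control_n < n_ctrl_samples) {
    stop("control_n (", control_n, ") is smaller than the number of distinct ",
         "control samples (", n_ctrl_samples, ")")
  }
  ctrl_class <- state_class(controls$state)
  key <- paste(controls$chrom, ctrl_class, sep = "\r")
  ctrl_split <- split(seq_len(nrow(controls)), key)

  # union length of a set of half-open intervals (sort-and-scan)
  union_len <- function(s, e) {
    if (length(s) == 1L) return(e - s)
    o <- order(s)
    s <- s[o]; e <- e[o]
    tot <- 0; cur_s <- s[1L]; cur_e <- e[1L]
    for (j in 2:length(s)) {
      if (s[j] > cur_e) {
        tot <- tot + (cur_e - cur_s); cur_s <- s[j]; cur_e <- e[j]
      } else if (e[j] > cur_e) cur_e <- e[j]
    }
    tot + (cur_e - cur_s)
  }

  matched <- integer(nrow(cases))
  for (i in seq_len(nrow(cases))) {
    k <- paste(cases$chrom[i], state_class(cases$state[i]), sep = "\r")
    idx <- ctrl_split[[k]]
    if (is.null(idx)) next
    # restrict to calls actually touching the query before per-sample work
    touch <- idx[controls$start[idx] < cases$end[i] &
                   controls$end[idx] > cases$start[i]]
    if (length(touch) == 0L) next
    qs <- cases$start[i]; qe <- cases$end[i]
    cs <- pmax(controls$start[touch], qs)
    ce <- pmin(controls$end[touch], qe)
    per_sample <- split(seq_along(touch), controls$sample_id[touch])
    n_match <- 0L
    for (rows in per_sample) {
      ok <- union_len(cs[rows], ce[rows]) / (qe - qs) >= min_overlap
      if (ok && reciprocal) {
        full <- union_len(controls$start[touch][rows],
                          controls$end[touch][rows])
        ok <- union_len(cs[rows], ce[rows]) / full >= min_overlap
      }
      if (ok) n_match <- n_match + 1L
    }
    matched[i] <- n_match
  }
  cases$matched_controls <- matched
  cases$control_n <- control_n
  cases$frequency <- matched / control_n
  cases$is_rare <- cases$frequency < freq_cutoff
  cases
}

#' Size z-scores of rare CNV calls
#'
#' Standardizes call sizes over the reference set of calls:
#' `z = (size - mean(sizes)) / sd(sizes)` with the sample (n-1) standard
#' deviation, either pooled or within each state class.
#'
#' @param calls CNV call data.frame (typically the rare calls).
#' @param stratify_by_state compute the reference mean/sd within each state
#'   class (losses pooled vs gains) instead of over all calls.
#' @return `calls` with added columns `size` and `size_z`.
#' @export
size_zscores <- function(calls, stratify_by_state = FALSE) {
  calls <- validate_cnv_calls(calls)
  calls$size <- calls$end - calls$start
  zs <- function(x) {
    if (length(x) < 2L) stop("need >= 2 calls in the reference set")
    s <- stats::sd(x)
    if (s == 0) stop("zero size variance in the reference set")
    (x - mean(x)) / s
  }
  if (stratify_by_state) {
    cls <- state_class(calls$state)
    calls$size_z <- NA_real_
    for (cl in unique(cls)) {
      sel <- cls == cl
      calls$size_z[sel] <- zs(calls$size[sel])
    }
  } else {
    calls$size_z <- zs(calls$size)
  }
  calls
}
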