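#' Fragments per million (FPM)
#'
#' Normalises unique-read counts within each sample: every smMIP's count is
#' divided by the sample's total assigned unique reads and multiplied by
#' 10^6. No housekeeping-gene normalisation is applied. Per sample, FPM sums
#' to 10^6 whenever the total is positive; a sample with zero total yields
#' all-zero FPM with a warning (not an error).
#'
#' @param counts non-negative count vector (one sample) or matrix with one
#'   column per sample (e.g. from [count_table()]).
#' @return FPM values with the shape and dimnames of `counts`.
#' @export
compute_fpm <- function(counts) {
  if (is.matrix(counts)) {
    out <- counts * 0
    for (j in seq_len(ncol(counts))) out[, j] <- compute_fpm(counts[, j])
    return(out)
  }
  if (any(counts < 0)) stop("counts must be non-negative", call. = FALSE)
  total <- sum(counts)
  if (total == 0) {
    warning("sample has zero assigned unique reads; FPM set to 0")
    return(counts * 0)
  }
  counts / total * 1e6
}

#' Aggregate per-smMIP FPM to transcript level
#'
#' Combines the FPM values of all smMIPs targeting one transcript. `mean`
#' (the default used for transcriptome comparisons) deliberately includes
#' zero-FPM smMIPs, so non-performing probes pull the transcript value down;
#' `best` takes the best-performing smMIP (maximum); `median` the standard
#' midpoint rule.
#'
#' @param fpm per-smMIP FPM vector (named by smMIP) or matrix (rows =
#'   smMIPs, columns = samples).
#' @param panel an `smmip_panel` mapping every smMIP to one transcript.
#' @param method one of `"mean"`, `"median"`, `"best"`.
#' @return per-transcript values; matrix input gives a transcript x sample
#'   matrix.
#' @export
aggregate_transcript <- function(fpm, panel, method = c("mean", "median", "best")) {
  method <- match.arg(method)
  f <- switch(method, mean = mean, median = median, best = max)
  if (!is.matrix(fpm)) fpm <- matrix(fpm, ncol = 1L,
                                     dimnames = list(names(fpm), "sample"))
  unknown <- setdiff(rownames(fpm), panel$smmip_id)
  if (length(unknown))
    stop("FPM rows not in panel: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  tid <- panel$transcript_id[match(rownames(fpm), panel$smmip_id)]
  transcripts <- unique(panel$transcript_id)
  out <- matrix(NA_real_, nrow = length(transcripts), ncol = ncol(fpm),
                dimnames = list(transcripts, colnames(fpm)))
  for (tr in transcripts) {
    rows <- which(tid == tr)
    if (length(rows))
      out[tr, ] <- apply(fpm[rows, , drop = FALSE], 2L, f)
  }
  out
}

#' Transcripts per million (TPM)
#'
#' Length-normalised relative expression from whole-transcriptome gene
#' counts: TPM_i = (count_i / length_i) / sum_j(count_j / length_j) x 10^6.
#'
#' @param counts non-negative gene counts (vector or matrix, rows = genes).
#' @param lengths positive effective gene/transcript lengths, recycled over
#'   rows.
#' @return TPM values with the shape of `counts`; columns sum to 10^6.
#' @export
compute_tpm <- function(counts, lengths) {
  if (any(lengths <= 0)) stop("lengths must be positive", call. = FALSE)
  if (is.matrix(counts)) {
    out <- counts * 0
    for (j in seq_len(ncol(counts))) out[, j] <- compute_tpm(counts[, j], lengths)
    return(out)
  }
  rate <- counts / lengths
  rate / sum(rate) * 1e6
}

#' Concordance between smMIP FPM and whole-transcriptome TPM
#'
#' Pairs per-transcript aggregate FPM values with TPM values for the same
#' transcripts and computes the Pearson correlation, by default on
#' log10(x + pseudocount) because expression spans orders of magnitude and
#' non-performing panels produce very low FPM values. Transcripts present on
#' only one side are reported in the result, never silently dropped.
#'
#' @param fpm named per-transcript aggregate FPM vector (e.g. one column of
#'   [aggregate_transcript()]).
#' @param tpm named per-transcript TPM vector.
#' @param pseudocount positive offset added before the log (default 0.01).
#' @param log_transform correlate on log10(x + pseudocount) (default) or on
#'   the raw scale.
#' @return object of class `concordance_result`: `pairs` (data.frame of
#'   matched values), `r`, `n`, `transform`, `missing_fpm`, `missing_tpm`.
#' @export
correlate_fpm_tpm <- function(fpm, tpm, pseudocount = 0.01,
                              log_transform = TRUE) {
  if (pseudocount <= 0) stop("pseudocount must be > 0", call. = FALSE)
  if (is.null(names(fpm)) || is.null(names(tpm)))
    stop("fpm and tpm must be named by transcript", call. = FALSE)
  shared <- intersect(names(fpm), names(tpm))
  if (length(shared) < 3L)
    stop("need at least 3 matched transcripts for a correlation", call. = FALSE)
  x <- as.numeric(fpm[shared]); y <- as.numeric(tpm[shared])
  if (log_transform) { x <- log10(x + pseudocount); y <- log10(y + pseudocount) }
  structure(list(
    pairs = data.frame(transcript_id = shared, fpm = as.numeric(fpm[shared]),
                       tpm = as.numeric(tpm[shared]),
                       stringsAsFactors = FALSE),
    r = cor(x, y), n = length(shared),
    transform = if (log_transform)
      sprintf("log10(x + %g)", pseudocount) else "identity",
    missing_fpm = setdiff(names(tpm), names(fpm)),
    missing_tpm = setdiff(names(fpm), names(tpm))),
    class = "concordance_result")
}

#' @export
print.concordance_result <- function(x, ...) {
  cat(sprintf("FPM-TPM concordance: Pearson r = %.3f on %d transcripts (%s)\n",
              x$r, x$n, x$transform))
  if (length(x$missing_tpm))
    cat("no TPM value for:", paste(x$missing_tpm, collapse = ", "), "\n")
  if (length(x$missing_fpm))
    cat("no FPM value for:", paste(x$missing_fpm, collapse = ", "), "\n")
  invisible(x)
}
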