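#' Transcript model
#'
#' A spliced mRNA (sense strand) together with its exon structure and coding
#' interval, the substrate for probe design, read simulation and variant
#' annotation. All coordinates are 0-based, half-open transcript coordinates;
#' 1-based c. numbering appears only in HGVS output.
#'
#' @param transcript_id transcript identifier (RefSeq-style ids work well).
#' @param gene_symbol gene symbol used to name smMIPs (e.g. `VHL` gives
#'   `VHL_1`, `VHL_2`, ...).
#' @param sequence spliced mRNA sequence, alphabet A/C/G/T.
#' @param exon_ends strictly increasing integer offsets marking exon ends in
#'   transcript coordinates; the last entry must equal `nchar(sequence)`.
#' @param cds_start,cds_end 0-based half-open coding interval; the CDS length
#'   must be divisible by 3.
#' @return an object of class `transcript_model`.
#' @export
transcript_model <- function(transcript_id, gene_symbol, sequence,
                             exon_ends = nchar(sequence),
                             cds_start = 0L, cds_end = nchar(sequence)) {
  sequence <- toupper(sequence)
  assert_dna(sequence, sprintf("transcript %s", transcript_id))
  exon_ends <- as.integer(exon_ends)
  if (any(diff(exon_ends) <= 0L) || length(exon_ends) == 0L)
    stop("exon_ends must be strictly increasing", call. = FALSE)
  if (exon_ends[length(exon_ends)] != nchar(sequence))
    stop("last exon end must equal transcript length", call. = FALSE)
  cds_start <- as.integer(cds_start); cds_end <- as.integer(cds_end)
  if (cds_start < 0L || cds_end > nchar(sequence) || cds_end <= cds_start)
    stop("CDS interval outside transcript", call. = FALSE)
  if ((cds_end - cds_start) %% 3L != 0L)
    stop("CDS length must be divisible by 3", call. = FALSE)
  structure(
    list(transcript_id = transcript_id, gene_symbol = gene_symbol,
         sequence = sequence, exon_ends = exon_ends,
         cds_start = cds_start, cds_end = cds_end),
    class = "transcript_model")
}

#' @export
print.transcript_model <- function(x, ...) {
  cat(sprintf("transcript_model %s (%s): %d nt, %d exon(s), CDS [%d, %d)\n",
              x$transcript_id, x$gene_symbol, nchar(x$sequence),
              length(x$exon_ends), x$cds_start, x$cds_end))
  invisible(x)
}

# 1-based exon index containing 0-based transcript position pos.
exon_of <- function(transcript, pos) {
  findInterval(pos, c(0L, transcript$exon_ends), left.open = FALSE,
               rightmost.closed = TRUE)
}

# Coding sequence of a transcript model.
cds_seq <- function(transcript) {
  substr(transcript$sequence, transcript$cds_start + 1L, transcript$cds_end)
}

#' Read transcript models from FASTA plus a sidecar table
#'
#' The sidecar TSV has columns `transcript_id`, `gene_symbol`, `exon_ends`
#' (comma-separated ascending offsets), `cds_start`, `cds_end`. Every sidecar
#' row must have a FASTA record with a matching id.
#'
#' @param fasta path to a (possibly gzipped) FASTA of spliced transcripts.
#' @param meta path to the sidecar TSV.
#' @return named list of [transcript_model()] objects.
#' @export
read_transcripts <- function(fasta, meta) {
  seqs <- Biostrings::readDNAStringSet(fasta)
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  tab <- read.delim(meta, stringsAsFactors = FALSE)
  need <- c("transcript_id", "gene_symbol", "exon_ends", "cds_start", "cds_end")
  if (!all(need %in% names(tab)))
    stop("transcript sidecar must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  missing <- setdiff(tab$transcript_id, names(seqs))
  if (length(missing))
    stop("no FASTA record for transcript(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  out <- lapply(seq_len(nrow(tab)), function(i) {
    transcript_model(
      transcript_id = tab$transcript_id[i],
      gene_symbol = tab$gene_symbol[i],
      sequence = as.character(seqs[[tab$transcript_id[i]]]),
      exon_ends = as.integer(strsplit(tab$exon_ends[i], ",", fixed = TRUE)[[1L]]),
      cds_start = tab$cds_start[i], cds_end = tab$cds_end[i])
  })
  setNames(out, tab$transcript_id)
}

#' Write transcript models to FASTA plus a sidecar table
#'
#' Inverse of [read_transcripts()].
#'
#' @param transcripts named list of [transcript_model()] objects.
#' @param fasta,meta output paths.
#' @return invisibly, the two paths.
#' @export
write_transcripts <- function(transcripts, fasta, meta) {
  seqs <- Biostrings::DNAStringSet(vapply(transcripts, `[[`, "", "sequence"))
  names(seqs) <- vapply(transcripts, `[[`, "", "transcript_id")
  Biostrings::writeXStringSet(seqs, fasta)
  tab <- data.frame(
    transcript_id = vapply(transcripts, `[[`, "", "transcript_id"),
    gene_symbol = vapply(transcripts, `[[`, "", "gene_symbol"),
    exon_ends = vapply(transcripts, function(t)
      paste(t$exon_ends, collapse = ","), ""),
    cds_start = vapply(transcripts, function(t) t$cds_start, 0L),
    cds_end = vapply(transcripts, function(t) t$cds_end, 0L))
  write.table(tab, meta, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(fasta, meta))
}

#' Table of targeted metabolic transcripts shipped with the package
#'
#' The panel's target list of 104 metabolic transcript entries (gene symbol,
#' gene name, RefSeq mRNA id), as used for a metabolism-focused smMIP panel
#' in clear cell renal cell carcinoma profiling.
#'
#' @return data.frame with columns `gene_symbol`, `gene_name`, `refseq_id`.
#' @export
target_transcript_table <- function() {
  read.delim(system.file("extdata", "table1_targets.tsv", package = "smmipseq"),
             stringsAsFactors = FALSE)
}
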