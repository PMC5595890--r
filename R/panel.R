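#' Constant smMIP backbone
#'
#' The 40-nt constant linker joining the ligation and extension probes. It
#' carries the PCR primer sites in the wet-lab assay; in this package it is a
#' fixed, documented constant shared by the amplicon simulator and the read
#' processor.
#' @export
SMMIP_BACKBONE <- "CTTCAGCTTCCCGATATCCGACGGTAGTGTCGCAGATCGG"

GAP_LENGTH <- 112L
UMI_LENGTH <- 8L

#' Design parameters for smMIP panels
#'
#' Collects all tunable thresholds of the probe designer. Arm-length minima
#' (16 nt extension, 18 nt ligation), the 112-nt gap and the 8-nt UMI are the
#' assay's structural constants; maxima, GC window and stride are design
#' choices with documented defaults.
#'
#' @param ext_min,ext_max extension-arm length search range (nt).
#' @param lig_min,lig_max ligation-arm length search range (nt).
#' @param stride spacing between successive candidate gap starts (nt).
#' @param gc_min,gc_max arm GC-content window; the shortest arm whose GC
#'   falls inside the window is preferred, falling back to the minimum length.
#' @param n_per_transcript smMIPs selected per transcript in default mode.
#' @param max_per_transcript upper bound on `n_per_transcript`.
#' @param junction_bonus additive score bonus used when ranking
#'   junction-spanning candidates during selection (soft preference).
#' @return a named list of class `smmip_design_params`.
#' @export
design_params <- function(ext_min = 16L, ext_max = 30L,
                          lig_min = 18L, lig_max = 30L,
                          stride = 10L, gc_min = 0.2, gc_max = 0.8,
                          n_per_transcript = 5L, max_per_transcript = 10L,
                          junction_bonus = 0.1) {
  if (n_per_transcript < 1L)
    stop("n_per_transcript must be >= 1", call. = FALSE)
  if (n_per_transcript > max_per_transcript)
    stop("n_per_transcript exceeds max_per_transcript", call. = FALSE)
  if (stride < 1L) stop("stride must be >= 1", call. = FALSE)
  structure(list(
    ext_min = as.integer(ext_min), ext_max = as.integer(ext_max),
    lig_min = as.integer(lig_min), lig_max = as.integer(lig_max),
    gap_length = GAP_LENGTH, umi_length = UMI_LENGTH,
    stride = as.integer(stride), gc_min = gc_min, gc_max = gc_max,
    n_per_transcript = as.integer(n_per_transcript),
    max_per_transcript = as.integer(max_per_transcript),
    junction_bonus = junction_bonus), class = "smmip_design_params")
}

# Shortest arm length in [lo, hi] whose target GC falls in the window;
# falls back to lo. `get_target(len)` returns the target substring.
.pick_arm_len <- function(lo, hi, get_target, params) {
  for (len in lo:hi) {
    gcx <- gc_fraction(get_target(len))
    if (!is.na(gcx) && gcx >= params$gc_min && gcx <= params$gc_max)
      return(len)
  }
  lo
}

#' Score an smMIP candidate
#'
#' Transparent arm-quality score in `[0, 1]`: each arm contributes a GC
#' penalty (1 inside the `[gc_min, gc_max]` window, decaying linearly to 0
#' over 0.2 GC units outside it) times a homopolymer penalty (halved for
#' every base a run extends beyond 5). Arms containing N score 0. The two arm
#' scores multiply. Deterministic in its inputs.
#'
#' @param ext_arm,lig_arm probe arm sequences.
#' @param params a [design_params()] list.
#' @return numeric score in `[0, 1]`.
#' @export
score_candidate <- function(ext_arm, lig_arm, params = design_params()) {
  arm_score <- function(arm) {
    if (grepl("N", arm, fixed = TRUE)) return(0)
    gcx <- gc_fraction(arm)
    dist <- max(0, params$gc_min - gcx, gcx - params$gc_max)
    gc_pen <- max(0, 1 - dist / 0.2)
    run <- max_homopolymer(arm)
    hp_pen <- if (run >= 6L) 0.5^(run - 5L) else 1
    gc_pen * hp_pen
  }
  mapply(function(e, l) arm_score(e) * arm_score(l), ext_arm, lig_arm,
         USE.NAMES = FALSE)
}

.empty_candidates <- function() {
  data.frame(candidate_id = character(0), transcript_id = character(0),
             gene_symbol = character(0), ext_arm = character(0),
             lig_arm = character(0), gap_start = integer(0),
             gap_end = integer(0), umi_length = integer(0),
             backbone = character(0), spans_junction = logical(0),
             score = numeric(0), cds_start = integer(0),
             cds_end = integer(0), stringsAsFactors = FALSE)
}

#' Enumerate smMIP candidates along a transcript
#'
#' Slides a 112-nt gap window along the transcript at the configured stride
#' and, for each admissible window, picks the shortest extension (>= 16 nt)
#' and ligation (>= 18 nt) arms whose GC falls in the configured window. The
#' probe arms are the reverse complements of the transcript regions
#' immediately flanking the gap (the probe hybridises to the antisense strand
#' of the cDNA). A candidate whose two arms fall on different exons is
#' flagged `spans_junction`; such probes cannot capture contaminating genomic
#' DNA, where the intervening intron breaks the arm spacing.
#'
#' A transcript too short for `ext_min + 112 + lig_min` yields an empty
#' candidate frame (a "no feasible window" result), not an error.
#'
#' @param transcript a [transcript_model()].
#' @param params a [design_params()] list.
#' @param stride optional stride override (e.g. 1 for full-coverage tiling).
#' @return data.frame of candidates, one row per admissible gap window.
#' @export
enumerate_candidates <- function(transcript, params = design_params(),
                                 stride = params$stride) {
  len <- nchar(transcript$sequence)
  first <- params$ext_min
  last <- len - GAP_LENGTH - params$lig_min
  if (last < first) return(.empty_candidates())
  gap_starts <- seq.int(first, last, by = stride)
  seqn <- transcript$sequence
  ext_targets <- character(length(gap_starts))
  lig_targets <- character(length(gap_starts))
  for (i in seq_along(gap_starts)) {
    g <- gap_starts[i]
    e <- .pick_arm_len(params$ext_min, min(params$ext_max, g),
                       function(k) substr(seqn, g - k + 1L, g), params)
    max_l <- min(params$lig_max, len - (g + GAP_LENGTH))
    l <- .pick_arm_len(params$lig_min, max_l,
                       function(k) substr(seqn, g + GAP_LENGTH + 1L,
                                          g + GAP_LENGTH + k), params)
    ext_targets[i] <- substr(seqn, g - e + 1L, g)
    lig_targets[i] <- substr(seqn, g + GAP_LENGTH + 1L, g + GAP_LENGTH + l)
  }
  out <- data.frame(
    candidate_id = sprintf("%s:g%d", transcript$transcript_id, gap_starts),
    transcript_id = transcript$transcript_id,
    gene_symbol = transcript$gene_symbol,
    ext_arm = revcomp(ext_targets), lig_arm = revcomp(lig_targets),
    gap_start = gap_starts, gap_end = gap_starts + GAP_LENGTH,
    umi_length = UMI_LENGTH, backbone = SMMIP_BACKBONE,
    spans_junction = exon_of(transcript, gap_starts - 1L) !=
      exon_of(transcript, gap_starts + GAP_LENGTH),
    score = NA_real_, cds_start = transcript$cds_start,
    cds_end = transcript$cds_end, stringsAsFactors = FALSE)
  out$score <- score_candidate(out$ext_arm, out$lig_arm, params)
  out
}

# Deterministic candidate ordering used for all tie-breaks:
# higher score first, then lower gap_start, then candidate id.
.tie_order <- function(df, primary = NULL) {
  if (is.null(primary)) primary <- rep(0, nrow(df))
  order(primary, -df$score, df$gap_start, df$candidate_id)
}

# Select n candidates for one transcript, maximising even spacing of gap
# midpoints over the CDS: greedy assignment of the closest candidate to each
# point of the ideal n-point grid.
.select_even <- function(cand, n, params) {
  if (nrow(cand) <= n) return(cand[.tie_order(cand), , drop = FALSE])
  cds_len <- cand$cds_end[1L] - cand$cds_start[1L]
  grid <- cand$cds_start[1L] + (seq_len(n) - 0.5) * cds_len / n
  mid <- (cand$gap_start + cand$gap_end) / 2
  taken <- logical(nrow(cand))
  picked <- integer(0)
  for (g in grid) {
    avail <- which(!taken)
    d <- abs(mid[avail] - g)
    o <- order(d, -cand$score[avail], cand$gap_start[avail],
               cand$candidate_id[avail])
    sel <- avail[o[1L]]
    taken[sel] <- TRUE
    picked <- c(picked, sel)
  }
  sel <- cand[sort(picked), , drop = FALSE]
  # junction guarantee: if some admissible window spans a junction, make
  # sure at least one selected probe does (soft preference made effective)
  if (!any(sel$spans_junction) && any(cand$spans_junction)) {
    junc <- cand[cand$spans_junction, , drop = FALSE]
    junc <- junc[.tie_order(junc), , drop = FALSE][1L, , drop = FALSE]
    jm <- (junc$gap_start + junc$gap_end) / 2
    drop_idx <- which.min(abs((sel$gap_start + sel$gap_end) / 2 - jm))
    sel <- rbind(sel[-drop_idx, , drop = FALSE], junc)
    sel <- sel[order(sel$gap_start), , drop = FALSE]
  }
  sel
}

# Greedy interval covering of the CDS by candidate gaps (full-coverage mode).
.select_cover <- function(cand, params) {
  cand <- cand[order(cand$gap_start), , drop = FALSE]
  cds_start <- cand$cds_start[1L]; cds_end <- cand$cds_end[1L]
  target <- max(cds_start, min(cand$gap_start))
  picked <- integer(0)
  while (target < cds_end) {
    reach <- which(cand$gap_start <= target & cand$gap_end > target)
    if (!length(reach)) {
      nxt <- which(cand$gap_start > target)
      if (!length(nxt)) break
      target <- min(cand$gap_start[nxt])  # hole candidates cannot fill
      next
    }
    o <- order(-cand$gap_end[reach], -cand$score[reach],
               cand$gap_start[reach], cand$candidate_id[reach])
    best <- reach[o[1L]]
    picked <- c(picked, best)
    target <- cand$gap_end[best]
  }
  cand[sort(unique(picked)), , drop = FALSE]
}

# TRUE when the union of selected gaps covers [cds_start, cds_end).
.covers_cds <- function(sel) {
  if (nrow(sel) == 0L) return(FALSE)
  cds_start <- sel$cds_start[1L]; cds_end <- sel$cds_end[1L]
  sel <- sel[order(sel$gap_start), , drop = FALSE]
  cover <- cds_start
  for (i in seq_len(nrow(sel))) {
    if (sel$gap_start[i] > cover) return(FALSE)
    cover <- max(cover, sel$gap_end[i])
  }
  cover >= cds_end
}

#' Select an smMIP panel from per-transcript candidates
#'
#' Default mode picks `n_per_transcript` candidates per transcript (default
#' 5, capped at 10) maximising even spacing of gap midpoints across the CDS,
#' greedily assigning each point of the ideal grid its nearest candidate
#' (ties: higher score, then lower gap start, then candidate id). If any
#' admissible window spans an exon junction, at least one selected probe
#' will. Full-coverage mode instead tiles gaps so their union covers the
#' whole CDS wherever candidates allow. Transcripts ending up with fewer
#' than `n_per_transcript` probes (or an incompletely covered CDS) are
#' reported in the `under_covered` attribute. Selection is deterministic.
#'
#' @param candidates named list of candidate data.frames from
#'   [enumerate_candidates()], one per transcript.
#' @param params a [design_params()] list.
#' @param full_coverage character vector of transcript_ids (or gene symbols)
#'   to design in full-coverage mode.
#' @return an `smmip_panel` data.frame; smMIP ids are `<gene>_<ordinal>` in
#'   gap order. Attributes: `design_params`, `under_covered`.
#' @export
select_panel <- function(candidates, params = design_params(),
                         full_coverage = character(0)) {
  n <- params$n_per_transcript
  under <- character(0)
  chosen <- lapply(candidates, function(cand) {
    if (nrow(cand) == 0L) return(cand)
    full <- cand$transcript_id[1L] %in% full_coverage ||
      cand$gene_symbol[1L] %in% full_coverage
    sel <- if (full) .select_cover(cand, params) else .select_even(cand, n, params)
    sel
  })
  for (tid in names(candidates)) {
    sel <- chosen[[tid]]
    full <- length(sel$transcript_id) && (sel$transcript_id[1L] %in% full_coverage ||
      sel$gene_symbol[1L] %in% full_coverage)
    short <- if (nrow(sel) == 0L) TRUE
             else if (full) !.covers_cds(sel)
             else nrow(sel) < n
    if (short) under <- c(under, tid)
  }
  panel <- do.call(rbind, c(chosen, list(make.row.names = FALSE)))
  if (is.null(panel) || nrow(panel) == 0L) {
    panel <- .empty_candidates()
  }
  # final ids: <gene>_<ordinal>, ordered within gene by transcript then gap
  panel <- panel[order(panel$gene_symbol, panel$transcript_id,
                       panel$gap_start), , drop = FALSE]
  ord <- stats::ave(seq_len(nrow(panel)), panel$gene_symbol,
                    FUN = seq_along)
  panel$smmip_id <- sprintf("%s_%d", panel$gene_symbol, ord)
  panel <- panel[, c("smmip_id", "transcript_id", "gene_symbol", "ext_arm",
                     "lig_arm", "gap_start", "gap_end", "umi_length",
                     "backbone", "spans_junction", "score")]
  rownames(panel) <- NULL
  structure(panel, class = c("smmip_panel", "data.frame"),
            design_params = params, under_covered = under)
}

#' Design an smMIP panel against a set of transcripts
#'
#' Convenience wrapper: enumerates candidates for every transcript (stride 1
#' for full-coverage transcripts) and selects the panel.
#'
#' @param transcripts named list of [transcript_model()] objects.
#' @param params a [design_params()] list.
#' @param full_coverage transcript ids or gene symbols to tile across the
#'   full CDS.
#' @return an `smmip_panel` (see [select_panel()]).
#' @export
design_panel <- function(transcripts, params = design_params(),
                         full_coverage = character(0)) {
  cands <- lapply(transcripts, function(tr) {
    full <- tr$transcript_id %in% full_coverage ||
      tr$gene_symbol %in% full_coverage
    enumerate_candidates(tr, params, stride = if (full) 1L else params$stride)
  })
  select_panel(cands, params, full_coverage)
}

#' @export
print.smmip_panel <- function(x, ...) {
  cat(sprintf("smmip_panel: %d smMIPs on %d transcript(s)\n",
              nrow(x), length(unique(x$transcript_id))))
  uc <- attr(x, "under_covered")
  if (length(uc)) cat("under-covered:", paste(uc, collapse = ", "), "\n")
  NextMethod()
}

.panel_cols <- c("smmip_id", "transcript_id", "gene_symbol", "ext_arm",
                 "lig_arm", "gap_start", "gap_end", "umi_length", "backbone",
                 "spans_junction", "score")

#' Write / read an smMIP panel as TSV
#'
#' The panel file is a TSV with one row per smMIP and the columns
#' `smmip_id, transcript_id, gene_symbol, ext_arm, lig_arm, gap_start,
#' gap_end, umi_length, backbone, spans_junction, score`. Design parameters
#' and under-covered transcripts are preserved in `#param` / `#under_covered`
#' comment lines, so `read_panel(write_panel(p))` reproduces `p`.
#'
#' @param panel an `smmip_panel`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_panel <- function(panel, path) {
  con <- file(path, "w")
  on.exit(close(con))
  p <- attr(panel, "design_params")
  if (!is.null(p)) {
    for (k in names(p))
      writeLines(sprintf("#param\t%s\t%s", k, format(p[[k]], digits = 15)), con)
  }
  for (u in attr(panel, "under_covered"))
    writeLines(sprintf("#under_covered\t%s", u), con)
  writeLines(paste(.panel_cols, collapse = "\t"), con)
  if (nrow(panel)) {
    df <- as.data.frame(panel)[, .panel_cols]
    df$score <- format(df$score, digits = 15, trim = TRUE)
    writeLines(do.call(paste, c(df, sep = "\t")), con)
  }
  invisible(path)
}

#' @rdname write_panel
#' @param file panel TSV path to read.
#' @export
read_panel <- function(file) {
  lines <- readLines(file)
  is_comment <- startsWith(lines, "#")
  params <- list(); under <- character(0)
  for (cl in lines[is_comment]) {
    f <- strsplit(cl, "\t", fixed = TRUE)[[1L]]
    if (f[1L] == "#param") params[[f[2L]]] <- f[3L]
    if (f[1L] == "#under_covered") under <- c(under, f[2L])
  }
  body <- which(!is_comment)
  if (!length(body)) stop("panel file has no header", call. = FALSE)
  header <- strsplit(lines[body[1L]], "\t", fixed = TRUE)[[1L]]
  if (!identical(header, .panel_cols))
    stop("unexpected panel header; expected: ",
         paste(.panel_cols, collapse = ", "), call. = FALSE)
  rows <- body[-1L]
  parsed <- lapply(rows, function(i) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1L]]
    if (length(f) != length(.panel_cols))
      stop(sprintf("malformed panel row at line %d: expected %d fields, got %d",
                   i, length(.panel_cols), length(f)), call. = FALSE)
    f
  })
  if (length(parsed)) {
    m <- do.call(rbind, parsed)
    panel <- data.frame(
      smmip_id = m[, 1L], transcript_id = m[, 2L], gene_symbol = m[, 3L],
      ext_arm = m[, 4L], lig_arm = m[, 5L],
      gap_start = as.integer(m[, 6L]), gap_end = as.integer(m[, 7L]),
      umi_length = as.integer(m[, 8L]), backbone = m[, 9L],
      spans_junction = as.logical(m[, 10L]), score = as.numeric(m[, 11L]),
      stringsAsFactors = FALSE)
  } else {
    panel <- data.frame(
      smmip_id = character(0), transcript_id = character(0),
      gene_symbol = character(0), ext_arm = character(0),
      lig_arm = character(0), gap_start = integer(0), gap_end = integer(0),
      umi_length = integer(0), backbone = character(0),
      spans_junction = logical(0), score = numeric(0),
      stringsAsFactors = FALSE)
  }
  if (anyDuplicated(panel$smmip_id))
    stop("duplicate smmip_id in panel file", call. = FALSE)
  if (any(panel$gap_end - panel$gap_start != GAP_LENGTH))
    stop("panel contains gaps of length != 112", call. = FALSE)
  dp <- NULL
  if (length(params)) {
    dp <- design_params(
      ext_min = as.integer(params$ext_min), ext_max = as.integer(params$ext_max),
      lig_min = as.integer(params$lig_min), lig_max = as.integer(params$lig_max),
      stride = as.integer(params$stride),
      gc_min = as.numeric(params$gc_min), gc_max = as.numeric(params$gc_max),
      n_per_transcript = as.integer(params$n_per_transcript),
      max_per_transcript = as.integer(params$max_per_transcript),
      junction_bonus = as.numeric(params$junction_bonus))
  }
  structure(panel, class = c("smmip_panel", "data.frame"),
            design_params = dp, under_covered = under)
}

#' Export gap regions as BED
#'
#' Transcript-space BED (0-based half-open) of the gap-fill intervals, the
#' only regions in which variants are observable.
#'
#' @param panel an `smmip_panel`.
#' @param path output BED path.
#' @return `path`, invisibly.
#' @export
panel_to_bed <- function(panel, path) {
  df <- data.frame(panel$transcript_id, panel$gap_start, panel$gap_end,
                   panel$smmip_id, round(1000 * panel$score), "+")
  write.table(df, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

# Reconstruct the contiguous transcript substring an smMIP was designed on:
# ext-arm target + gap + lig-arm target.
smmip_target_seq <- function(smmip_row, transcript) {
  e <- nchar(smmip_row$ext_arm); l <- nchar(smmip_row$lig_arm)
  substr(transcript$sequence, smmip_row$gap_start - e + 1L,
         smmip_row$gap_end + l)
}
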