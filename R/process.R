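.datatable.aware <- TRUE
utils::globalVariables(c(".", "sample_id", "smmip_id", "umi", "J",
                         "gap_obs_1", "gap_obs_2", "qual_obs_1", "qual_obs_2"))

#' Read a paired FASTQ into memory
#'
#' @param r1_path,r2_path FASTQ paths (gzipped or plain); mates must be in
#'   the same order.
#' @return data.frame with `read_id`, `seq1`, `seq2`, `qual1`, `qual2`.
#' @export
read_fastq_pair <- function(r1_path, r2_path) {
  rd <- function(p) {
    x <- Biostrings::readDNAStringSet(p, format = "fastq", with.qualities = TRUE)
    list(id = sub("\\s.*$", "", names(x)), seq = as.character(x),
         qual = as.character(S4Vectors::mcols(x)$qualities))
  }
  a <- rd(r1_path); b <- rd(r2_path)
  if (length(a$seq) != length(b$seq))
    stop("R1 and R2 have different read counts", call. = FALSE)
  data.frame(read_id = a$id, seq1 = a$seq, seq2 = b$seq,
             qual1 = a$qual, qual2 = b$qual, stringsAsFactors = FALSE)
}

#' Demultiplex read pairs by the in-read sample barcode
#'
#' The sample barcode sits at the amplicon's 3' end, so read 2 begins with
#' its reverse complement. Each pair is assigned to the unique sample whose
#' barcode image is within `max_mismatch` of the first bases of read 2, or
#' left unassigned (`NA`). Barcodes must be equal-length and pairwise more
#' than `2 * max_mismatch` apart, otherwise assignment could be ambiguous
#' and the map is rejected.
#'
#' @param reads data.frame from [read_fastq_pair()] (or simulated reads).
#' @param barcodes named character vector: sample_id -> barcode.
#' @param max_mismatch maximum Hamming distance tolerated (default 1).
#' @return `reads` with a `sample_id` column (`NA` = unassigned).
#' @export
demultiplex <- function(reads, barcodes, max_mismatch = 1L) {
  if (is.null(names(barcodes)) || anyDuplicated(names(barcodes)))
    stop("barcodes must be uniquely named by sample", call. = FALSE)
  blen <- unique(nchar(barcodes))
  if (length(blen) != 1L)
    stop("barcodes must all have the same length", call. = FALSE)
  if (length(barcodes) > 1L) {
    for (i in seq_along(barcodes)) for (j in seq_len(i - 1L)) {
      if (hamming(barcodes[i], barcodes[j]) <= 2L * max_mismatch)
        stop(sprintf("barcodes %s and %s are within 2*max_mismatch: ambiguous map",
                     names(barcodes)[i], names(barcodes)[j]), call. = FALSE)
    }
  }
  obs <- substr(reads$seq2, 1L, blen)
  images <- revcomp(barcodes)
  assigned <- rep(NA_character_, nrow(reads))
  exact <- match(obs, images)
  assigned[!is.na(exact)] <- names(barcodes)[exact[!is.na(exact)]]
  if (max_mismatch > 0L) {
    todo <- which(is.na(assigned))
    if (length(todo)) {
      d <- vapply(images, function(img) hamming_to(obs[todo], img),
                  integer(length(todo)))
      d <- matrix(d, nrow = length(todo))
      ok <- which(apply(d, 1L, min) <= max_mismatch)
      assigned[todo[ok]] <- names(barcodes)[apply(
        d[ok, , drop = FALSE], 1L, which.min)]
    }
  }
  reads$sample_id <- assigned
  reads
}

# Read-2 layout offsets for a given barcode length: the UMI image occupies
# blen+41 .. blen+48, the ligation-arm image starts at blen+49.
.read2_umi_start <- function(blen) blen + nchar(SMMIP_BACKBONE) + 1L
.read2_lig_start <- function(blen) blen + nchar(SMMIP_BACKBONE) + UMI_LENGTH + 1L

#' Assign read pairs to smMIPs by positional arm matching
#'
#' A pair belongs to an smMIP when both arm images sit at their expected,
#' fixed read positions: the extension-arm target at the start of read 1 and
#' the ligation arm right after the barcode/backbone/UMI images in read 2,
#' each within `max_arm_mismatch` substitutions. If two smMIPs match equally
#' well the pair is left unassigned (tie rule); unmatched pairs are data,
#' not errors.
#'
#' @param reads demultiplexed data.frame (see [demultiplex()]).
#' @param panel an `smmip_panel`.
#' @param max_arm_mismatch per-arm Hamming tolerance (default 1).
#' @param barcode_length barcode length used in the read-2 layout (default 8).
#' @return `reads` with an `smmip_id` column (`NA` = unassigned).
#' @export
match_smmip <- function(reads, panel, max_arm_mismatch = 1L,
                        barcode_length = 8L) {
  n <- nrow(reads)
  assigned <- rep(NA_character_, n)
  if (n == 0L) { reads$smmip_id <- assigned; return(reads) }
  lig_start <- .read2_lig_start(barcode_length)
  ext_targets <- revcomp(panel$ext_arm)
  e_len <- nchar(ext_targets); l_len <- nchar(panel$lig_arm)
  key_panel <- paste0(ext_targets, "|", panel$lig_arm)

  # fast path: exact arm images, grouped by distinct (ext_len, lig_len)
  combos <- unique(data.frame(e = e_len, l = l_len))
  hits <- vector("list", nrow(combos))
  for (k in seq_len(nrow(combos))) {
    sel <- which(e_len == combos$e[k] & l_len == combos$l[k])
    keys <- paste0(substr(reads$seq1, 1L, combos$e[k]), "|",
                   substr(reads$seq2, lig_start, lig_start + combos$l[k] - 1L))
    hits[[k]] <- sel[match(keys, key_panel[sel])]
  }
  hitmat <- do.call(cbind, hits)
  n_hit <- rowSums(!is.na(hitmat))
  uniq <- which(n_hit == 1L)
  idx <- hitmat[cbind(uniq, max.col(!is.na(hitmat[uniq, , drop = FALSE])))]
  # exact-duplicate panel keys are intrinsic ties
  dup_keys <- key_panel[duplicated(key_panel)]
  ok <- !(key_panel[idx] %in% dup_keys)
  assigned[uniq[ok]] <- panel$smmip_id[idx[ok]]
  # n_hit > 1 means two smMIPs with different arm lengths both match exactly:
  # an exact tie, leave unassigned

  # slow path: reads with no exact hit, scanned against the whole panel
  todo <- which(n_hit == 0L)
  if (length(todo) && max_arm_mismatch > 0L) {
    ext_int <- lapply(ext_targets, utf8ToInt)
    lig_int <- lapply(panel$lig_arm, utf8ToInt)
    max_e <- max(e_len); max_l <- max(l_len)
    for (i in todo) {
      r1 <- utf8ToInt(substr(reads$seq1[i], 1L, max_e))
      r2 <- utf8ToInt(substr(reads$seq2[i], lig_start,
                             lig_start + max_l - 1L))
      best <- Inf; best_s <- NA_integer_; tie <- FALSE
      for (s in seq_len(nrow(panel))) {
        d1 <- sum(r1[seq_len(e_len[s])] != ext_int[[s]])
        if (d1 > max_arm_mismatch) next
        d2 <- sum(r2[seq_len(l_len[s])] != lig_int[[s]])
        if (d2 > max_arm_mismatch) next
        d <- d1 + d2
        if (d < best) { best <- d; best_s <- s; tie <- FALSE }
        else if (d == best) tie <- TRUE
      }
      if (!is.na(best_s) && !tie) assigned[i] <- panel$smmip_id[best_s]
    }
  }
  reads$smmip_id <- assigned
  reads
}

#' Extract UMI and per-mate gap observations from assigned read pairs
#'
#' For each assigned pair, pulls the 8-nt UMI image out of read 2, the full
#' gap observation out of read 1 and the 3'-side gap observation out of
#' read 2 (read 2 also carries the barcode, backbone and UMI images, so it
#' reaches only the last `95 - lig_len` nt of the gap). Spiked template
#' deletions shorten the gap; the deletion size is inferred per pair from
#' the position of the ligation-arm image in read 1.
#'
#' @param reads data.frame with `smmip_id` assignments (see [match_smmip()]).
#' @param panel an `smmip_panel`.
#' @param barcode_length barcode length in the read-2 layout.
#' @param max_deletion largest template deletion considered (default 20 nt).
#' @return assigned subset of `reads` with columns `umi`, `gap_obs_1`,
#'   `gap_obs_2`, `qual_obs_1`, `qual_obs_2`.
#' @export
extract_observations <- function(reads, panel, barcode_length = 8L,
                                 max_deletion = 20L) {
  keep <- !is.na(reads$smmip_id)
  out <- reads[keep, , drop = FALSE]
  if (!nrow(out)) {
    out$umi <- character(0); out$gap_obs_1 <- character(0)
    out$gap_obs_2 <- character(0); out$qual_obs_1 <- character(0)
    out$qual_obs_2 <- character(0)
    return(out)
  }
  umi_start <- .read2_umi_start(barcode_length)
  lig_start <- .read2_lig_start(barcode_length)
  pidx <- match(out$smmip_id, panel$smmip_id)
  e <- nchar(panel$ext_arm)[pidx]; l <- nchar(panel$lig_arm)[pidx]
  lig_target <- revcomp(panel$lig_arm)[pidx]
  out$umi <- revcomp(substr(out$seq2, umi_start, umi_start + UMI_LENGTH - 1L))
  # infer template deletion size from the ligation-arm image in read 1
  d <- integer(nrow(out))
  for (i in seq_len(nrow(out))) {
    di <- 0L
    for (cand in 0:max_deletion) {
      pos <- e[i] + GAP_LENGTH - cand + 1L
      vis <- min(l[i], READ_LENGTH - pos + 1L)
      if (vis < 5L) next
      if (hamming(substr(out$seq1[i], pos, pos + vis - 1L),
                  substr(lig_target[i], 1L, vis)) <= 1L) { di <- cand; break }
    }
    d[i] <- di
  }
  out$gap_obs_1 <- substr(out$seq1, e + 1L, e + GAP_LENGTH - d)
  out$qual_obs_1 <- substr(out$qual1, e + 1L, e + GAP_LENGTH - d)
  g2 <- revcomp(substring(out$seq2, lig_start + l, READ_LENGTH))
  q2 <- vapply(substring(out$qual2, lig_start + l, READ_LENGTH),
               function(q) paste(rev(strsplit(q, "", fixed = TRUE)[[1L]]),
                                 collapse = ""), character(1L),
               USE.NAMES = FALSE)
  out$gap_obs_2 <- g2
  out$qual_obs_2 <- q2
  out
}

# Majority-vote consensus over equal-length strings; ties broken by summed
# base quality (Phred+33), remaining ties by alphabetical base. Only
# discordant positions are voted on.
.consensus <- function(seqs, quals) {
  if (length(seqs) == 1L) return(seqs)
  if (all(seqs == seqs[1L])) return(seqs[1L])
  m <- do.call(rbind, strsplit(seqs, "", fixed = TRUE))
  disc <- which(vapply(seq_len(ncol(m)),
                       function(j) any(m[, j] != m[1L, j]), logical(1L)))
  out <- strsplit(seqs[1L], "", fixed = TRUE)[[1L]]
  q <- do.call(rbind, strsplit(quals, "", fixed = TRUE))
  lvls <- sort(unique(as.vector(m[, disc])))
  for (j in disc) {
    col <- m[, j]
    code <- match(col, lvls)
    votes <- tabulate(code, length(lvls))
    top <- lvls[votes == max(votes)]
    if (length(top) > 1L) {
      qs <- vapply(top, function(b)
        sum(utf8ToInt(paste(q[col == b, j], collapse = ""))), 0)
      top <- sort(top[qs == max(qs)])
    }
    out[j] <- top[1L]
  }
  paste(out, collapse = "")
}

#' Collapse PCR duplicates into unique reads by UMI
#'
#' Groups assigned read pairs by (sample, smMIP, UMI): every group is one
#' captured molecule, its PCR amplicates reduced to a single unique read.
#' Per-mate consensus is taken by per-position majority vote (ties by summed
#' base quality, then alphabetical base) among observations of the modal
#' length; the reported `consensus_gap` additionally pools mate-2 votes over
#' the 3' region both mates cover. Singletons pass; no minimum family size
#' is applied.
#'
#' @param assigned data.frame from [extract_observations()] (columns
#'   `sample_id`, `smmip_id`, `umi`, `gap_obs_1`, `gap_obs_2`,
#'   `qual_obs_1`, `qual_obs_2`).
#' @return `unique_observations` data.frame: one row per (sample, smMIP,
#'   UMI) with per-mate consensus observations and `n_read_pairs`.
#' @export
collapse_umis <- function(assigned) {
  need <- c("sample_id", "smmip_id", "umi", "gap_obs_1", "gap_obs_2",
            "qual_obs_1", "qual_obs_2")
  if (!all(need %in% names(assigned)))
    stop("collapse_umis() needs columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  dt <- data.table::as.data.table(assigned[, need])
  one_mate <- function(ss, qq) {
    lens <- nchar(ss)
    tab <- table(lens)
    modal <- as.integer(names(tab)[tab == max(tab)])[1L]
    keep <- lens == modal
    .consensus(ss[keep], qq[keep])
  }
  res <- dt[, {
    g1 <- one_mate(gap_obs_1, qual_obs_1)
    g2 <- one_mate(gap_obs_2, qual_obs_2)
    # pooled consensus: overlay mate-2 votes on the shared 3' region
    pooled <- g1
    off <- nchar(g1) - nchar(g2)
    if (off >= 0L && nchar(g2) > 0L) {
      seqs <- c(gap_obs_1[nchar(gap_obs_1) == nchar(g1)],
                paste0(substr(g1, 1L, off),
                       gap_obs_2[nchar(gap_obs_2) == nchar(g2)]))
      quals <- c(qual_obs_1[nchar(gap_obs_1) == nchar(g1)],
                 paste0(substr(qual_obs_1[1L], 1L, off),
                        qual_obs_2[nchar(gap_obs_2) == nchar(g2)]))
      pooled <- .consensus(seqs, quals)
    }
    list(gap_obs_1 = g1, gap_obs_2 = g2, consensus_gap = pooled,
         qual_obs_1 = strrep(PHRED_CHAR, nchar(g1)),
         qual_obs_2 = strrep(PHRED_CHAR, nchar(g2)),
         n_read_pairs = .N)
  }, by = .(sample_id, smmip_id, umi)]
  out <- as.data.frame(res)
  class(out) <- c("unique_observations", "data.frame")
  out
}

#' Unique-read count table
#'
#' Raw unique-molecule counts per smMIP per sample, with zero rows for
#' smMIPs without observations; column sums equal per-sample unique totals.
#'
#' @param observations a `unique_observations` data.frame.
#' @param panel an `smmip_panel`.
#' @param samples sample ids fixing the column set (default: those present).
#' @return integer matrix, rows = panel smMIPs, columns = samples.
#' @export
count_table <- function(observations, panel, samples = NULL) {
  unknown <- setdiff(unique(observations$smmip_id), panel$smmip_id)
  if (length(unknown))
    stop("observations reference unknown smMIP(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  if (is.null(samples)) samples <- sort(unique(observations$sample_id))
  counts <- matrix(0L, nrow = nrow(panel), ncol = length(samples),
                   dimnames = list(panel$smmip_id, samples))
  if (nrow(observations)) {
    tab <- table(factor(observations$smmip_id, levels = panel$smmip_id),
                 factor(observations$sample_id, levels = samples))
    counts[] <- as.integer(tab)
  }
  counts
}

#' Full FASTQ-to-counts processing
#'
#' Demultiplexes, arm-matches, extracts UMIs and gap observations, collapses
#' PCR duplicates and tabulates unique counts, with assignment statistics.
#'
#' @param r1_path,r2_path paired FASTQ paths.
#' @param panel an `smmip_panel`.
#' @param barcodes named character vector: sample_id -> barcode.
#' @param max_mismatch barcode Hamming tolerance.
#' @param max_arm_mismatch per-arm Hamming tolerance.
#' @return list: `observations`, `counts`, `stats` (read-pair accounting).
#' @export
process_fastq <- function(r1_path, r2_path, panel, barcodes,
                          max_mismatch = 1L, max_arm_mismatch = 1L) {
  reads <- read_fastq_pair(r1_path, r2_path)
  reads <- demultiplex(reads, barcodes, max_mismatch)
  blen <- unique(nchar(barcodes))
  reads <- match_smmip(reads, panel, max_arm_mismatch, barcode_length = blen)
  n_total <- nrow(reads)
  n_demux <- sum(!is.na(reads$sample_id))
  reads <- reads[!is.na(reads$sample_id), , drop = FALSE]
  obs_reads <- extract_observations(reads, panel, barcode_length = blen)
  observations <- collapse_umis(obs_reads)
  counts <- count_table(observations, panel, samples = names(barcodes))
  stats <- data.frame(
    read_pairs = n_total, demultiplexed = n_demux,
    smmip_assigned = nrow(obs_reads), unique_reads = nrow(observations))
  list(observations = observations, counts = counts, stats = stats)
}

#' Write / read unique observations as TSV
#' @param observations a `unique_observations` data.frame.
#' @param path TSV path.
#' @return `path` (write) or the observations (read).
#' @export
write_observations <- function(observations, path) {
  write.table(observations, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_observations
#' @export
read_observations <- function(path) {
  out <- read.delim(path, stringsAsFactors = FALSE,
                    colClasses = c(umi = "character"))
  class(out) <- c("unique_observations", "data.frame")
  out
}
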