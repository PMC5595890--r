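PILEUP_SYMBOLS <- c("A", "C", "G", "T", "-")

.aa3_table <- c(A = "Ala", R = "Arg", N = "Asn", D = "Asp", C = "Cys",
                Q = "Gln", E = "Glu", G = "Gly", H = "His", I = "Ile",
                L = "Leu", K = "Lys", M = "Met", F = "Phe", P = "Pro",
                S = "Ser", T = "Thr", W = "Trp", Y = "Tyr", V = "Val",
                `*` = "*", X = "Xaa")

aa3 <- function(code1) unname(.aa3_table[code1])

# Translate a nucleotide string codon by codon (trailing partial codon
# dropped); codons with non-ACGT characters give X.
translate_nt <- function(nt) {
  n <- nchar(nt) %/% 3L
  if (n == 0L) return(character(0))
  codons <- substring(nt, 3L * seq_len(n) - 2L, 3L * seq_len(n))
  aa <- Biostrings::GENETIC_CODE[codons]
  aa[is.na(aa)] <- "X"
  unname(aa)
}

# Shift a deletion interval [start0, start0 + d) (0-based transcript
# coordinates) as far 3' as the sequence allows (HGVS convention).
.shift3 <- function(seqn, start0, d) {
  len <- nchar(seqn)
  while (start0 + d < len &&
         substr(seqn, start0 + 1L, start0 + 1L) ==
         substr(seqn, start0 + d + 1L, start0 + d + 1L)) {
    start0 <- start0 + 1L
  }
  start0
}

#' Build a transcript-space pileup from unique observations
#'
#' Every unique read contributes at most one forward (mate 1) and one
#' reverse (mate 2) observation per transcript position of its gap; mate 2
#' reaches only the 3' part of the gap (the read also carries barcode,
#' backbone and UMI images). Positions covered by overlapping smMIPs
#' accumulate observations from all of them, pooled without per-smMIP
#' splitting. Template deletions (consensus shorter than 112 nt) are located
#' by maximal-prefix comparison against the reference gap, normalised to
#' their 3'-most transcript placement, recorded per position as `-` and
#' collected as deletion events.
#'
#' @param observations a `unique_observations` data.frame.
#' @param panel an `smmip_panel`.
#' @param transcripts named list of [transcript_model()] objects.
#' @return object of class `smmip_pileup`: per transcript a list with
#'   forward/reverse position x symbol count matrices and the reference
#'   base vector, plus a `deletions` event table.
#' @export
build_pileup <- function(observations, panel, transcripts) {
  unknown <- setdiff(unique(observations$smmip_id), panel$smmip_id)
  if (length(unknown))
    stop("observations reference unknown smMIP(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  by_tr <- list()
  events <- list()
  pidx <- match(observations$smmip_id, panel$smmip_id)
  for (tid in unique(panel$transcript_id[pidx])) {
    tr <- transcripts[[tid]]
    if (is.null(tr)) stop("pileup references unknown transcript: ", tid,
                          call. = FALSE)
    len <- nchar(tr$sequence)
    fwd <- matrix(0L, len, length(PILEUP_SYMBOLS),
                  dimnames = list(NULL, PILEUP_SYMBOLS))
    rev_ <- fwd
    smmips <- panel[panel$transcript_id == tid, , drop = FALSE]
    for (s in seq_len(nrow(smmips))) {
      row <- smmips[s, ]
      obs <- observations[observations$smmip_id == row$smmip_id, , drop = FALSE]
      if (!nrow(obs)) next
      gap_ref <- substr(tr$sequence, row$gap_start + 1L, row$gap_end)
      grp <- data.table::as.data.table(obs)[, .N, by = .(gap_obs_1, gap_obs_2)]
      for (k in seq_len(nrow(grp))) {
        g1 <- grp$gap_obs_1[k]; g2 <- grp$gap_obs_2[k]; cnt <- grp$N[k]
        len1 <- nchar(g1); len2 <- nchar(g2)
        d <- GAP_LENGTH - len1
        if (d < 0L || len2 > len1) next  # malformed observation, skip
        start2 <- len1 - len2 + 1L       # first gap position mate 2 covers
        if (d == 0L) {
          b1 <- match(strsplit(g1, "", fixed = TRUE)[[1L]], PILEUP_SYMBOLS)
          pos <- row$gap_start + seq_len(GAP_LENGTH)  # 1-based transcript
          ok <- !is.na(b1)
          fwd[cbind(pos[ok], b1[ok])] <- fwd[cbind(pos[ok], b1[ok])] + cnt
          if (len2 > 0L) {
            b2 <- match(strsplit(g2, "", fixed = TRUE)[[1L]], PILEUP_SYMBOLS)
            pos2 <- row$gap_start + start2 - 1L + seq_len(len2)
            ok2 <- !is.na(b2)
            rev_[cbind(pos2[ok2], b2[ok2])] <-
              rev_[cbind(pos2[ok2], b2[ok2])] + cnt
          }
        } else {
          p_raw <- min(common_prefix_len(g1, gap_ref), len1)
          del0 <- .shift3(tr$sequence, row$gap_start + p_raw, d)
          p <- del0 - row$gap_start          # local prefix length after shift
          if (p > len1) p <- len1
          # mate 1: bases before, '-' across, shifted bases after
          loc <- seq_len(len1)
          ref_loc <- ifelse(loc <= p, loc, loc + d)
          b1 <- match(strsplit(g1, "", fixed = TRUE)[[1L]], PILEUP_SYMBOLS)
          ok <- !is.na(b1) & ref_loc <= GAP_LENGTH
          pos <- row$gap_start + ref_loc
          fwd[cbind(pos[ok], b1[ok])] <- fwd[cbind(pos[ok], b1[ok])] + cnt
          delpos <- row$gap_start + p + seq_len(d)
          delpos <- delpos[delpos <= row$gap_end]
          fwd[delpos, "-"] <- fwd[delpos, "-"] + cnt
          mate2_sees <- len2 > 0L && start2 <= p
          if (len2 > 0L) {
            loc2 <- start2 - 1L + seq_len(len2)
            ref_loc2 <- ifelse(loc2 <= p, loc2, loc2 + d)
            b2 <- match(strsplit(g2, "", fixed = TRUE)[[1L]], PILEUP_SYMBOLS)
            ok2 <- !is.na(b2) & ref_loc2 <= GAP_LENGTH
            pos2 <- row$gap_start + ref_loc2
            rev_[cbind(pos2[ok2], b2[ok2])] <-
              rev_[cbind(pos2[ok2], b2[ok2])] + cnt
            if (mate2_sees) rev_[delpos, "-"] <- rev_[delpos, "-"] + cnt
          }
          events[[length(events) + 1L]] <- data.frame(
            transcript_id = tid, position = del0,
            ref = substr(tr$sequence, del0 + 1L, del0 + d),
            fwd = cnt, rev = if (mate2_sees) cnt else 0L,
            stringsAsFactors = FALSE)
        }
      }
    }
    by_tr[[tid]] <- list(fwd = fwd, rev = rev_,
                         ref = strsplit(tr$sequence, "", fixed = TRUE)[[1L]])
  }
  dels <- if (length(events)) {
    ev <- do.call(rbind, events)
    ev <- stats::aggregate(cbind(fwd, rev) ~ transcript_id + position + ref,
                           data = ev, FUN = sum)
    ev[order(ev$transcript_id, ev$position), , drop = FALSE]
  } else {
    data.frame(transcript_id = character(0), position = integer(0),
               ref = character(0), fwd = integer(0), rev = integer(0))
  }
  structure(list(transcripts = by_tr, deletions = dels),
            class = "smmip_pileup")
}

.empty_calls <- function() {
  data.frame(transcript_id = character(0), position = integer(0),
             ref = character(0), alt = character(0), vaf = numeric(0),
             support_total = integer(0), support_fwd = integer(0),
             support_rev = integer(0), filter = character(0),
             stringsAsFactors = FALSE)
}

#' Call variants from a pileup
#'
#' Emits every non-reference allele passing the unique-read filter: variant
#' allele fraction at least `min_vaf` (default 5%) over at least
#' `min_support` unique-read observations (default 5) with both orientations
#' represented (at least one forward and one reverse observation; set
#' `strict_orientation` to demand `min_support` in each orientation).
#' Sub-threshold alleles with VAF at least `min_vaf / 2` are emitted with a
#' fail reason for audit; weaker signals are dropped. The VAF denominator is
#' the orientation-split observation count at the position: each unique
#' molecule contributes up to two observations (one per mate).
#'
#' @param pileup an `smmip_pileup` from [build_pileup()].
#' @param min_vaf minimum variant allele fraction (default 0.05).
#' @param min_support minimum total unique-read observations (default 5).
#' @param strict_orientation require `min_support` per orientation.
#' @return `variant_calls` data.frame; `position` is the 0-based transcript
#'   coordinate, `alt = ""` marks a deletion of `nchar(ref)` nt.
#' @export
call_variants <- function(pileup, min_vaf = 0.05, min_support = 5L,
                          strict_orientation = FALSE) {
  stopifnot(inherits(pileup, "smmip_pileup"))
  out <- list()
  status <- function(vaf, total, f, r) {
    fails <- character(0)
    if (vaf < min_vaf) fails <- c(fails, "low_vaf")
    if (strict_orientation) {
      if (f < min_support || r < min_support)
        fails <- c(fails, "orientation_support")
    } else {
      if (total < min_support) fails <- c(fails, "low_support")
      if (f < 1L || r < 1L) fails <- c(fails, "orientation")
    }
    if (length(fails)) paste(fails, collapse = ";") else "PASS"
  }
  for (tid in names(pileup$transcripts)) {
    pl <- pileup$transcripts[[tid]]
    tot_f <- rowSums(pl$fwd); tot_r <- rowSums(pl$rev)
    total <- tot_f + tot_r
    for (pos in which(total > 0L)) {
      refb <- pl$ref[pos]
      for (b in setdiff(PILEUP_SYMBOLS, c(refb, "-"))) {
        f <- pl$fwd[pos, b]; r <- pl$rev[pos, b]
        if (f + r == 0L) next
        vaf <- (f + r) / total[pos]
        st <- status(vaf, f + r, f, r)
        if (st != "PASS" && vaf < min_vaf / 2) next
        out[[length(out) + 1L]] <- data.frame(
          transcript_id = tid, position = pos - 1L, ref = refb, alt = b,
          vaf = vaf, support_total = as.integer(f + r),
          support_fwd = as.integer(f), support_rev = as.integer(r),
          filter = st, stringsAsFactors = FALSE)
      }
    }
  }
  dels <- pileup$deletions
  for (i in seq_len(nrow(dels))) {
    tid <- dels$transcript_id[i]
    pl <- pileup$transcripts[[tid]]
    pos <- dels$position[i] + 1L
    denom <- sum(pl$fwd[pos, ]) + sum(pl$rev[pos, ])
    f <- dels$fwd[i]; r <- dels$rev[i]
    vaf <- (f + r) / denom
    st <- status(vaf, f + r, f, r)
    if (st != "PASS" && vaf < min_vaf / 2) next
    out[[length(out) + 1L]] <- data.frame(
      transcript_id = tid, position = dels$position[i], ref = dels$ref[i],
      alt = "", vaf = vaf, support_total = as.integer(f + r),
      support_fwd = as.integer(f), support_rev = as.integer(r),
      filter = st, stringsAsFactors = FALSE)
  }
  calls <- if (length(out)) do.call(rbind, out) else .empty_calls()
  calls <- calls[order(calls$transcript_id, calls$position), , drop = FALSE]
  rownames(calls) <- NULL
  class(calls) <- c("variant_calls", "data.frame")
  calls
}

# Translate the alternate reading frame after a frameshifting deletion and
# diff it against the reference frame. Returns the HGVS p. string and class.
.frameshift_consequence <- function(transcript, cp1, cp2) {
  cds <- cds_seq(transcript)
  utr3 <- substring(transcript$sequence, transcript$cds_end + 1L)
  n0 <- (cp1 - 1L) %/% 3L + 1L
  tail_ref <- substring(cds, 3L * (n0 - 1L) + 1L)
  tail_alt_nt <- paste0(substring(cds, 3L * (n0 - 1L) + 1L, cp1 - 1L),
                        substring(cds, cp2 + 1L), utr3)
  p_ref <- translate_nt(tail_ref)
  p_alt <- translate_nt(tail_alt_nt)
  stop_at <- which(p_alt == "*")
  if (length(stop_at)) p_alt <- p_alt[seq_len(stop_at[1L])]
  n_cmp <- min(length(p_ref), length(p_alt))
  diff <- which(p_ref[seq_len(n_cmp)] != p_alt[seq_len(n_cmp)])
  i_local <- if (length(diff)) diff[1L] else n_cmp + 1L
  if (i_local > length(p_alt)) i_local <- length(p_alt)  # degenerate
  i_abs <- n0 - 1L + i_local
  ref_aa <- p_ref[i_local]; alt_aa <- p_alt[i_local]
  if (i_abs == 1L && ref_aa == "M")
    return(list(hgvs_p = "p.Met1?", classification = "frameshift"))
  if (!is.na(alt_aa) && alt_aa == "*") {
    return(list(hgvs_p = sprintf("p.%s%d*", aa3(ref_aa), i_abs),
                classification = "nonsense"))
  }
  if (!length(stop_at)) {
    return(list(hgvs_p = sprintf("p.%s%d%sfs*?", aa3(ref_aa), i_abs,
                                 aa3(alt_aa)),
                classification = "frameshift"))
  }
  k <- stop_at[1L] - i_local + 1L
  list(hgvs_p = sprintf("p.%s%d%sfs*%d", aa3(ref_aa), i_abs, aa3(alt_aa), k),
       classification = "frameshift")
}

# In-frame deletion consequence via residue-level prefix/suffix trimming.
.inframe_consequence <- function(transcript, cp1, cp2) {
  cds <- cds_seq(transcript)
  alt_cds <- paste0(substring(cds, 1L, cp1 - 1L), substring(cds, cp2 + 1L))
  p_ref <- translate_nt(cds)
  p_alt <- translate_nt(alt_cds)
  stop_at <- which(p_alt == "*")
  if (length(stop_at)) p_alt <- p_alt[seq_len(stop_at[1L])]
  a <- 0L
  while (a < length(p_alt) && p_ref[a + 1L] == p_alt[a + 1L]) a <- a + 1L
  if (a == 0L && p_ref[1L] == "M")
    return(list(hgvs_p = "p.Met1?", classification = "inframe_deletion"))
  if (a < length(p_alt) && p_alt[a + 1L] == "*" && p_ref[a + 1L] != "*") {
    # the junction codon of the deletion spells a new stop
    return(list(hgvs_p = sprintf("p.%s%d*", aa3(p_ref[a + 1L]), a + 1L),
                classification = "nonsense"))
  }
  b <- 0L
  while (b < length(p_alt) - a &&
         p_ref[length(p_ref) - b] == p_alt[length(p_alt) - b]) b <- b + 1L
  i <- a + 1L
  j <- length(p_ref) - b
  ins <- if (length(p_alt) - b >= i) p_alt[i:(length(p_alt) - b)] else character(0)
  hg <- if (!length(ins)) {
    if (i == j) sprintf("p.%s%ddel", aa3(p_ref[i]), i)
    else sprintf("p.%s%d_%s%ddel", aa3(p_ref[i]), i, aa3(p_ref[j]), j)
  } else {
    sprintf("p.%s%d_%s%ddelins%s", aa3(p_ref[i]), i, aa3(p_ref[j]), j,
            paste(aa3(ins), collapse = ""))
  }
  list(hgvs_p = hg, classification = "inframe_deletion")
}

#' Annotate a variant call with HGVS coding consequences
#'
#' Maps a transcript-space call into c. numbering and derives the protein
#' consequence: SNVs by codon substitution under the standard genetic code
#' (synonymous `p.(=)`, missense `p.Xaa{n}Yaa`, stop gain `p.Xaa{n}*`,
#' stop loss `p.*{n}Yaaext*{k}`); deletions of length not divisible by 3 by
#' translating the shifted frame to its first new stop
#' (`p.Xaa{n}Yaafs*{k}`, or `fs*?` when translation runs off the transcript
#' without a stop); in-frame deletions as `p...del`/`p...delins`. Variants
#' not fully inside the CDS are annotated in n. notation with no
#' classification.
#'
#' @param call one-row slice of a `variant_calls` data.frame (or an
#'   equivalent list with `position`, `ref`, `alt`).
#' @param transcript the [transcript_model()] the call lives on.
#' @return `call` with `hgvs_c`, `hgvs_p`, `classification` filled in.
#' @export
annotate_variant <- function(call, transcript) {
  pos0 <- call$position
  is_del <- call$alt == ""
  d <- if (is_del) nchar(call$ref) else 1L
  in_cds <- pos0 >= transcript$cds_start && pos0 + d <= transcript$cds_end
  if (!in_cds) {
    call$hgvs_c <- if (is_del) {
      if (d == 1L) sprintf("n.%ddel%s", pos0 + 1L, call$ref)
      else sprintf("n.%d_%ddel%s", pos0 + 1L, pos0 + d, call$ref)
    } else sprintf("n.%d%s>%s", pos0 + 1L, call$ref, call$alt)
    call$hgvs_p <- NA_character_
    call$classification <- NA_character_
    return(call)
  }
  cp <- pos0 - transcript$cds_start + 1L
  cds <- cds_seq(transcript)
  if (!is_del) {
    call$hgvs_c <- sprintf("c.%d%s>%s", cp, call$ref, call$alt)
    ci <- (cp - 1L) %/% 3L + 1L
    off <- (cp - 1L) %% 3L + 1L
    codon <- substring(cds, 3L * ci - 2L, 3L * ci)
    mut <- codon
    substr(mut, off, off) <- call$alt
    ref_aa <- translate_nt(codon); alt_aa <- translate_nt(mut)
    if (ci == 1L && ref_aa == "M" && alt_aa != ref_aa) {
      # initiation-codon change: downstream effect unknowable from sequence
      call$hgvs_p <- "p.Met1?"; call$classification <- "missense"
      return(call)
    }
    if (ref_aa == alt_aa) {
      call$hgvs_p <- "p.(=)"; call$classification <- "synonymous"
    } else if (alt_aa == "*") {
      call$hgvs_p <- sprintf("p.%s%d*", aa3(ref_aa), ci)
      call$classification <- "nonsense"
    } else if (ref_aa == "*") {
      # stop loss: translation extends into the 3' UTR to the next stop
      utr3 <- substring(transcript$sequence, transcript$cds_end + 1L)
      ext <- translate_nt(paste0(mut, utr3))
      stop_at <- which(ext == "*")
      k <- if (length(stop_at)) stop_at[1L] else NA_integer_
      call$hgvs_p <- if (is.na(k))
        sprintf("p.*%d%sext*?", ci, aa3(alt_aa))
      else sprintf("p.*%d%sext*%d", ci, aa3(alt_aa), k - 1L)
      call$classification <- "missense"
    } else {
      call$hgvs_p <- sprintf("p.%s%d%s", aa3(ref_aa), ci, aa3(alt_aa))
      call$classification <- "missense"
    }
    return(call)
  }
  cp2 <- cp + d - 1L
  call$hgvs_c <- if (d == 1L) sprintf("c.%ddel%s", cp, call$ref)
                 else sprintf("c.%d_%ddel%s", cp, cp2, call$ref)
  cons <- if (d %% 3L == 0L) .inframe_consequence(transcript, cp, cp2)
          else .frameshift_consequence(transcript, cp, cp2)
  call$hgvs_p <- cons$hgvs_p
  call$classification <- cons$classification
  call
}

#' Annotate every call in a table
#'
#' @param calls a `variant_calls` data.frame.
#' @param transcripts named list of [transcript_model()] objects.
#' @return `calls` with `hgvs_c`, `hgvs_p`, `classification` columns.
#' @export
annotate_variants <- function(calls, transcripts) {
  if (!nrow(calls)) {
    calls$hgvs_c <- character(0); calls$hgvs_p <- character(0)
    calls$classification <- character(0)
    return(calls)
  }
  rows <- lapply(seq_len(nrow(calls)), function(i) {
    tr <- transcripts[[calls$transcript_id[i]]]
    if (is.null(tr)) stop("call on unknown transcript: ",
                          calls$transcript_id[i], call. = FALSE)
    annotate_variant(calls[i, , drop = FALSE], tr)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("variant_calls", "data.frame")
  out
}

#' Write a variant report and a minimal transcript-space VCF
#'
#' The report TSV has one row per call: gene, nucleotide change, coverage
#' formatted as `vaf% (total) [fwd / rev]`, amino-acid change,
#' c. and p. HGVS, classification and filter status. The optional VCF-like
#' export uses transcript ids as sequence names and 1-based transcript
#' coordinates; its header documents that the coordinates are not genomic.
#'
#' @param calls annotated `variant_calls`.
#' @param path report TSV path.
#' @param transcripts named list of [transcript_model()] (for gene symbols).
#' @param vcf_path optional path of the VCF-like export.
#' @return `path`, invisibly.
#' @export
write_variant_report <- function(calls, path, transcripts = NULL,
                                 vcf_path = NULL) {
  gene <- if (!is.null(transcripts)) {
    vapply(calls$transcript_id, function(tid) {
      tr <- transcripts[[tid]]
      if (is.null(tr)) NA_character_ else tr$gene_symbol
    }, character(1L), USE.NAMES = FALSE)
  } else rep(NA_character_, nrow(calls))
  nuc <- ifelse(calls$alt == "",
                sprintf("del%s", calls$ref),
                sprintf("%s>%s", calls$ref, calls$alt))
  cov <- sprintf("%d%% (%d) [%d / %d]", round(100 * calls$vaf),
                 calls$support_total, calls$support_fwd, calls$support_rev)
  aa <- if ("hgvs_p" %in% names(calls)) sub("^p\\.", "", calls$hgvs_p)
        else rep(NA_character_, nrow(calls))
  rep_df <- data.frame(
    gene = gene, transcript_id = calls$transcript_id, nuc_change = nuc,
    coverage = cov, aa_change = aa,
    hgvs_c = calls$hgvs_c %||% NA_character_,
    hgvs_p = calls$hgvs_p %||% NA_character_,
    classification = calls$classification %||% NA_character_,
    filter = calls$filter, stringsAsFactors = FALSE)
  write.table(rep_df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(vcf_path)) write_variant_vcf(calls, vcf_path, transcripts)
  invisible(path)
}

#' @rdname write_variant_report
#' @export
write_variant_vcf <- function(calls, vcf_path, transcripts = NULL) {
  con <- file(vcf_path, "w")
  on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##source=smmipseq",
    "##coordinates=transcript-space (spliced mRNA), not genomic",
    "##INFO=<ID=DP,Number=1,Type=Integer,Description=\"Unique-read observations\">",
    "##INFO=<ID=VAF,Number=1,Type=Float,Description=\"Variant allele fraction\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO"), con)
  for (i in seq_len(nrow(calls))) {
    c_i <- calls[i, ]
    if (c_i$alt == "") {
      # anchored deletion representation
      if (c_i$position < 1L) next
      anchor_pos <- c_i$position  # 0-based position of the base before
      tr <- if (!is.null(transcripts)) transcripts[[c_i$transcript_id]] else NULL
      anchor <- if (!is.null(tr))
        substr(tr$sequence, anchor_pos, anchor_pos) else "N"
      pos <- anchor_pos  # 1-based coordinate of the anchor base
      ref <- paste0(anchor, c_i$ref); alt <- anchor
    } else {
      pos <- c_i$position + 1L; ref <- c_i$ref; alt <- c_i$alt
    }
    writeLines(sprintf("%s\t%d\t.\t%s\t%s\t.\t%s\tDP=%d;VAF=%.4f",
                       c_i$transcript_id, pos, ref, alt, c_i$filter,
                       c_i$support_total, c_i$vaf), con)
  }
  invisible(vcf_path)
}
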