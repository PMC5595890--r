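# Shared fixtures and an in-memory simulate -> process pipeline.

# Attach constant Phred-30 qualities to simulated reads (what the FASTQ
# writer would emit), so processing can run without touching disk.
with_quals <- function(reads) {
  reads$qual1 <- strrep("?", nchar(reads$seq1))
  reads$qual2 <- strrep("?", nchar(reads$seq2))
  reads
}

# Simulate one or more sample plans and push the pooled reads through
# demultiplexing, arm matching, UMI collapse and counting.
run_sim_pipeline <- function(panel, transcripts, plans,
                             error_rate = 0, dup_mean = 0,
                             efficiencies = NULL, sigma = 1.5) {
  if (inherits(plans, "sample_plan")) plans <- list(plans)
  sims <- lapply(plans, function(p)
    simulate_reads(panel, transcripts, p, efficiencies, sigma,
                   error_rate, dup_mean))
  reads <- do.call(rbind, lapply(sims, `[[`, "reads"))
  reads <- with_quals(reads)
  barcodes <- setNames(vapply(plans, `[[`, "", "barcode"),
                       vapply(plans, `[[`, "", "sample_id"))
  blen <- unique(nchar(barcodes))
  reads <- demultiplex(reads, barcodes)
  reads <- match_smmip(reads, panel, barcode_length = blen)
  assigned <- reads[!is.na(reads$sample_id) & !is.na(reads$smmip_id), ,
                    drop = FALSE]
  obs <- collapse_umis(extract_observations(assigned, panel,
                                            barcode_length = blen))
  counts <- count_table(obs, panel, samples = names(barcodes))
  list(sims = sims, reads = reads, observations = obs, counts = counts)
}

# --- independent brute-force translate-and-diff annotation oracle ---------

.aa3_oracle <- c(A = "Ala", R = "Arg", N = "Asn", D = "Asp", C = "Cys",
                 Q = "Gln", E = "Glu", G = "Gly", H = "His", I = "Ile",
                 L = "Leu", K = "Lys", M = "Met", F = "Phe", P = "Pro",
                 S = "Ser", T = "Thr", W = "Trp", Y = "Tyr", V = "Val",
                 `*` = "*", X = "Xaa")

oracle_translate <- function(nt) {
  nt <- substr(nt, 1L, 3L * (nchar(nt) %/% 3L))
  if (nchar(nt) == 0L) return(character(0))
  aa <- strsplit(as.character(suppressWarnings(
    Biostrings::translate(Biostrings::DNAString(nt), no.init.codon = TRUE))),
    "", fixed = TRUE)[[1L]]
  stop_at <- which(aa == "*")
  if (length(stop_at)) aa <- aa[seq_len(stop_at[1L])]
  aa
}

# Rebuild the whole mutated transcript, translate reference and mutant
# coding sequence (reading into the 3' UTR until the first stop), and derive
# the protein consequence from the residue-level diff.
oracle_annotate <- function(transcript, pos0, ref, alt) {
  seqn <- transcript$sequence
  stopifnot(substr(seqn, pos0 + 1L, pos0 + nchar(ref)) == ref)
  mut <- if (alt == "") {
    paste0(substr(seqn, 1L, pos0), substring(seqn, pos0 + nchar(ref) + 1L))
  } else {
    s <- seqn; substr(s, pos0 + 1L, pos0 + 1L) <- alt; s
  }
  p_ref <- oracle_translate(substring(seqn, transcript$cds_start + 1L))
  p_alt <- oracle_translate(substring(mut, transcript$cds_start + 1L))
  if (identical(p_ref, p_alt))
    return(list(hgvs_p = "p.(=)", classification = "synonymous"))
  a <- 0L
  n_cmp <- min(length(p_ref), length(p_alt))
  while (a < n_cmp && p_ref[a + 1L] == p_alt[a + 1L]) a <- a + 1L
  i <- a + 1L
  aa3 <- function(x) unname(.aa3_oracle[x])
  if (i == 1L && p_ref[1L] == "M") {
    # initiation codon disrupted (shared notation convention: p.Met1?)
    cls <- if (alt != "") "missense"
           else if (nchar(ref) %% 3L == 0L) "inframe_deletion"
           else "frameshift"
    return(list(hgvs_p = "p.Met1?", classification = cls))
  }
  if (alt != "") {  # SNV
    if (p_alt[i] == "*")
      return(list(hgvs_p = sprintf("p.%s%d*", aa3(p_ref[i]), i),
                  classification = "nonsense"))
    return(list(hgvs_p = sprintf("p.%s%d%s", aa3(p_ref[i]), i, aa3(p_alt[i])),
                classification = "missense"))
  }
  d <- nchar(ref)
  if (d %% 3L == 0L) {  # in-frame deletion: trim prefix, then suffix
    if (i <= length(p_alt) && p_alt[i] == "*" && p_ref[i] != "*")
      return(list(hgvs_p = sprintf("p.%s%d*", aa3(p_ref[i]), i),
                  classification = "nonsense"))
    b <- 0L
    while (b < length(p_alt) - a &&
           p_ref[length(p_ref) - b] == p_alt[length(p_alt) - b]) b <- b + 1L
    j <- length(p_ref) - b
    ins <- if (length(p_alt) - b >= i) p_alt[i:(length(p_alt) - b)]
           else character(0)
    hg <- if (!length(ins)) {
      if (i == j) sprintf("p.%s%ddel", aa3(p_ref[i]), i)
      else sprintf("p.%s%d_%s%ddel", aa3(p_ref[i]), i, aa3(p_ref[j]), j)
    } else {
      sprintf("p.%s%d_%s%ddelins%s", aa3(p_ref[i]), i, aa3(p_ref[j]), j,
              paste(aa3(ins), collapse = ""))
    }
    return(list(hgvs_p = hg, classification = "inframe_deletion"))
  }
  if (p_alt[i] == "*")
    return(list(hgvs_p = sprintf("p.%s%d*", aa3(p_ref[i]), i),
                classification = "nonsense"))
  if (p_alt[length(p_alt)] != "*")
    return(list(hgvs_p = sprintf("p.%s%d%sfs*?", aa3(p_ref[i]), i,
                                 aa3(p_alt[i])),
                classification = "frameshift"))
  list(hgvs_p = sprintf("p.%s%d%sfs*%d", aa3(p_ref[i]), i, aa3(p_alt[i]),
                        length(p_alt) - i + 1L),
       classification = "frameshift")
}
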