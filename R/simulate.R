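READ_LENGTH <- 151L
PHRED_CHAR <- "?"  # constant Phred 30, Sanger (Phred+33) encoding

#' Define a simulated sample
#'
#' A sample plan fixes everything the simulator needs for one barcoded
#' sample: relative transcript abundances, spiked variants with their allele
#' fractions, the number of captured molecules and the RNG seed.
#'
#' Variants are given in 0-based transcript coordinates; an SNV has
#' single-base `ref`/`alt`, a deletion has the deleted bases (1--20 nt) as
#' `ref` and `alt = ""`. A variant is only observable -- and only simulated --
#' through smMIPs whose gap-fill fully contains it.
#'
#' @param sample_id sample name.
#' @param barcode per-sample barcode appended to the amplicon (8 nt default).
#' @param abundance named non-negative numeric vector of relative transcript
#'   abundances (names = transcript_ids); not all zero.
#' @param n_molecules total captured molecules to distribute over the panel.
#' @param variants data.frame with columns `transcript_id`, `position`,
#'   `ref`, `alt`, `allele_fraction` (fractions in (0,1]).
#' @param seed integer seed driving all of this sample's randomness.
#' @return an object of class `sample_plan`.
#' @export
sample_plan <- function(sample_id, barcode, abundance, n_molecules,
                        variants = NULL, seed = 1L) {
  assert_dna(barcode, "barcode")
  if (is.null(names(abundance)) || any(abundance < 0) || all(abundance == 0))
    stop("abundance must be a named, non-negative, not-all-zero vector",
         call. = FALSE)
  if (is.null(variants)) {
    variants <- data.frame(transcript_id = character(0), position = integer(0),
                           ref = character(0), alt = character(0),
                           allele_fraction = numeric(0))
  }
  if (nrow(variants)) {
    if (any(variants$allele_fraction <= 0 | variants$allele_fraction > 1))
      stop("allele_fraction must be in (0, 1]", call. = FALSE)
    if (any(nchar(variants$ref) < 1L | nchar(variants$ref) > 20L))
      stop("variant ref must be 1-20 nt", call. = FALSE)
    if (any(nchar(variants$ref) > 1L & variants$alt != ""))
      stop("multi-base ref requires alt == \"\" (deletion)", call. = FALSE)
  }
  structure(list(sample_id = sample_id, barcode = barcode,
                 abundance = abundance, n_molecules = as.integer(n_molecules),
                 variants = variants, seed = as.integer(seed)),
            class = "sample_plan")
}

#' Per-smMIP capture efficiencies
#'
#' Capture efficiency of individual smMIPs varies greatly in practice, even
#' between probes on one transcript. The simulator emulates this dispersion
#' with a log-normal model: efficiency ~ LogNormal(0, sigma), drawn once per
#' panel per seed.
#'
#' @param panel an `smmip_panel`.
#' @param sigma log-scale standard deviation (default 1.5).
#' @param seed integer seed; fixed seed gives reproducible efficiencies.
#' @return named positive numeric vector, one entry per smMIP.
#' @export
capture_efficiencies <- function(panel, sigma = 1.5, seed = 1L) {
  with_local_seed(seed,
    setNames(rlnorm(nrow(panel), meanlog = 0, sdlog = sigma), panel$smmip_id))
}

#' Assemble a sequenced amplicon
#'
#' The documented amplicon dialect shared by the simulator and the read
#' processor: `ext_arm_target + gap + lig_arm_target + UMI(8) + backbone(40)
#' + barcode`, all on the transcript sense strand. Primer tails are not
#' modelled. With minimal arms and an 8-nt barcode the insert is
#' 16 + 112 + 18 + 8 + 40 + 8 = 202 nt.
#'
#' @param smmip one-row `smmip_panel` slice (or equivalent list).
#' @param gap_seq the molecule's gap-fill sequence; 112 nt for a reference
#'   molecule, down to 92 nt when a spiked deletion shortens the template.
#' @param umi 8-nt unique molecule identifier.
#' @param barcode sample barcode.
#' @return amplicon string.
#' @export
build_amplicon <- function(smmip, gap_seq, umi, barcode) {
  if (nchar(gap_seq) > GAP_LENGTH || nchar(gap_seq) < GAP_LENGTH - 20L)
    stop(sprintf("gap sequence must be %d nt (down to %d with a deletion), got %d",
                 GAP_LENGTH, GAP_LENGTH - 20L, nchar(gap_seq)), call. = FALSE)
  if (nchar(umi) != smmip$umi_length)
    stop("UMI length mismatch", call. = FALSE)
  paste0(revcomp(smmip$ext_arm), gap_seq, revcomp(smmip$lig_arm),
         umi, smmip$backbone, barcode)
}

# Apply a set of held variants (rows of the plan's variant table) to a
# reference gap sequence; positions are 0-based transcript coordinates.
.apply_variants_to_gap <- function(gap_ref, gap_start, vars) {
  if (nrow(vars) == 0L) return(gap_ref)
  vars <- vars[order(-vars$position), , drop = FALSE]
  g <- gap_ref
  for (i in seq_len(nrow(vars))) {
    lp <- vars$position[i] - gap_start + 1L  # 1-based local
    if (vars$alt[i] == "") {
      d <- nchar(vars$ref[i])
      g <- paste0(substr(g, 1L, lp - 1L), substr(g, lp + d, nchar(g)))
    } else {
      substr(g, lp, lp) <- vars$alt[i]
    }
  }
  g
}

# Vectorised substitution errors at per-base rate `rate`.
.add_errors <- function(reads, rate) {
  if (rate <= 0 || length(reads) == 0L) return(reads)
  n_err <- stats::rbinom(length(reads), nchar(reads), rate)
  hit <- which(n_err > 0L)
  for (i in hit) {
    pos <- sample.int(nchar(reads[i]), n_err[i])
    s <- strsplit(reads[i], "", fixed = TRUE)[[1L]]
    for (p in pos) s[p] <- sample(setdiff(DNA_BASES, s[p]), 1L)
    reads[i] <- paste(s, collapse = "")
  }
  reads
}

#' Simulate capture, PCR and sequencing of one sample
#'
#' Distributes `n_molecules` captured molecules over the panel's smMIPs by a
#' multinomial over abundance x capture efficiency, assigns each molecule a
#' uniform-random 8-nt UMI and 1 + Poisson(`dup_mean`) PCR copies, applies
#' per-base substitution errors at `error_rate`, and reads each amplicon as
#' a 2 x 151 bp pair: read 1 is the first 151 nt of the amplicon, read 2 the
#' reverse complement of its last 151 nt (so read 2 starts with the barcode
#' and backbone images, then the UMI image, the ligation arm and finally the
#' 3' part of the gap). A fixed plan seed makes the output byte-identical
#' across runs.
#'
#' @param panel an `smmip_panel`.
#' @param transcripts named list of [transcript_model()] objects.
#' @param plan a [sample_plan()].
#' @param efficiencies optional named per-smMIP efficiency vector (e.g. from
#'   [capture_efficiencies()]); by default drawn from the plan's seed with
#'   `sigma`.
#' @param sigma efficiency log-sd used when `efficiencies` is NULL.
#' @param error_rate per-base substitution error probability.
#' @param dup_mean mean extra PCR copies per molecule.
#' @return list with `reads` (data.frame: `read_id`, `seq1`, `seq2`),
#'   `truth_counts` (per-smMIP true molecule counts) and `truth_variants`
#'   (per-variant planned and realized fractions).
#' @export
simulate_reads <- function(panel, transcripts, plan, efficiencies = NULL,
                           sigma = 1.5, error_rate = 0.001, dup_mean = 1) {
  stopifnot(inherits(plan, "sample_plan"))
  # validate variant refs before any output
  vars <- plan$variants
  if (nrow(vars)) {
    for (i in seq_len(nrow(vars))) {
      tr <- transcripts[[vars$transcript_id[i]]]
      if (is.null(tr)) stop("variant on unknown transcript: ",
                            vars$transcript_id[i], call. = FALSE)
      obs <- substr(tr$sequence, vars$position[i] + 1L,
                    vars$position[i] + nchar(vars$ref[i]))
      if (obs != vars$ref[i])
        stop(sprintf("variant ref mismatch at %s:%d: plan says %s, transcript has %s",
                     vars$transcript_id[i], vars$position[i], vars$ref[i], obs),
             call. = FALSE)
    }
  }
  set.seed(plan$seed)
  if (is.null(efficiencies))
    efficiencies <- setNames(rlnorm(nrow(panel), 0, sigma), panel$smmip_id)
  ab <- plan$abundance[panel$transcript_id]
  ab[is.na(ab)] <- 0
  w <- as.numeric(ab) * as.numeric(efficiencies[panel$smmip_id])
  if (sum(w) <= 0) stop("all capture weights are zero", call. = FALSE)
  counts <- as.integer(stats::rmultinom(1L, plan$n_molecules, w))

  ids <- character(0); r1 <- character(0); r2 <- character(0)
  var_cap <- matrix(0L, nrow = nrow(vars), ncol = 2L)  # mutant, total
  for (s in seq_len(nrow(panel))) {
    n_s <- counts[s]
    if (n_s == 0L) next
    row <- panel[s, ]
    tr <- transcripts[[row$transcript_id]]
    if (is.null(tr)) stop("panel references unknown transcript: ",
                          row$transcript_id, call. = FALSE)
    gap_ref <- substr(tr$sequence, row$gap_start + 1L, row$gap_end)
    applicable <- which(vars$transcript_id == row$transcript_id &
                          vars$position >= row$gap_start &
                          vars$position + nchar(vars$ref) <= row$gap_end)
    umis <- random_dna(n_s, row$umi_length)
    ext_target <- revcomp(row$ext_arm); lig_target <- revcomp(row$lig_arm)
    if (length(applicable)) {
      hold <- matrix(runif(n_s * length(applicable)) <
                       rep(vars$allele_fraction[applicable], each = n_s),
                     nrow = n_s)
      var_cap[applicable, 1L] <- var_cap[applicable, 1L] + colSums(hold)
      var_cap[applicable, 2L] <- var_cap[applicable, 2L] + n_s
      gap_seqs <- vapply(seq_len(n_s), function(m) {
        held <- vars[applicable[hold[m, ]], , drop = FALSE]
        .apply_variants_to_gap(gap_ref, row$gap_start, held)
      }, character(1L))
    } else {
      gap_seqs <- rep(gap_ref, n_s)
    }
    # same layout as build_amplicon(), assembled vectorised over molecules
    amp <- paste0(ext_target, gap_seqs, lig_target, umis, row$backbone,
                  plan$barcode)
    L <- nchar(amp)
    m1 <- substr(amp, 1L, READ_LENGTH)
    m2 <- revcomp(substring(amp, L - READ_LENGTH + 1L, L))
    dups <- 1L + stats::rpois(n_s, dup_mean)
    mol_idx <- rep(seq_len(n_s), dups)
    dup_idx <- sequence(dups)
    ids <- c(ids, sprintf("%s:%s:m%06d:d%d", plan$sample_id, row$smmip_id,
                          mol_idx, dup_idx))
    r1 <- c(r1, .add_errors(m1[mol_idx], error_rate))
    r2 <- c(r2, .add_errors(m2[mol_idx], error_rate))
  }
  truth_counts <- data.frame(smmip_id = panel$smmip_id,
                             transcript_id = panel$transcript_id,
                             true_molecules = counts,
                             stringsAsFactors = FALSE)
  truth_variants <- cbind(vars, data.frame(
    realized_fraction = ifelse(var_cap[, 2L] > 0,
                               var_cap[, 1L] / var_cap[, 2L], NA_real_),
    mutant_molecules = var_cap[, 1L], covered_molecules = var_cap[, 2L]))
  list(reads = data.frame(read_id = ids, seq1 = r1, seq2 = r2,
                          stringsAsFactors = FALSE),
       truth_counts = truth_counts, truth_variants = truth_variants)
}

#' Write a paired FASTQ from simulated reads
#'
#' Constant Phred 30 qualities, Sanger encoding. Files ending in `.gz` are
#' gzip-compressed.
#'
#' @param reads data.frame with `read_id`, `seq1`, `seq2` (e.g. the `reads`
#'   element of [simulate_reads()]; rbind several to pool samples).
#' @param r1_path,r2_path output FASTQ paths.
#' @return the two paths, invisibly.
#' @export
write_fastq_pair <- function(reads, r1_path, r2_path) {
  write_one <- function(seqs, ids, path) {
    x <- Biostrings::DNAStringSet(seqs)
    names(x) <- ids
    qual <- Biostrings::BStringSet(strrep(PHRED_CHAR, nchar(seqs)))
    Biostrings::writeXStringSet(x, path, format = "fastq", qualities = qual,
                                compress = grepl("\\.gz$", path))
  }
  write_one(reads$seq1, reads$read_id, r1_path)
  write_one(reads$seq2, reads$read_id, r2_path)
  invisible(c(r1_path, r2_path))
}

#' Simulate a sample and write FASTQ plus truth tables
#'
#' Runs [simulate_reads()] and writes `<sample>_R1.fastq.gz`,
#' `<sample>_R2.fastq.gz` and the truth tables to `out_dir`.
#'
#' @inheritParams simulate_reads
#' @param out_dir output directory (created if needed).
#' @param compress write gzipped FASTQ (default TRUE).
#' @return invisibly, the [simulate_reads()] result with file paths attached.
#' @export
simulate_sample <- function(panel, transcripts, plan, out_dir,
                            efficiencies = NULL, sigma = 1.5,
                            error_rate = 0.001, dup_mean = 1,
                            compress = TRUE) {
  sim <- simulate_reads(panel, transcripts, plan, efficiencies, sigma,
                        error_rate, dup_mean)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  ext <- if (compress) ".fastq.gz" else ".fastq"
  r1 <- file.path(out_dir, paste0(plan$sample_id, "_R1", ext))
  r2 <- file.path(out_dir, paste0(plan$sample_id, "_R2", ext))
  write_fastq_pair(sim$reads, r1, r2)
  write_truth(sim, out_dir, prefix = plan$sample_id)
  sim$r1 <- r1; sim$r2 <- r2
  invisible(sim)
}

#' Write simulation truth tables
#'
#' Per-smMIP true molecule counts (summing to the plan's `n_molecules`) and
#' per-variant planned and realized allele fractions, used as ground truth
#' by the test-suite.
#'
#' @param sim a [simulate_reads()] result.
#' @param dir output directory.
#' @param prefix file name prefix.
#' @return invisibly, the two paths.
#' @export
write_truth <- function(sim, dir, prefix = "truth") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p1 <- file.path(dir, paste0(prefix, "_truth_counts.tsv"))
  p2 <- file.path(dir, paste0(prefix, "_truth_variants.tsv"))
  write.table(sim$truth_counts, p1, sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(sim$truth_variants, p2, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(p1, p2))
}
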