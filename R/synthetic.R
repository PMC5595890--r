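# Synthetic transcript models used as design/simulation substrates and as
# offline stand-ins for reference transcripts that are not shipped with the
# package. Everything here is generated in code and labelled synthetic.

# Default reverse-translation codon table. One codon per amino acid, chosen
# among common human codons with the constraint that no codon ends in T, so
# that a +1/-1 frameshift through default-codon regions can never create a
# stop codon (stops all start with T). Overrides re-introduce specific local
# codon context where a worked example depends on it.
.codon_default <- c(
  A = "GCC", R = "CGC", N = "AAC", D = "GAC", C = "TGC", Q = "CAG",
  E = "GAG", G = "GGC", H = "CAC", I = "ATC", L = "CTG", K = "AAG",
  M = "ATG", F = "TTC", P = "CCC", S = "AGC", T = "ACC", W = "TGG",
  Y = "TAC", V = "GTG", `*` = "TGA")

# Run code under a fixed seed without disturbing the caller's RNG stream.
with_local_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Reverse-translate a protein into a synthetic CDS
#'
#' Builds a coding sequence (including the stop codon) from a one-letter
#' protein string using a fixed codon table, with optional per-residue codon
#' overrides to plant a specific local nucleotide context.
#'
#' @param protein one-letter amino acid string (no stop; one is appended).
#' @param codon_overrides named character vector, names = residue numbers
#'   (1-based), values = codons to use there.
#' @return CDS string, length `3 * (nchar(protein) + 1)`.
#' @export
reverse_translate <- function(protein, codon_overrides = character(0)) {
  aa <- strsplit(protein, "", fixed = TRUE)[[1L]]
  bad <- setdiff(aa, names(.codon_default))
  if (length(bad)) stop("no codon for residue(s): ", paste(bad, collapse = ","))
  codons <- .codon_default[aa]
  if (length(codon_overrides)) {
    idx <- as.integer(names(codon_overrides))
    if (any(is.na(idx)) || any(idx < 1L) || any(idx > length(aa)))
      stop("codon override index out of range")
    codons[idx] <- toupper(codon_overrides)
  }
  paste0(paste(codons, collapse = ""), .codon_default[["*"]])
}

# VHL-like 213-residue protein used for the synthetic VHL transcript. The
# residues that the shipped worked examples depend on (Arg82, Val83, Val130,
# Asn131, Gln132) match the canonical VHL protein hotspot context.
.vhl_like_protein <- paste0(
  "MPRRAENWDEAEVGAEEAGVEEYGPEEDGGEESGAEESGPEESGPEELGAEEEMEAGRPR",
  "PVLRSVNSREPSQVIFCNRSPRVVLPVWLNFDGEPQPYPTLPPGTGRRIHSYRGHLWLFR",
  "DAGTHDGLLVNQTELFVPSLNVDGQPIFANITLPVYTLKERCLQVVRSLVKPENYRRLDI",
  "VRSLYEDLEDHPNVQKDLERLTQERIAHQRMGD")

#' Synthetic VHL-like transcript
#'
#' A synthetic stand-in for a VHL mRNA, built in code: the 213-residue
#' VHL-like protein above is reverse-translated with codon overrides fixing
#' the local context at residues 82/83 and 130--132. Under that context the
#' annotation engine derives the classic VHL consequences from first
#' principles: deleting CG at c.246_247 shifts the frame at Val83 to Arg and
#' reaches a new stop 48 codons in (p.Val83Argfs*48), and c.394C>T turns
#' codon 132 (CAA, Gln) into TAA (p.Gln132*). The transcript carries a 60-nt
#' 5' UTR, a 642-nt CDS and a 99-nt 3' UTR, with exon junctions at c.340/341
#' and c.463/464 as in the real gene.
#'
#' @return a [transcript_model()] with `gene_symbol = "VHL"`.
#' @export
synthetic_vhl_transcript <- function() {
  cds <- reverse_translate(.vhl_like_protein, c(
    `82` = "CGC",  # Arg82: c.246 = C
    `83` = "GTC",  # Val83: shifted codon 83 reads CGT = Arg
    `130` = "GTT", # Val130: shifted codon 130 reads TAA = stop (offset 48)
    `131` = "AAT", # Asn131
    `132` = "CAA"  # Gln132: c.394C>T -> TAA, p.Gln132*
  ))
  utr5 <- with_local_seed(4101L, random_dna(1L, 60L))
  utr3 <- with_local_seed(4102L, random_dna(1L, 99L))
  seqn <- paste0(utr5, cds, utr3)
  transcript_model(
    transcript_id = "VHLsyn", gene_symbol = "VHL", sequence = seqn,
    exon_ends = c(60L + 340L, 60L + 463L, nchar(seqn)),
    cds_start = 60L, cds_end = 60L + nchar(cds))
}

#' Synthetic IDH1-like transcript
#'
#' A synthetic stand-in for an IDH1 mRNA: a random 414-residue protein
#' (fixed internal seed) with Arg planted at residues 132 and 314 and codon
#' overrides CGT/CGC there, so that c.395G>A yields p.Arg132His (the R132H
#' hotspot context) and c.940C>T yields p.Arg314Cys.
#'
#' @return a [transcript_model()] with `gene_symbol = "IDH1"`.
#' @export
synthetic_idh1_transcript <- function() {
  aa20 <- setdiff(names(.codon_default), "*")
  prot <- with_local_seed(4201L,
    paste(c("M", sample(aa20, 413L, replace = TRUE)), collapse = ""))
  substr(prot, 132L, 132L) <- "R"
  substr(prot, 314L, 314L) <- "R"
  cds <- reverse_translate(prot, c(`132` = "CGT", `314` = "CGC"))
  utr5 <- with_local_seed(4202L, random_dna(1L, 90L))
  utr3 <- with_local_seed(4203L, random_dna(1L, 150L))
  seqn <- paste0(utr5, cds, utr3)
  transcript_model(
    transcript_id = "IDH1syn", gene_symbol = "IDH1", sequence = seqn,
    exon_ends = c(90L + 400L, 90L + 800L, nchar(seqn)),
    cds_start = 90L, cds_end = 90L + nchar(cds))
}

#' Generate a set of random synthetic transcripts
#'
#' Random-sequence transcript models for simulation studies: each transcript
#' has a random CDS of `n_codons` codons (no internal stops), short UTRs and
#' `n_exons` exons with junctions placed uniformly. Uses the caller's RNG
#' stream; seed it for reproducibility.
#'
#' @param n number of transcripts.
#' @param n_codons codons per CDS (default 300, i.e. a 903-nt CDS).
#' @param n_exons exons per transcript (default 3).
#' @param utr5,utr3 UTR lengths.
#' @param gene_prefix gene symbols become `<gene_prefix><i>`.
#' @return named list of [transcript_model()] objects.
#' @export
synthetic_transcript_set <- function(n, n_codons = 300L, n_exons = 3L,
                                     utr5 = 50L, utr3 = 80L,
                                     gene_prefix = "GENE") {
  gc <- Biostrings::GENETIC_CODE
  sense <- names(gc)[gc != "*"]
  out <- lapply(seq_len(n), function(i) {
    cds <- paste0("ATG",
                  paste(sample(sense, n_codons - 2L, replace = TRUE),
                        collapse = ""),
                  "TAA")
    seqn <- paste0(random_dna(1L, utr5), cds, random_dna(1L, utr3))
    len <- nchar(seqn)
    if (n_exons > 1L) {
      cuts <- sort(sample(seq(80L, len - 80L), n_exons - 1L))
      ends <- c(cuts, len)
    } else ends <- len
    transcript_model(
      transcript_id = sprintf("%s%03d.1", gene_prefix, i),
      gene_symbol = sprintf("%s%03d", gene_prefix, i),
      sequence = seqn, exon_ends = ends,
      cds_start = utr5, cds_end = utr5 + nchar(cds))
  })
  setNames(out, vapply(out, `[[`, "", "transcript_id"))
}
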