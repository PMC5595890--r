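# Minimal hand-built observation sets for pileup arithmetic.
obs_row <- function(smmip_id, umi, g1, g2 = substr(g1, 36, nchar(g1)),
                    sample_id = "S1") {
  data.frame(sample_id = sample_id, smmip_id = smmip_id, umi = umi,
             gap_obs_1 = g1, gap_obs_2 = g2, consensus_gap = g1,
             qual_obs_1 = strrep("?", nchar(g1)),
             qual_obs_2 = strrep("?", nchar(g2)),
             n_read_pairs = 1L, stringsAsFactors = FALSE)
}

one_smmip_fixture <- function(seed = 101) {
  set.seed(seed)
  trs <- synthetic_transcript_set(1, n_codons = 200)
  panel <- design_panel(trs)[1, , drop = FALSE]
  gap <- substr(trs[[1]]$sequence, panel$gap_start + 1, panel$gap_end)
  list(trs = trs, panel = panel, gap = gap)
}

test_that("pileup counts one forward and one reverse observation per mate", {
  fx <- one_smmip_fixture()
  obs <- obs_row(fx$panel$smmip_id, "AAAACCCC", fx$gap)
  pl <- build_pileup(obs, fx$panel, fx$trs)
  m <- pl$transcripts[[fx$panel$transcript_id]]
  pos1 <- fx$panel$gap_start + 1L       # first gap position (1-based)
  posL <- fx$panel$gap_end              # last gap position
  refb <- substr(fx$gap, 1, 1); refe <- substr(fx$gap, 112, 112)
  expect_identical(unname(m$fwd[pos1, refb]), 1L)
  expect_identical(unname(m$rev[pos1, refb]), 0L)  # mate 2 misses the 5' part
  expect_identical(unname(m$fwd[posL, refe]), 1L)
  expect_identical(unname(m$rev[posL, refe]), 1L)
  # totals: mate 1 covers 112 positions, mate 2 the 3'-most 77
  expect_identical(sum(m$fwd), 112L)
  expect_identical(sum(m$rev), 77L)
  # empty input gives an empty pileup
  empty <- build_pileup(obs[0, ], fx$panel, fx$trs)
  expect_length(empty$transcripts, 0L)
  expect_error(build_pileup(obs_row("GHOST_1", "AAAAAAAA", fx$gap),
                            fx$panel, fx$trs), "unknown smMIP")
})

test_that("overlapping smMIPs pool their observations", {
  set.seed(103)
  trs <- synthetic_transcript_set(1, n_codons = 200)
  cand <- enumerate_candidates(trs[[1]], stride = 1L)
  two <- cand[cand$gap_start %in% c(cand$gap_start[1], cand$gap_start[1] + 100L), ]
  two$smmip_id <- c("OV_1", "OV_2")
  panel <- structure(two[, c("smmip_id", "transcript_id", "gene_symbol",
                             "ext_arm", "lig_arm", "gap_start", "gap_end",
                             "umi_length", "backbone", "spans_junction",
                             "score")],
                     class = c("smmip_panel", "data.frame"))
  gaps <- lapply(1:2, function(i)
    substr(trs[[1]]$sequence, panel$gap_start[i] + 1, panel$gap_end[i]))
  obs <- rbind(obs_row("OV_1", "AAAACCCC", gaps[[1]]),
               obs_row("OV_2", "GGGGTTTT", gaps[[2]]))
  pl <- build_pileup(obs, panel, trs)
  m <- pl$transcripts[[panel$transcript_id[1]]]
  # the 12-nt overlap gets forward observations from both probes
  overlap <- (panel$gap_start[2] + 1L):panel$gap_end[1]
  expect_identical(length(overlap), 12L)
  expect_true(all(rowSums(m$fwd[overlap, , drop = FALSE]) == 2L))
})

test_that("the 5 percent / 5 unique reads / both orientations filter is enforced", {
  fx <- one_smmip_fixture()
  alt <- setdiff(c("A", "C", "G", "T"), substr(fx$gap, 60, 60))[1]
  g_alt <- fx$gap; substr(g_alt, 60, 60) <- alt
  mk <- function(n, g, tag) do.call(rbind, lapply(seq_len(n), function(i)
    obs_row(fx$panel$smmip_id, sprintf("%s%06d", tag, i), g)))
  # 11 mutant molecules among 122: VAF 22/244 = 9.0%, support 22 = 11 + 11
  obs <- rbind(mk(111, fx$gap, "RR"), mk(11, g_alt, "AA"))
  pl <- build_pileup(obs, fx$panel, fx$trs)
  calls <- call_variants(pl)
  hit <- calls[calls$alt == alt & calls$position == fx$panel$gap_start + 59L, ]
  expect_identical(nrow(hit), 1L)
  expect_identical(hit$filter, "PASS")
  expect_identical(hit$support_total, 22L)
  expect_identical(hit$support_fwd, 11L)
  expect_identical(hit$support_rev, 11L)
  expect_equal(hit$vaf, 22 / 244, tolerance = 1e-12)
  expect_identical(hit$support_total, hit$support_fwd + hit$support_rev)

  # VAF 100% but support 4 (2 molecules x 2 mates): support failure
  obs4 <- mk(2, g_alt, "XX")
  c4 <- call_variants(build_pileup(obs4, fx$panel, fx$trs))
  h4 <- c4[c4$alt == alt, ]
  expect_identical(h4$filter, "low_support")

  # VAF 4.9% with plenty of support: VAF failure, kept for audit
  obs49 <- rbind(mk(478, fx$gap, "R"), mk(25, g_alt, "A"))  # 50/1006 = 4.97%
  c49 <- call_variants(build_pileup(obs49, fx$panel, fx$trs))
  h49 <- c49[c49$alt == alt, ]
  expect_identical(h49$filter, "low_vaf")

  # forward-only support fails the orientation rule: place the variant in
  # the 5' third of the gap, which mate 2 never reaches
  alt5 <- setdiff(c("A", "C", "G", "T"), substr(fx$gap, 10, 10))[1]
  g5 <- fx$gap; substr(g5, 10, 10) <- alt5
  obs5 <- mk(6, g5, "FW")
  c5 <- call_variants(build_pileup(obs5, fx$panel, fx$trs))
  h5 <- c5[c5$alt == alt5 & c5$position == fx$panel$gap_start + 9L, ]
  expect_identical(h5$support_rev, 0L)
  expect_match(h5$filter, "orientation")

  # strict per-orientation mode
  cs <- call_variants(build_pileup(obs, fx$panel, fx$trs),
                      strict_orientation = TRUE)
  expect_identical(cs[cs$alt == alt, "filter"], "PASS")
  cs4 <- call_variants(build_pileup(obs4, fx$panel, fx$trs),
                       strict_orientation = TRUE)
  expect_match(cs4[cs4$alt == alt, "filter"], "orientation_support")
})

test_that("SNV annotation covers the canonical hotspot consequences", {
  vhl <- synthetic_vhl_transcript()
  # CAA -> TAA at codon 132: nonsense
  snv <- function(tr, cpos, ref, alt)
    data.frame(transcript_id = tr$transcript_id,
               position = tr$cds_start + cpos - 1L, ref = ref, alt = alt,
               stringsAsFactors = FALSE)
  q132 <- annotate_variant(snv(vhl, 394L, "C", "T"), vhl)
  expect_identical(q132$hgvs_c, "c.394C>T")
  expect_identical(q132$hgvs_p, "p.Gln132*")
  expect_identical(q132$classification, "nonsense")
  # dinucleotide deletion at c.246_247: frameshift to a stop 48 codons in
  del <- data.frame(transcript_id = vhl$transcript_id,
                    position = vhl$cds_start + 245L, ref = "CG", alt = "",
                    stringsAsFactors = FALSE)
  fs <- annotate_variant(del, vhl)
  expect_identical(fs$hgvs_c, "c.246_247delCG")
  expect_identical(fs$hgvs_p, "p.Val83Argfs*48")
  expect_identical(fs$classification, "frameshift")
  # IDH1 codon 132 CGT: G>A at the second position gives Arg -> His
  idh <- synthetic_idh1_transcript()
  r132h <- annotate_variant(snv(idh, 395L, "G", "A"), idh)
  expect_identical(r132h$hgvs_p, "p.Arg132His")
  expect_identical(r132h$classification, "missense")
  r314c <- annotate_variant(snv(idh, 940L, "C", "T"), idh)
  expect_identical(r314c$hgvs_p, "p.Arg314Cys")
  # synonymous: CGT -> CGC keeps Arg (IDH1 codon 132, third position T>C)
  syn <- annotate_variant(snv(idh, 396L, "T", "C"), idh)
  expect_identical(syn$hgvs_p, "p.(=)")
  expect_identical(syn$classification, "synonymous")
  # outside the CDS: n. notation, no classification
  utr <- annotate_variant(data.frame(transcript_id = vhl$transcript_id,
                                     position = 5L,
                                     ref = substr(vhl$sequence, 6, 6),
                                     alt = "A", stringsAsFactors = FALSE), vhl)
  expect_match(utr$hgvs_c, "^n\\.6")
  expect_true(is.na(utr$classification))
})

test_that("annotation agrees with the brute-force translate-and-diff oracle", {
  set.seed(107)
  n_cases <- 1000L
  trs <- synthetic_transcript_set(10, n_codons = 150)
  mismatches <- 0L
  for (k in seq_len(n_cases)) {
    tr <- trs[[sample.int(10L, 1L)]]
    cds_len <- tr$cds_end - tr$cds_start
    if (k %% 2L == 0L) {  # SNV, excluding the stop codon
      cp <- sample.int(cds_len - 3L, 1L)
      pos0 <- tr$cds_start + cp - 1L
      ref <- substr(tr$sequence, pos0 + 1L, pos0 + 1L)
      alt <- sample(setdiff(c("A", "C", "G", "T"), ref), 1L)
    } else {              # deletion of 1-20 nt, ending >= 30 nt before the stop
      d <- sample.int(20L, 1L)
      cp <- sample.int(cds_len - 30L - d, 1L)
      pos0 <- tr$cds_start + cp - 1L
      ref <- substr(tr$sequence, pos0 + 1L, pos0 + d)
      alt <- ""
    }
    call <- data.frame(transcript_id = tr$transcript_id, position = pos0,
                       ref = ref, alt = alt, stringsAsFactors = FALSE)
    got <- annotate_variant(call, tr)
    want <- oracle_annotate(tr, pos0, ref, alt)
    if (!identical(got$hgvs_p, want$hgvs_p) ||
        !identical(got$classification, want$classification)) {
      mismatches <- mismatches + 1L
      if (mismatches <= 3L)
        message(sprintf("disagreement at %s pos %d %s>%s: got %s/%s want %s/%s",
                        tr$transcript_id, pos0, ref, alt, got$hgvs_p,
                        got$classification, want$hgvs_p, want$classification))
    }
  }
  expect_identical(mismatches, 0L)
})

test_that("variant report and VCF export format calls faithfully", {
  vhl <- synthetic_vhl_transcript()
  trs <- list(VHLsyn = vhl)
  calls <- data.frame(
    transcript_id = "VHLsyn", position = vhl$cds_start + 245L, ref = "CG",
    alt = "", vaf = 22 / 244, support_total = 22L, support_fwd = 11L,
    support_rev = 11L, filter = "PASS", stringsAsFactors = FALSE)
  calls <- annotate_variants(calls, trs)
  path <- tempfile(fileext = ".tsv"); vcf <- tempfile(fileext = ".vcf")
  write_variant_report(calls, path, transcripts = trs, vcf_path = vcf)
  rep_df <- read.delim(path)
  expect_identical(nrow(rep_df), 1L)
  expect_identical(rep_df$gene, "VHL")
  expect_identical(rep_df$coverage, "9% (22) [11 / 11]")
  expect_identical(rep_df$hgvs_p, "p.Val83Argfs*48")
  vcf_lines <- readLines(vcf)
  expect_true(any(grepl("^##coordinates=transcript-space", vcf_lines)))
  body <- vcf_lines[!startsWith(vcf_lines, "#")]
  expect_identical(length(body), 1L)
  f <- strsplit(body, "\t")[[1]]
  expect_identical(nchar(f[4]) - nchar(f[5]), 2L)  # anchored 2-nt deletion
  # empty call set: header only
  write_variant_report(calls[0, ], path, transcripts = trs)
  expect_identical(nrow(read.delim(path)), 0L)
})

test_that("spiked variants are recovered through the full pipeline", {
  vhl <- synthetic_vhl_transcript()
  trs <- list(VHLsyn = vhl)
  # place the gap so that c.246_247 (transcript 305-306) sits in the region
  # both mates cover: gap [250, 362), local offset 55
  cand <- enumerate_candidates(vhl, stride = 1L)
  panel <- cand[cand$gap_start == 250L, ]
  panel$smmip_id <- "VHL_1"
  panel <- structure(panel[, c("smmip_id", "transcript_id", "gene_symbol",
                               "ext_arm", "lig_arm", "gap_start", "gap_end",
                               "umi_length", "backbone", "spans_junction",
                               "score")],
                     class = c("smmip_panel", "data.frame"))
  plan <- sample_plan("S1", "ACGTACGT", c(VHLsyn = 1), 300L,
                      variants = data.frame(transcript_id = "VHLsyn",
                                            position = 305L, ref = "CG",
                                            alt = "", allele_fraction = 0.5),
                      seed = 61)
  res <- run_sim_pipeline(panel, trs, plan, error_rate = 0, dup_mean = 1)
  pl <- build_pileup(res$observations, panel, trs)
  calls <- call_variants(pl)
  calls <- annotate_variants(calls[calls$filter == "PASS", ], trs)
  expect_identical(nrow(calls), 1L)
  expect_identical(calls$hgvs_c, "c.246_247delCG")
  expect_identical(calls$hgvs_p, "p.Val83Argfs*48")
  truth <- res$sims[[1]]$truth_variants$realized_fraction
  expect_lt(abs(calls$vaf - truth), 3 * sqrt(0.25 / calls$support_total))

  # no false PASS calls on an error-free, variant-free run
  plan0 <- sample_plan("S1", "ACGTACGT", c(VHLsyn = 1), 300L, seed = 67)
  res0 <- run_sim_pipeline(panel, trs, plan0, error_rate = 0, dup_mean = 1)
  c0 <- call_variants(build_pileup(res0$observations, panel, trs))
  expect_identical(sum(c0$filter == "PASS"), 0L)

  # at error_rate 0.001 and deep unique coverage, errors alone stay far
  # below the 5% VAF floor
  plan_e <- sample_plan("S1", "ACGTACGT", c(VHLsyn = 1), 400L, seed = 71)
  res_e <- run_sim_pipeline(panel, trs, plan_e, error_rate = 0.001,
                            dup_mean = 1)
  ce <- call_variants(build_pileup(res_e$observations, panel, trs))
  expect_identical(sum(ce$filter == "PASS"), 0L)
})
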