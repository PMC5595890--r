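test_that("demultiplexing assigns by barcode image and conserves reads", {
  bc <- c(A = "ACGTACGT", B = "TGCACTGA")
  mk_read2 <- function(barcode, nmut = 0) {
    img <- revcomp(barcode)
    if (nmut > 0) {
      s <- strsplit(img, "")[[1]]
      for (i in seq_len(nmut)) s[i] <- setdiff(c("A","C","G","T"), s[i])[1]
      img <- paste(s, collapse = "")
    }
    paste0(img, strrep("T", 143))
  }
  reads <- data.frame(
    read_id = sprintf("r%d", 1:10),
    seq1 = strrep("A", 151),
    seq2 = c(rep(mk_read2("ACGTACGT"), 6),      # exact -> A
             mk_read2("ACGTACGT", 1),           # 1 mismatch -> A
             rep(mk_read2("ACGTACGT", 2), 3)),  # 2 mismatches -> unassigned
    stringsAsFactors = FALSE)
  out <- demultiplex(reads, bc, max_mismatch = 1)
  expect_identical(sum(out$sample_id == "A", na.rm = TRUE), 7L)
  expect_identical(sum(is.na(out$sample_id)), 3L)
  expect_identical(sum(!is.na(out$sample_id)) + sum(is.na(out$sample_id)), 10L)
  # ambiguous barcode maps are a configuration error
  expect_error(demultiplex(reads, c(A = "ACGTACGT", B = "ACGTACGA")),
               "ambiguous")
})

test_that("arm matching finds the true smMIP, tolerates one substitution, refuses ties", {
  set.seed(61)
  trs <- synthetic_transcript_set(2, n_codons = 200)
  panel <- design_panel(trs)
  plan <- sample_plan("S1", "ACGTACGT", setNames(c(1, 1), names(trs)), 200L,
                      seed = 31)
  sim <- simulate_reads(panel, trs, plan, error_rate = 0, dup_mean = 0)
  reads <- with_quals(sim$reads)
  reads$sample_id <- "S1"
  out <- match_smmip(reads, panel)
  truth <- sub("^S1:([^:]+):.*$", "\\1", reads$read_id)
  expect_identical(out$smmip_id, truth)

  # one substitution inside the extension arm image still matches
  r <- out[1, ]
  s <- strsplit(r$seq1, "")[[1]]
  s[3] <- setdiff(c("A","C","G","T"), s[3])[1]
  r$seq1 <- paste(s, collapse = "")
  expect_identical(match_smmip(r, panel)$smmip_id, truth[1])

  # a panel duplicating both arms can never be assigned
  dup_panel <- rbind(as.data.frame(panel), as.data.frame(panel[1, ]))
  dup_panel$smmip_id[nrow(dup_panel)] <- "DUP_1"
  out2 <- match_smmip(reads[truth == panel$smmip_id[1], ], dup_panel)
  expect_true(all(is.na(out2$smmip_id)))
})

test_that("UMI collapse groups by (smMIP, UMI) and votes out lone errors", {
  set.seed(71)
  trs <- synthetic_transcript_set(1, n_codons = 200)
  panel <- design_panel(trs)[1, , drop = FALSE]
  tr <- trs[[1]]
  gap <- substr(tr$sequence, panel$gap_start + 1, panel$gap_end)
  mk_obs <- function(umi, g1, n = 1) {
    do.call(rbind, replicate(n, data.frame(
      sample_id = "S1", smmip_id = panel$smmip_id, umi = umi,
      gap_obs_1 = g1, gap_obs_2 = substr(g1, 36, 112),
      qual_obs_1 = strrep("?", nchar(g1)),
      qual_obs_2 = strrep("?", 77), stringsAsFactors = FALSE),
      simplify = FALSE))
  }
  # 3 duplicate pairs, one with a lone substitution at gap position 50
  g_err <- gap
  substr(g_err, 50, 50) <- setdiff(c("A","C","G","T"),
                                   substr(gap, 50, 50))[1]
  fam <- rbind(mk_obs("AAAATTTT", gap, 2), mk_obs("AAAATTTT", g_err, 1))
  obs <- collapse_umis(fam)
  expect_identical(nrow(obs), 1L)
  expect_identical(obs$n_read_pairs, 3L)
  expect_identical(obs$gap_obs_1, gap)        # majority base carried
  expect_identical(obs$consensus_gap, gap)

  # same smMIP, two UMIs: two unique observations
  two <- rbind(mk_obs("AAAATTTT", gap), mk_obs("CCCCGGGG", gap))
  expect_identical(nrow(collapse_umis(two)), 2L)

  # idempotence: collapsing already-unique observations changes nothing
  once <- collapse_umis(two)
  twice <- collapse_umis(once[, c("sample_id", "smmip_id", "umi",
                                  "gap_obs_1", "gap_obs_2",
                                  "qual_obs_1", "qual_obs_2")])
  expect_identical(twice$consensus_gap[order(twice$umi)],
                   once$consensus_gap[order(once$umi)])
  expect_identical(nrow(twice), nrow(once))
})

test_that("count table includes zero rows and conserves totals", {
  set.seed(73)
  trs <- synthetic_transcript_set(1, n_codons = 260)
  panel <- design_panel(trs)
  obs <- data.frame(sample_id = c("S1", "S1", "S2"),
                    smmip_id = panel$smmip_id[c(1, 2, 1)],
                    umi = c("AAAAAAAA", "CCCCCCCC", "GGGGGGGG"),
                    stringsAsFactors = FALSE)
  ct <- count_table(obs, panel, samples = c("S1", "S2", "S3"))
  expect_identical(dim(ct), c(nrow(panel), 3L))
  expect_equal(unname(colSums(ct)), c(2, 1, 0))
  expect_identical(unname(ct[3, "S1"]), 0L)
  expect_error(count_table(data.frame(sample_id = "S1", smmip_id = "NOPE_1",
                                      umi = "A"), panel), "unknown smMIP")
})

test_that("end-to-end: duplication-only runs recover the truth table exactly", {
  set.seed(79)
  trs <- synthetic_transcript_set(3, n_codons = 200)
  panel <- design_panel(trs)
  plans <- list(
    sample_plan("S1", "ACGTACGT", setNames(c(5, 1, 2), names(trs)), 600L,
                seed = 101),
    sample_plan("S2", "TGCACTGA", setNames(c(1, 4, 1), names(trs)), 400L,
                seed = 102))
  eff <- capture_efficiencies(panel, sigma = 1.5, seed = 9)
  res <- run_sim_pipeline(panel, trs, plans, error_rate = 0, dup_mean = 2,
                          efficiencies = eff)
  for (k in 1:2) {
    truth <- res$sims[[k]]$truth_counts
    got <- res$counts[truth$smmip_id, plans[[k]]$sample_id]
    expect_identical(unname(got), truth$true_molecules)
  }
  # increasing duplication leaves unique counts invariant
  res4 <- run_sim_pipeline(panel, trs, plans, error_rate = 0, dup_mean = 4,
                           efficiencies = eff)
  expect_identical(res4$counts, res$counts)
  expect_gt(nrow(res4$reads), nrow(res$reads))
})

test_that("FASTQ files round-trip through the processor", {
  set.seed(83)
  trs <- synthetic_transcript_set(2, n_codons = 200)
  panel <- design_panel(trs)
  plan <- sample_plan("S1", "ACGTACGT", setNames(c(1, 2), names(trs)), 250L,
                      seed = 55)
  dir <- tempfile()
  sim <- simulate_sample(panel, trs, plan, dir, error_rate = 0, dup_mean = 1)
  res <- process_fastq(sim$r1, sim$r2, panel, c(S1 = "ACGTACGT"))
  expect_identical(res$stats$read_pairs, nrow(sim$reads))
  expect_identical(res$stats$demultiplexed, nrow(sim$reads))
  expect_identical(unname(res$counts[sim$truth_counts$smmip_id, "S1"]),
                   sim$truth_counts$true_molecules)
  # observation TSV round-trip
  p <- tempfile(fileext = ".tsv")
  write_observations(res$observations, p)
  back <- read_observations(p)
  expect_identical(back$umi, res$observations$umi)
  expect_identical(back$consensus_gap, res$observations$consensus_gap)
})
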