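test_that("splicing reconstructs hand-built transcripts on both strands", {
  # single-exon plus strand: mRNA equals the genome slice
  genome <- Biostrings::DNAStringSet(c(chr1 = "ACGTACGTACGTACGTACGT"))
  m1 <- transcript_model("T1", chrom = "chr1", strand = "+",
                         exons = data.frame(start = 2, end = 14),
                         cds_end_tx = 0)
  expect_identical(splice_transcript(genome, m1)$mrna, "GTACGTACGTAC")

  # two-exon minus-strand toy: exons [0,6) and [10,16) of a 20-nt chrom;
  # expected sequence built by hand as revcomp(slice2) + revcomp(slice1)
  m2 <- transcript_model("T2", chrom = "chr1", strand = "-",
                         exons = data.frame(start = c(10, 0), end = c(16, 6)),
                         cds_end_tx = 0)
  rc <- function(s) as.character(
    Biostrings::reverseComplement(Biostrings::DNAString(s)))
  s <- "ACGTACGTACGTACGTACGT"
  expect_identical(splice_transcript(genome, m2)$mrna,
                   paste0(rc(substr(s, 11, 16)), rc(substr(s, 1, 6))))

  # the coordinate map is a bijection: strand-adjusted genome base at
  # coord_map(i) equals mrna[i] for all i
  sp <- splice_transcript(genome, m2)
  for (i in seq_along(sp$coord_map)) {
    g <- substr(s, sp$coord_map[i] + 1, sp$coord_map[i] + 1)
    expect_identical(rc(g), substr(sp$mrna, i, i))
  }
  expect_false(anyDuplicated(sp$coord_map) > 0)

  expect_error(
    splice_transcript(genome, transcript_model(
      "T3", chrom = "chr1", strand = "+",
      exons = data.frame(start = 10, end = 30), cds_end_tx = 0)),
    "annotation error")
})

test_that("region boundaries match a naive codon scanner on random transcripts", {
  set.seed(11)
  for (i in 1:500) {
    rt <- random_mrna()
    model <- mrna_model(rt$mrna, rt$cds_end_tx)
    reg <- find_readthrough_region(model)
    start <- rt$cds_end_tx + 3
    nxt <- naive_next_stop(rt$mrna, start)
    if (is.na(nxt)) {
      expect_identical(reg$status, "no_downstream_stop")
      expect_identical(reg$tx_end,
                       as.integer(start + 3 * ((nchar(rt$mrna) - start) %/% 3)))
    } else {
      expect_identical(reg$status, "ok")
      expect_identical(reg$length_nt, as.integer(nxt - start))
    }
    # frame conservation: the region's own sequence contains no stop
    if (reg$length_nt > 0 && reg$status == "ok")
      expect_true(is.na(naive_next_stop(reg$seq, 0)))
  }
})

test_that("edge cases: immediate stop, no downstream stop, short mRNA", {
  m <- mrna_model(paste0("ATGAAA", "TGA", "TAAGGG"), 6)
  reg <- find_readthrough_region(m)
  expect_identical(reg$length_nt, 0L)
  expect_identical(reg$status, "ok")

  # 10 nt after the stop, none of them a stop codon: region is the
  # last complete codon boundary (9 nt)
  m2 <- mrna_model(paste0("ATGAAA", "TGA", "AAACCCGGGA"), 6)
  reg2 <- find_readthrough_region(m2)
  expect_identical(reg2$status, "no_downstream_stop")
  expect_identical(reg2$length_nt, 9L)

  expect_error(find_readthrough_region(mrna_model("ATGAA", 3)),
               "annotation error")
  # codon at cds_end_tx must be a stop
  expect_error(find_readthrough_region(mrna_model("ATGAAACCCGGG", 6)),
               "annotation error")
})

test_that("mean conservation averages covered positions and enforces coverage", {
  mk_track <- function(scores, start = 9) {
    conservation_track(data.frame(
      chrom = "chr1", start = start + seq_along(scores) - 1,
      end = start + seq_along(scores), score = scores))
  }
  m <- mrna_model(paste0("ATGAAA", "TGA", "AAACCC", "TAG", "TT"), 6)
  reg <- find_readthrough_region(m)  # region = tx [9, 15)
  expect_identical(reg$length_nt, 6L)

  expect_equal(mean_conservation(reg, mk_track(rep(1, 6)))$mean_score, 1.0)
  expect_equal(mean_conservation(reg, mk_track(rep(0, 6)))$mean_score, 0.0)

  # one of six positions missing: mean over the present five only
  t5 <- conservation_track(data.frame(chrom = "chr1", start = 9:13,
                                      end = 10:14, score = c(1, 1, 0, 0, 1)))
  sc <- mean_conservation(reg, t5, min_coverage = 0.8)
  expect_equal(sc$coverage, 5 / 6)
  expect_equal(sc$mean_score, 3 / 5)

  # below min_coverage: flagged, no mean
  low <- mean_conservation(reg, t5, min_coverage = 0.9)
  expect_identical(low$status, "low_coverage")
  expect_true(is.na(low$mean_score))
})

test_that("synthetic transcriptome: truth means exact, planted regions rank on top", {
  cfg <- sim_config(seed = 1)
  tx <- gen_transcriptome(cfg)
  res <- scan_readthrough(tx$models, tx$genome, conservation_track(tx$track))
  reg <- res$regions

  expect_identical(nrow(reg), cfg$n_transcripts)
  expect_identical(length(tx$truth$conserved_tr_ids),
                   as.integer(round(cfg$frac_conserved_tr * cfg$n_transcripts)))

  ok <- reg$status == "ok"
  expect_equal(reg$mean_score[ok],
               unname(tx$truth$true_mean_scores[reg$transcript_id[ok]]),
               tolerance = 1e-12)

  # planted score range is disjoint from background: planted ids are
  # exactly the top-scoring regions
  k <- length(tx$truth$conserved_tr_ids)
  top <- reg$transcript_id[order(-reg$mean_score)][seq_len(k)]
  expect_setequal(top, tx$truth$conserved_tr_ids)

  # transcripts without a downstream stop are present but unscored
  expect_true(all(reg$status[reg$transcript_id %in% tx$truth$no_stop_ids] ==
                    "no_downstream_stop"))
  expect_equal(sum(res$histogram$proportion), 1, tolerance = 1e-9)
  expect_identical(sum(res$histogram$count), sum(ok & !is.na(reg$mean_score)))
})

test_that("generated files round-trip through the format readers", {
  dir <- withr::local_tempdir()
  cfg <- sim_config(seed = 3, n_transcripts = 30)
  tx <- gen_transcriptome(cfg, dir = dir)

  # regenerate with the same seed: byte-identical outputs
  dir2 <- withr::local_tempdir()
  gen_transcriptome(sim_config(seed = 3, n_transcripts = 30), dir = dir2)
  for (f in c("genome.fa", "transcripts.bed", "track.bedGraph"))
    expect_identical(readLines(file.path(dir, f)),
                     readLines(file.path(dir2, f)))

  # scanning from files (rtracklayer-parsed BED12/bedGraph) matches
  # scanning the in-memory objects
  a <- scan_readthrough(tx$models, tx$genome, conservation_track(tx$track))
  b <- scan_readthrough(file.path(dir, "transcripts.bed"),
                        file.path(dir, "genome.fa"),
                        file.path(dir, "track.bedGraph"))
  oa <- order(a$regions$transcript_id)
  ob <- order(b$regions$transcript_id)
  expect_identical(a$regions$length_nt[oa], b$regions$length_nt[ob])
  expect_identical(a$regions$status[oa], b$regions$status[ob])
  expect_equal(a$regions$mean_score[oa], b$regions$mean_score[ob],
               tolerance = 1e-12)
})

test_that("GTF annotations convert to the same models as BED12", {
  # two-exon transcript on each strand, written as GTF by hand
  gtf <- c(
    'chr1\ttest\texon\t11\t30\t.\t+\t.\tgene_id "G1"; transcript_id "T1";',
    'chr1\ttest\texon\t41\t60\t.\t+\t.\tgene_id "G1"; transcript_id "T1";',
    'chr1\ttest\tstop_codon\t45\t47\t.\t+\t.\tgene_id "G1"; transcript_id "T1";',
    'chr1\ttest\texon\t71\t90\t.\t-\t.\tgene_id "G2"; transcript_id "T2";',
    'chr1\ttest\tstop_codon\t80\t82\t.\t-\t.\tgene_id "G2"; transcript_id "T2";')
  f <- withr::local_tempfile(fileext = ".gtf")
  writeLines(gtf, f)
  models <- read_gtf_models(f)
  m <- models[[match("T1", vapply(models, `[[`, "", "transcript_id"))]]
  expect_equal(m$exons$start, c(10, 40))
  expect_equal(m$exons$end, c(30, 60))
  # stop at genome 44 (0-based) = tx 20 + 4
  expect_identical(m$cds_end_tx, 24L)
  m2 <- models[[match("T2", vapply(models, `[[`, "", "transcript_id"))]]
  expect_identical(m2$strand, "-")
  # minus strand: tx coord of genome base 81 (first stop base) = 90-1-81
  expect_identical(m2$cds_end_tx, 8L)
})

test_that("strand symmetry: a mirrored transcript yields the same region", {
  set.seed(21)
  rt <- random_mrna(min_tail = 30)
  L <- 10 + nchar(rt$mrna)
  pad <- paste(sample(c("A", "C", "G", "T"), 10, replace = TRUE),
               collapse = "")
  fwd_seq <- paste0(rt$mrna, pad)
  rc <- function(s) as.character(
    Biostrings::reverseComplement(Biostrings::DNAString(s)))
  genome_f <- Biostrings::DNAStringSet(c(chr1 = fwd_seq))
  genome_r <- Biostrings::DNAStringSet(c(chr1 = rc(fwd_seq)))
  mf <- transcript_model("T", chrom = "chr1", strand = "+",
                         exons = data.frame(start = 0, end = nchar(rt$mrna)),
                         cds_end_tx = rt$cds_end_tx)
  mr <- transcript_model("T", chrom = "chr1", strand = "-",
                         exons = data.frame(start = 10, end = L),
                         cds_end_tx = rt$cds_end_tx)
  mf$mrna <- splice_transcript(genome_f, mf)$mrna
  mr$mrna <- splice_transcript(genome_r, mr)$mrna
  expect_identical(mf$mrna, mr$mrna)
  rf <- find_readthrough_region(mf)
  rr <- find_readthrough_region(mr)
  expect_identical(rf$length_nt, rr$length_nt)
  expect_identical(rf$status, rr$status)

  # mirrored per-base scores give the same mean
  if (rf$status == "ok" && rf$length_nt > 0) {
    sc <- runif(rf$length_nt)
    tf <- conservation_track(data.frame(
      chrom = "chr1", start = rf$genome_intervals$start[1] +
        seq_len(rf$length_nt) - 1,
      end = rf$genome_intervals$start[1] + seq_len(rf$length_nt),
      score = sc))
    gi <- rr$genome_intervals
    tr <- conservation_track(data.frame(
      chrom = "chr1", start = gi$start[1] + seq_len(rf$length_nt) - 1,
      end = gi$start[1] + seq_len(rf$length_nt), score = rev(sc)))
    expect_equal(mean_conservation(rf, tf)$mean_score,
                 mean_conservation(rr, tr)$mean_score, tolerance = 1e-12)
  }
})

test_that("extension translation matches an independent codon-table oracle", {
  set.seed(31)
  sense <- setdiff(as.vector(outer(outer(c("A", "C", "G", "T"),
                                         c("A", "C", "G", "T"), paste0),
                                   c("A", "C", "G", "T"), paste0)), STOPS)
  for (i in 1:300) {
    s <- paste(sample(sense, sample(1:40, 1), replace = TRUE), collapse = "")
    expect_identical(translate_extension(s), oracle_translate(s))
  }
  expect_identical(translate_extension(""), "")
  expect_error(translate_extension("ACGTA"), "input error")
  expect_error(translate_extension("ACGTAATTT"), "invariant violation")
})
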