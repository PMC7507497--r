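#' Generate a synthetic transcriptome with a conservation track
#'
#' Builds a small genome of single- and multi-exon transcripts on both
#' strands, each with a CDS ending in TAA/TAG/TGA followed by a
#' readthrough region (a stop-free codon run terminated by a downstream
#' in-frame stop, except for a configurable fraction that lacks one).
#' A per-base conservation track covers all exonic bases minus a
#' dropout fraction; a planted fraction of transcripts carries high
#' conservation over exactly their readthrough region. Ground truth
#' records the planted ids and the exact mean track score over each
#' emitted region.
#'
#' @param config a [sim_config()].
#' @param dir optional output directory; when given, writes
#'   `genome.fa`, `transcripts.bed` (BED12) and `track.bedGraph`.
#' @return list with `genome` ([Biostrings::DNAStringSet]), `models`
#'   (list of [transcript_model()]s with mRNA filled), `track`
#'   (data.frame chrom/start/end/score, 0-based half-open), `truth`,
#'   and file paths when `dir` is given.
#' @export
gen_transcriptome <- function(config, dir = NULL) {
  validate_sim_config(config)
  sim_seed(config, "transcriptome")
  n <- config$n_transcripts
  ids <- sprintf("TX%04d", seq_len(n))
  n_cons <- round(config$frac_conserved_tr * n)
  conserved_ids <- if (n_cons > 0) sample(ids, n_cons) else character(0)
  n_nostop <- round(config$frac_no_stop * n)
  pool <- setdiff(ids, conserved_ids)
  no_stop_ids <- if (n_nostop > 0 && length(pool) > 0)
    sample(pool, min(n_nostop, length(pool))) else character(0)

  chrom_seqs <- list(chr1 = character(0), chr2 = character(0))
  chrom_len <- c(chr1 = 0L, chr2 = 0L)
  models <- vector("list", n)
  tr_tx <- matrix(0L, n, 2, dimnames = list(ids, c("start", "end")))
  tr_len <- integer(n)

  random_bases <- function(k) {
    if (k == 0L) return("")
    paste(sample(c("A", "C", "G", "T"), k, replace = TRUE), collapse = "")
  }

  for (i in seq_len(n)) {
    id <- ids[i]
    utr5 <- sample(0:30, 1L)
    n_cds <- sample(20:60, 1L)
    n_tr <- sample(10:40, 1L)
    cds <- paste0(random_orf(n_cds), sample(STOP_CODONS, 1L))
    tr <- random_orf(n_tr)
    post <- if (id %in% no_stop_ids) {
      paste0(tr, random_bases(sample(0:2, 1L)))
    } else {
      paste0(tr, sample(STOP_CODONS, 1L), random_bases(sample(5:30, 1L)))
    }
    mrna <- paste0(random_bases(utr5), cds, post)
    cds_end_tx <- utr5 + 3L * n_cds       # first base of annotated stop
    tr_start <- cds_end_tx + 3L
    tr_tx[i, ] <- c(tr_start, tr_start + 3L * n_tr)
    tr_len[i] <- 3L * n_tr

    # exon structure: first transcript single-exon, second multi-exon,
    # rest random; splits at uniform transcript positions
    n_ex <- if (i == 1L) 1L else if (i == 2L) 2L else sample(1:3, 1L)
    L <- nchar(mrna)
    n_ex <- min(n_ex, L - 1L)
    cuts <- if (n_ex > 1L) sort(sample(seq_len(L - 1L), n_ex - 1L)) else integer(0)
    ex_tx_start <- c(0L, cuts)
    ex_tx_end <- c(cuts, L)
    ex_len <- ex_tx_end - ex_tx_start
    strand <- sample(c("+", "-"), 1L)
    chrom <- if (i %% 2L == 1L) "chr1" else "chr2"

    # genomic locus in transcript orientation: exon/intron alternation
    introns <- if (n_ex > 1L) sample(20:80, n_ex - 1L, replace = TRUE) else integer(0)
    locus_parts <- character(0)
    ex_locus_off <- integer(n_ex)   # offset of each exon in the locus, tx orientation
    off <- 0L
    for (e in seq_len(n_ex)) {
      ex_locus_off[e] <- off
      locus_parts <- c(locus_parts, substr(mrna, ex_tx_start[e] + 1L, ex_tx_end[e]))
      off <- off + ex_len[e]
      if (e < n_ex) {
        locus_parts <- c(locus_parts, random_bases(introns[e]))
        off <- off + introns[e]
      }
    }
    locus_tx <- paste(locus_parts, collapse = "")
    locus_len <- nchar(locus_tx)
    gap <- random_bases(sample(50:150, 1L))
    locus_start <- chrom_len[[chrom]] + nchar(gap)
    locus_genomic <- if (strand == "+") locus_tx else
      as.character(Biostrings::reverseComplement(Biostrings::DNAString(locus_tx)))
    chrom_seqs[[chrom]] <- c(chrom_seqs[[chrom]], gap, locus_genomic)
    chrom_len[[chrom]] <- locus_start + locus_len

    exons <- if (strand == "+") {
      data.frame(start = locus_start + ex_locus_off,
                 end = locus_start + ex_locus_off + ex_len)
    } else {
      data.frame(start = locus_start + locus_len - ex_locus_off - ex_len,
                 end = locus_start + locus_len - ex_locus_off)
    }
    models[[i]] <- transcript_model(id, gene_id = sub("TX", "G", id),
                                    chrom = chrom, strand = strand,
                                    exons = exons, cds_end_tx = cds_end_tx,
                                    mrna = mrna)
  }

  genome <- Biostrings::DNAStringSet(vapply(chrom_seqs, paste,
                                            character(1), collapse = ""))

  # conservation track: every exonic base scored on a per-mille grid,
  # planted-conserved scores over the readthrough region only
  grid <- function(range, k) sample(round(range[1] * 1000):round(range[2] * 1000),
                                    k, replace = TRUE) / 1000
  track_rows <- vector("list", n)
  for (i in seq_len(n)) {
    m <- models[[i]]
    map <- transcript_coord_map(m)
    L <- length(map)
    sc <- grid(config$background_score_range, L)
    if (m$transcript_id %in% conserved_ids) {
      idx <- (tr_tx[i, 1] + 1L):tr_tx[i, 2]
      sc[idx] <- grid(config$conserved_score_range, length(idx))
    }
    keep <- runif(L) >= config$track_dropout
    track_rows[[i]] <- data.frame(chrom = m$chrom, pos = map[keep],
                                  score = sc[keep])
  }
  tr_all <- do.call(rbind, track_rows)
  tr_all <- tr_all[order(tr_all$chrom, tr_all$pos), ]
  track <- data.frame(chrom = tr_all$chrom, start = tr_all$pos,
                      end = tr_all$pos + 1L, score = tr_all$score)

  # truth: recompute each region's mean from the emitted track
  ctrack <- conservation_track(track)
  true_mean <- rep(NA_real_, n)
  true_cov <- rep(NA_real_, n)
  gi_rows <- vector("list", n)
  for (i in seq_len(n)) {
    m <- models[[i]]
    if (tr_len[i] == 0L) next
    gi <- project_to_genome(m, tr_tx[i, 1], tr_tx[i, 2])
    gi_rows[[i]] <- cbind(transcript_id = m$transcript_id, gi)
    vals <- unlist(lapply(seq_len(nrow(gi)), function(k)
      ctrack$scores[[gi$chrom[k]]][(gi$start[k] + 1L):gi$end[k]]))
    true_cov[i] <- mean(!is.na(vals))
    if (any(!is.na(vals))) true_mean[i] <- mean(vals[!is.na(vals)])
  }
  truth <- list(conserved_tr_ids = sort(conserved_ids),
                no_stop_ids = sort(no_stop_ids),
                true_mean_scores = stats::setNames(true_mean, ids),
                true_coverage = stats::setNames(true_cov, ids),
                tr_length_nt = stats::setNames(tr_len, ids),
                tr_genome_intervals = do.call(rbind, gi_rows))

  out <- list(genome = genome, models = models, track = track, truth = truth)
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    out$genome_file <- file.path(dir, "genome.fa")
    out$annotation_file <- file.path(dir, "transcripts.bed")
    out$track_file <- file.path(dir, "track.bedGraph")
    Biostrings::writeXStringSet(genome, out$genome_file)
    write_bed12(models, out$annotation_file)
    write_bedgraph(track, out$track_file)
  }
  out
}

#' Write transcript models as BED12
#'
#' The thick interval spans the CDS including the annotated stop codon.
#'
#' @param models list of [transcript_model()]s.
#' @param path output file.
#' @export
write_bed12 <- function(models, path) {
  rows <- vapply(models, function(m) {
    ex <- m$exons[order(m$exons$start), , drop = FALSE]
    tx_start <- min(ex$start)
    map <- transcript_coord_map(m)
    # thick covers the genomic span of the stop codon (transcript
    # coords cds_end_tx .. +3); its 3'-most base is always exonic, so a
    # reader can recover the stop even when it spans an exon junction
    stop_g <- map[(m$cds_end_tx + 1L):(m$cds_end_tx + 3L)]
    thick_start <- min(stop_g)
    thick_end <- max(stop_g) + 1L
    sprintf("%s\t%d\t%d\t%s\t0\t%s\t%d\t%d\t0\t%d\t%s\t%s",
            m$chrom, tx_start, max(ex$end), m$transcript_id, m$strand,
            thick_start, thick_end, nrow(ex),
            paste0(paste(ex$end - ex$start, collapse = ","), ","),
            paste0(paste(ex$start - tx_start, collapse = ","), ","))
  }, character(1))
  writeLines(rows, path)
}

#' Write a per-base track as bedGraph
#'
#' @param track data.frame with `chrom`, `start`, `end`, `score`
#'   (0-based half-open).
#' @param path output file.
#' @export
write_bedgraph <- function(track, path) {
  writeLines(sprintf("%s\t%d\t%d\t%s", track$chrom, track$start,
                     track$end, formatC(track$score, format = "fg",
                                        digits = 15, flag = "#")),
             path)
}
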