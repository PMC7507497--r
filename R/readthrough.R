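#' Transcript model
#'
#' A spliced transcript: exon blocks in genome coordinates, strand, and
#' the transcript-coordinate position of the annotated stop codon. All
#' coordinates are 0-based half-open; exons are ordered 5'->3' in
#' transcript orientation (descending genome coordinates on the minus
#' strand).
#'
#' @param transcript_id,gene_id identifiers.
#' @param chrom chromosome name.
#' @param strand `"+"` or `"-"`.
#' @param exons data.frame with columns `start`, `end` (0-based
#'   half-open genome intervals), ordered 5'->3' in transcript
#'   orientation.
#' @param cds_end_tx transcript coordinate (0-based) of the first base
#'   of the annotated stop codon.
#' @param mrna optional spliced mRNA sequence (sense strand); filled by
#'   [splice_transcript()].
#' @return an object of class `transcript_model`.
#' @export
transcript_model <- function(transcript_id, gene_id = transcript_id, chrom,
                             strand = c("+", "-"), exons, cds_end_tx,
                             mrna = NULL) {
  strand <- match.arg(strand)
  exons <- as.data.frame(exons)[, c("start", "end")]
  if (any(exons$end <= exons$start))
    stop("annotation error: empty or inverted exon in ", transcript_id,
         call. = FALSE)
  gstart <- if (strand == "+") exons$start else rev(exons$start)
  if (is.unsorted(gstart, strictly = TRUE))
    stop("annotation error: exons of ", transcript_id,
         " not ordered 5'->3'", call. = FALSE)
  if (nrow(exons) > 1L) {
    o <- order(exons$start)
    if (any(exons$end[o][-nrow(exons)] > exons$start[o][-1L]))
      stop("annotation error: overlapping exons in ", transcript_id,
           call. = FALSE)
  }
  structure(list(transcript_id = transcript_id, gene_id = gene_id,
                 chrom = chrom, strand = strand, exons = exons,
                 cds_end_tx = as.integer(cds_end_tx), mrna = mrna),
            class = "transcript_model")
}

#' @export
print.transcript_model <- function(x, ...) {
  cat("<transcript_model>", x$transcript_id, "(", x$gene_id, ")",
      x$chrom, x$strand, nrow(x$exons), "exon(s),",
      sum(x$exons$end - x$exons$start), "nt; stop codon at tx",
      x$cds_end_tx, "\n")
  invisible(x)
}

#' Transcript-to-genome coordinate map
#'
#' @param model a [transcript_model()].
#' @return integer vector `m` with `m[i + 1]` the 0-based genome
#'   position of transcript position `i`; a bijection onto the exonic
#'   positions.
#' @export
transcript_coord_map <- function(model) {
  pos <- lapply(seq_len(nrow(model$exons)), function(i) {
    s <- model$exons$start[i]
    e <- model$exons$end[i]
    if (model$strand == "+") s:(e - 1L) else (e - 1L):s
  })
  as.integer(unlist(pos))
}

#' Splice a transcript out of the genome
#'
#' Extracts exon sequences, reverse-complementing on the minus strand,
#' and returns the mature mRNA together with the coordinate map.
#'
#' @param genome a named [Biostrings::DNAStringSet] (or FASTA path).
#' @param model a [transcript_model()].
#' @return list with `mrna` (character) and `coord_map` (see
#'   [transcript_coord_map()]).
#' @export
splice_transcript <- function(genome, model) {
  genome <- as_genome(genome)
  if (!model$chrom %in% names(genome))
    stop("annotation error: chromosome ", model$chrom, " not in genome",
         call. = FALSE)
  chrom_seq <- genome[[model$chrom]]
  if (max(model$exons$end) > length(chrom_seq))
    stop("annotation error: exon beyond end of ", model$chrom,
         call. = FALSE)
  pieces <- lapply(seq_len(nrow(model$exons)), function(i) {
    s <- Biostrings::subseq(chrom_seq, model$exons$start[i] + 1L,
                            model$exons$end[i])
    if (model$strand == "-") s <- Biostrings::reverseComplement(s)
    as.character(s)
  })
  list(mrna = paste(unlist(pieces), collapse = ""),
       coord_map = transcript_coord_map(model))
}

as_genome <- function(genome) {
  if (is.character(genome) && length(genome) == 1L)
    genome <- Biostrings::readDNAStringSet(genome)
  if (!methods::is(genome, "DNAStringSet"))
    stop("genome must be a DNAStringSet or FASTA path", call. = FALSE)
  names(genome) <- sub("\\s.*$", "", names(genome))
  genome
}

codon_at <- function(seq, pos0) substr(seq, pos0 + 1L, pos0 + 3L)

#' Find the putative readthrough region of a transcript
#'
#' Scans successive codons strictly downstream of the annotated stop
#' codon, in the annotated frame, over the mature mRNA. The region runs
#' from the first base after the annotated stop to the base before the
#' first in-frame TAA/TAG/TGA encountered; both stop codons are
#' excluded. If no downstream stop exists before the transcript end the
#' region extends to the last complete codon and the status is
#' `no_downstream_stop`.
#'
#' @param model a [transcript_model()] with `mrna` filled (see
#'   [splice_transcript()]).
#' @return an object of class `readthrough_region`: transcript interval
#'   (0-based half-open), length, sequence, status, and (when exons are
#'   present) the exon-aware genome intervals.
#' @export
find_readthrough_region <- function(model) {
  mrna <- model$mrna
  if (is.null(mrna))
    stop("annotation error: model has no mRNA sequence; splice it first",
         call. = FALSE)
  L <- nchar(mrna)
  if (L < model$cds_end_tx + 3L)
    stop("annotation error: mRNA shorter than annotated stop codon",
         call. = FALSE)
  if (!codon_at(mrna, model$cds_end_tx) %in% STOP_CODONS)
    stop("annotation error: codon at cds_end_tx of ", model$transcript_id,
         " is not a stop codon", call. = FALSE)
  start <- model$cds_end_tx + 3L
  pos <- start
  status <- "no_downstream_stop"
  while (pos + 3L <= L) {
    if (codon_at(mrna, pos) %in% STOP_CODONS) {
      status <- "ok"
      break
    }
    pos <- pos + 3L
  }
  end <- if (status == "ok") pos else start + 3L * ((L - start) %/% 3L)
  gi <- if (!is.null(model$exons) && end > start)
    project_to_genome(model, start, end) else NULL
  structure(list(transcript_id = model$transcript_id,
                 gene_id = model$gene_id,
                 tx_start = start, tx_end = end,
                 length_nt = end - start,
                 seq = substr(mrna, start + 1L, end),
                 next_stop = if (status == "ok") codon_at(mrna, pos) else NA_character_,
                 genome_intervals = gi,
                 mean_score = NA_real_, coverage = NA_real_,
                 status = status),
            class = "readthrough_region")
}

# project a transcript interval [tx_start, tx_end) onto the genome as a
# set of 0-based half-open intervals (one per run of adjacent bases)
project_to_genome <- function(model, tx_start, tx_end) {
  map <- transcript_coord_map(model)
  pos <- sort(map[(tx_start + 1L):tx_end])
  run <- cumsum(c(1L, diff(pos) != 1L))
  starts <- tapply(pos, run, min)
  ends <- tapply(pos, run, max) + 1L
  data.frame(chrom = model$chrom, start = as.integer(starts),
             end = as.integer(ends), row.names = NULL)
}

#' @export
print.readthrough_region <- function(x, ...) {
  cat("<readthrough_region>", x$transcript_id, "status:", x$status,
      sprintf("[%d,%d) %d nt", x$tx_start, x$tx_end, x$length_nt), "\n")
  if (!is.na(x$mean_score))
    cat("  mean conservation", signif(x$mean_score, 4),
        sprintf("(coverage %.2f)", x$coverage), "\n")
  invisible(x)
}

#' Score a readthrough region by mean per-base conservation
#'
#' Averages the conservation track over the genome positions of the
#' region. Positions absent from the track are excluded from the mean
#' (not imputed); when the covered fraction falls below `min_coverage`
#' the status becomes `low_coverage` and no mean is reported.
#'
#' @param region a `readthrough_region` with genome intervals.
#' @param track a [conservation_track()] (or object coercible to one).
#' @param min_coverage minimum fraction of region bases with a track
#'   value.
#' @return the region, with `mean_score`, `coverage` and `status`
#'   updated.
#' @export
mean_conservation <- function(region, track, min_coverage = 0.8) {
  track <- as_conservation_track(track)
  if (region$status != "ok") return(region)
  gi <- region$genome_intervals
  if (is.null(gi) || region$length_nt == 0L) {
    region$status <- "low_coverage"
    return(region)
  }
  vals <- unlist(lapply(seq_len(nrow(gi)), function(i) {
    v <- track$scores[[gi$chrom[i]]]
    idx <- (gi$start[i] + 1L):gi$end[i]
    if (is.null(v)) rep(NA_real_, length(idx)) else v[idx]
  }))
  covered <- !is.na(vals)
  region$coverage <- mean(covered)
  if (!any(covered) || region$coverage < min_coverage) {
    region$status <- "low_coverage"
    region$mean_score <- NA_real_
  } else {
    region$mean_score <- mean(vals[covered])
  }
  region
}

#' Per-base conservation track
#'
#' Sparse per-base scores in `[0, 1]` (as for PhastCons), stored as one
#' NA-filled numeric vector per chromosome, 0-based positions.
#'
#' @param x a data.frame with columns `chrom`, `start`, `end`, `score`
#'   (0-based half-open), or a `GRanges` with a `score` column.
#' @return an object of class `conservation_track`.
#' @export
conservation_track <- function(x) {
  if (methods::is(x, "GRanges")) {
    x <- data.frame(chrom = as.character(GenomicRanges::seqnames(x)),
                    start = GenomicRanges::start(x) - 1L,
                    end = GenomicRanges::end(x),
                    score = S4Vectors::mcols(x)$score)
  }
  if (any(x$score < 0 | x$score > 1))
    stop("input error: track scores must lie in [0, 1]", call. = FALSE)
  scores <- lapply(split(x, x$chrom), function(d) {
    v <- rep(NA_real_, max(d$end))
    for (i in seq_len(nrow(d))) v[(d$start[i] + 1L):d$end[i]] <- d$score[i]
    v
  })
  structure(list(scores = scores), class = "conservation_track")
}

as_conservation_track <- function(x) {
  if (inherits(x, "conservation_track")) return(x)
  if (is.character(x) && length(x) == 1L) return(read_track(x))
  conservation_track(x)
}

#' Read a conservation track from bedGraph (or bigWig)
#'
#' @param path path to a bedGraph file; bigWig is accepted when the
#'   extension is `.bw`/`.bigWig`.
#' @return a [conservation_track()].
#' @export
read_track <- function(path) {
  ext <- tolower(tools::file_ext(path))
  gr <- if (ext %in% c("bw", "bigwig"))
    rtracklayer::import(path, format = "BigWig")
  else rtracklayer::import(path, format = "bedGraph")
  conservation_track(gr)
}

#' Read transcript models from a BED12 file
#'
#' Blocks become exons; the thick (CDS) interval, which includes the
#' stop codon, locates the annotated stop. 0-based half-open
#' coordinates are kept throughout.
#'
#' @param path BED12 file path.
#' @return list of [transcript_model()] objects (mRNA not yet spliced).
#' @export
read_bed12 <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  if (anyDuplicated(S4Vectors::mcols(gr)$name))
    stop("input error: duplicate transcript ids in ", path, call. = FALSE)
  lapply(seq_along(gr), function(i) {
    g <- gr[i]
    strand <- as.character(BiocGenerics::strand(g))
    tx_start0 <- GenomicRanges::start(g) - 1L
    blocks <- S4Vectors::mcols(g)$blocks[[1L]]  # 1-based, relative to tx start
    exons <- data.frame(start = tx_start0 + BiocGenerics::start(blocks) - 1L,
                        end = tx_start0 + BiocGenerics::end(blocks))
    if (strand == "-") exons <- exons[rev(seq_len(nrow(exons))), , drop = FALSE]
    thick <- S4Vectors::mcols(g)$thick
    thick_start0 <- BiocGenerics::start(thick)[1L] - 1L
    thick_end0 <- BiocGenerics::end(thick)[1L]
    model <- transcript_model(
      transcript_id = S4Vectors::mcols(g)$name,
      chrom = as.character(GenomicRanges::seqnames(g)),
      strand = strand, exons = exons, cds_end_tx = 0L)
    # the thick (CDS) interval includes the stop codon; its 3'-most
    # base (transcript orientation) is exonic even when the stop spans
    # an exon junction, so the stop start is that base's tx coord - 2
    stop_last_g <- if (strand == "+") thick_end0 - 1L else thick_start0
    map <- transcript_coord_map(model)
    t_last <- match(stop_last_g, map) - 1L
    if (is.na(t_last) || t_last < 2L)
      stop("annotation error: stop codon of ", model$transcript_id,
           " not on an exon", call. = FALSE)
    model$cds_end_tx <- as.integer(t_last - 2L)
    model
  })
}

#' Read transcript models from a GTF file
#'
#' Consumes `exon` and `stop_codon` features; transcripts without a
#' `stop_codon` feature are dropped with a warning. GTF 1-based closed
#' coordinates are converted to the package's 0-based half-open
#' convention on read.
#'
#' @param path GTF file path.
#' @return list of [transcript_model()] objects.
#' @export
read_gtf_models <- function(path) {
  gr <- rtracklayer::import(path, format = "GTF")
  md <- S4Vectors::mcols(gr)
  keep <- md$type %in% c("exon", "stop_codon")
  gr <- gr[keep]
  md <- S4Vectors::mcols(gr)
  out <- lapply(split(seq_along(gr), md$transcript_id), function(idx) {
    sub <- gr[idx]
    typ <- S4Vectors::mcols(sub)$type
    ex <- sub[typ == "exon"]
    sc <- sub[typ == "stop_codon"]
    if (length(sc) == 0L) return(NULL)
    strand <- as.character(BiocGenerics::strand(ex)[1L])
    exons <- data.frame(start = GenomicRanges::start(ex) - 1L,
                        end = GenomicRanges::end(ex))
    exons <- exons[order(exons$start, decreasing = strand == "-"), ,
                   drop = FALSE]
    gid <- S4Vectors::mcols(ex)$gene_id[1L]
    model <- transcript_model(
      transcript_id = S4Vectors::mcols(ex)$transcript_id[1L],
      gene_id = if (is.null(gid)) NA_character_ else gid,
      chrom = as.character(GenomicRanges::seqnames(ex)[1L]),
      strand = strand, exons = exons, cds_end_tx = 0L)
    stop_g <- if (strand == "+") min(GenomicRanges::start(sc)) - 1L
      else max(GenomicRanges::end(sc)) - 1L
    tx <- match(stop_g, transcript_coord_map(model)) - 1L
    if (is.na(tx)) {
      warning("stop codon of ", model$transcript_id, " not on an exon; dropped")
      return(NULL)
    }
    model$cds_end_tx <- as.integer(tx)
    model
  })
  out <- Filter(Negate(is.null), out)
  unname(out)
}

#' Genome-wide readthrough-region scan
#'
#' Runs [splice_transcript()], [find_readthrough_region()] and
#' [mean_conservation()] over every transcript, and summarises the
#' distribution of mean conservation scores as a histogram.
#'
#' @param annotation BED12 path or a list of [transcript_model()]s.
#' @param genome FASTA path or [Biostrings::DNAStringSet].
#' @param track bedGraph path, [conservation_track()], or `NULL` to
#'   skip scoring.
#' @param min_coverage minimum track coverage for a region to be
#'   scored (see [mean_conservation()]).
#' @param bin_width histogram bin width on the score axis.
#' @param conserved_threshold report-time threshold above which a
#'   region is flagged `highly_conserved`.
#' @param highlight optional transcript ids flagged in the table.
#' @return list with `regions` (one row per transcript) and
#'   `histogram` (proportions over status-ok regions, summing to 1).
#' @export
scan_readthrough <- function(annotation, genome, track = NULL,
                             min_coverage = 0.8, bin_width = 0.05,
                             conserved_threshold = 0.5, highlight = NULL) {
  models <- if (is.character(annotation)) read_bed12(annotation)
    else annotation
  ids <- vapply(models, `[[`, character(1), "transcript_id")
  if (anyDuplicated(ids))
    stop("input error: duplicate transcript ids", call. = FALSE)
  genome <- as_genome(genome)
  if (!is.null(track)) track <- as_conservation_track(track)
  regions <- lapply(models, function(m) {
    if (is.null(m$mrna)) m$mrna <- splice_transcript(genome, m)$mrna
    r <- find_readthrough_region(m)
    if (!is.null(track) && r$status == "ok")
      r <- mean_conservation(r, track, min_coverage)
    r
  })
  fmt_gi <- function(gi) {
    if (is.null(gi)) return(NA_character_)
    paste(sprintf("%s:%d-%d", gi$chrom, gi$start, gi$end), collapse = ",")
  }
  tab <- data.frame(
    transcript_id = ids,
    gene_id = vapply(regions, `[[`, character(1), "gene_id"),
    status = vapply(regions, `[[`, character(1), "status"),
    length_nt = vapply(regions, `[[`, integer(1), "length_nt"),
    coverage = vapply(regions, `[[`, numeric(1), "coverage"),
    mean_score = vapply(regions, `[[`, numeric(1), "mean_score"),
    genome_intervals = vapply(regions, function(r) fmt_gi(r$genome_intervals),
                              character(1)),
    row.names = NULL)
  tab$highly_conserved <- !is.na(tab$mean_score) &
    tab$mean_score >= conserved_threshold
  if (!is.null(highlight)) tab$highlight <- tab$transcript_id %in% highlight
  ok <- tab$status == "ok" & !is.na(tab$mean_score)
  breaks <- seq(0, 1, by = bin_width)
  h <- graphics::hist(tab$mean_score[ok], breaks = breaks, plot = FALSE)
  histogram <- data.frame(bin_start = head(breaks, -1L),
                          bin_end = breaks[-1L],
                          count = h$counts,
                          proportion = if (sum(h$counts) > 0)
                            h$counts / sum(h$counts) else h$counts)
  list(regions = tab, histogram = histogram)
}

#' Translate a readthrough extension
#'
#' Standard genetic code; the input must be a stop-free codon run (as
#' produced by [find_readthrough_region()]).
#'
#' @param seq nucleotide string, length divisible by 3.
#' @return amino-acid string.
#' @export
translate_extension <- function(seq) {
  if (nchar(seq) == 0L) return("")
  if (nchar(seq) %% 3L != 0L)
    stop("input error: sequence length not divisible by 3", call. = FALSE)
  # no.init.codon: this is internal sequence, not a translation start
  aa <- as.character(Biostrings::translate(Biostrings::DNAString(seq),
                                           no.init.codon = TRUE))
  if (grepl("\\*", aa, fixed = FALSE))
    stop("invariant violation: internal stop codon in readthrough region",
         call. = FALSE)
  aa
}
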