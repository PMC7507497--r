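# Independent oracles and small fixture builders used across tests.

STOPS <- c("TAA", "TAG", "TGA")

# naive single-pass codon scanner: position (0-based) of the first
# in-frame stop at or after `from`, or NA
naive_next_stop <- function(seq, from) {
  p <- from
  while (p + 3 <= nchar(seq)) {
    if (substr(seq, p + 1, p + 3) %in% STOPS) return(p)
    p <- p + 3
  }
  NA_integer_
}

# per-codon translation via the standard code table (independent of
# Biostrings::translate, which the implementation uses)
oracle_translate <- function(seq) {
  if (nchar(seq) == 0) return("")
  code <- Biostrings::GENETIC_CODE
  cods <- substring(seq, seq(1, nchar(seq) - 2, 3), seq(3, nchar(seq), 3))
  paste(vapply(cods, function(cd) unname(code[cd]), character(1)),
        collapse = "")
}

# a random mRNA with a valid annotated stop at a random position;
# downstream content is fully random (may or may not contain a stop)
random_mrna <- function(min_tail = 0, max_tail = 150) {
  utr5 <- sample(0:10, 1)
  n_cds <- sample(5:20, 1)
  tail_len <- sample(min_tail:max_tail, 1)
  bases <- c("A", "C", "G", "T")
  mrna <- paste0(
    paste(sample(bases, utr5, replace = TRUE), collapse = ""),
    paste(sample(setdiff(as.vector(outer(outer(bases, bases, paste0),
                                         bases, paste0)), STOPS),
                 n_cds, replace = TRUE), collapse = ""),
    sample(STOPS, 1),
    paste(sample(bases, tail_len, replace = TRUE), collapse = ""))
  list(mrna = mrna, cds_end_tx = utr5 + 3 * n_cds)
}

# single-exon plus-strand model wrapping a bare mRNA
mrna_model <- function(mrna, cds_end_tx, id = "T1") {
  transcript_model(id, chrom = "chr1", strand = "+",
                   exons = data.frame(start = 0, end = nchar(mrna)),
                   cds_end_tx = cds_end_tx, mrna = mrna)
}

# intersection-over-union of two logical masks
iou <- function(a, b) sum(a & b) / sum(a | b)

# by-hand two-column alignment fixture
toy_alignment <- function(...) species_alignment(c(...))
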