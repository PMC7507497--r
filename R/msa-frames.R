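#' Multi-species alignment of a readthrough region
#'
#' Aligned nucleotide records (gaps as `-`), one per species, with a
#' designated reference whose gap-stripped length must be divisible by
#' 3; the reference defines the codon frame for all frame analyses.
#'
#' @param records named character vector of equal-length aligned
#'   strings.
#' @param reference name of the reference species (default: first
#'   record).
#' @return an object of class `species_alignment`.
#' @export
species_alignment <- function(records, reference = names(records)[1L]) {
  records <- toupper(records)
  if (is.null(names(records)) || any(names(records) == ""))
    stop("input error: alignment records must be named", call. = FALSE)
  if (length(unique(nchar(records))) != 1L)
    stop("input error: aligned records differ in length", call. = FALSE)
  if (!reference %in% names(records))
    stop("input error: reference ", reference, " not among records",
         call. = FALSE)
  ref_len <- nchar(gsub("-", "", records[[reference]]))
  if (ref_len %% 3L != 0L)
    stop("input error: reference gap-stripped length not divisible by 3",
         call. = FALSE)
  structure(list(records = records, reference = reference),
            class = "species_alignment")
}

#' Read an aligned FASTA into a species alignment
#'
#' @param path aligned FASTA path (one record per species).
#' @param reference reference species name; default the first record.
#' @return a [species_alignment()].
#' @export
read_alignment <- function(path, reference = NULL) {
  ss <- Biostrings::readBStringSet(path)
  records <- stats::setNames(as.character(ss), sub("\\s.*$", "", names(ss)))
  if (is.null(reference)) reference <- names(records)[1L]
  species_alignment(records, reference)
}

aln_matrix <- function(aln) {
  do.call(rbind, lapply(aln$records, function(x) strsplit(x, "")[[1L]]))
}

#' Reference codon columns
#'
#' Alignment columns grouped into reference-frame codons; columns where
#' the reference is gapped belong to no codon.
#'
#' @param aln a [species_alignment()].
#' @return integer matrix, one row per codon, three column indices
#'   (1-based) per row, ordered 5'->3'.
#' @export
reference_codon_columns <- function(aln) {
  ref <- strsplit(aln$records[[aln$reference]], "")[[1L]]
  cols <- which(ref != "-")
  if (length(cols) %% 3L != 0L)
    stop("input error: reference frame violation", call. = FALSE)
  matrix(cols, ncol = 3L, byrow = TRUE)
}

#' Count nonsense codons per species
#'
#' A codon counts as nonsense for a species iff its three
#' reference-frame columns are gap-free in that species and spell
#' TAA/TAG/TGA. Partially gapped codons are skipped, not guessed.
#'
#' @param aln a [species_alignment()].
#' @return named integer vector, one count per species (reference
#'   included; expected 0 there).
#' @export
count_nonsense <- function(aln) {
  trip <- reference_codon_columns(aln)
  m <- aln_matrix(aln)
  vapply(rownames(m), function(sp) {
    n <- 0L
    for (k in seq_len(nrow(trip))) {
      cc <- m[sp, trip[k, ]]
      if (any(cc == "-")) next
      if (paste(cc, collapse = "") %in% STOP_CODONS) n <- n + 1L
    }
    n
  }, integer(1))
}

#' Classify indel events per species
#'
#' Relative to the reference: a deletion is a maximal run of columns
#' gapped in the species but not in the reference; an insertion is a
#' maximal run gapped in the reference but not in the species. An
#' event is frame-preserving iff its length is a multiple of 3.
#'
#' @param aln a [species_alignment()].
#' @return named list (per non-reference species) of data.frames with
#'   columns `start_col` (1-based), `length_nt`, `kind`,
#'   `frame_preserving`; zero-row data.frames when a species has no
#'   events.
#' @export
classify_indels <- function(aln) {
  m <- aln_matrix(aln)
  ref <- m[aln$reference, ]
  runs_of <- function(flag) {
    if (!any(flag)) return(NULL)
    r <- rle(flag)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    data.frame(start_col = starts[r$values], length_nt = r$lengths[r$values])
  }
  species <- setdiff(rownames(m), aln$reference)
  out <- lapply(species, function(sp) {
    s <- m[sp, ]
    del <- runs_of(s == "-" & ref != "-")
    ins <- runs_of(s != "-" & ref == "-")
    ev <- rbind(
      if (!is.null(del)) cbind(del, kind = "deletion"),
      if (!is.null(ins)) cbind(ins, kind = "insertion"))
    if (is.null(ev))
      ev <- data.frame(start_col = integer(0), length_nt = integer(0),
                       kind = character(0))
    ev <- ev[order(ev$start_col), , drop = FALSE]
    ev$frame_preserving <- ev$length_nt %% 3L == 0L
    rownames(ev) <- NULL
    ev
  })
  stats::setNames(out, species)
}

#' Frame report for a readthrough-region alignment
#'
#' Aggregates nonsense counts and indel events; a species' frame is
#' intact iff it has no nonsense codon and every indel is
#' frame-preserving. The reference species is reported too (it has no
#' indel events relative to itself).
#'
#' @param aln a [species_alignment()].
#' @return list with `per_species` (data.frame: species,
#'   nonsense_count, n_indels, frame_intact), `indel_events`, and
#'   `summary` (n_species, n_species_frame_intact, total_nonsense,
#'   total_indels).
#' @export
frame_report <- function(aln) {
  ns <- count_nonsense(aln)
  indels <- classify_indels(aln)
  species <- names(aln$records)
  n_ind <- function(sp) if (sp == aln$reference) 0L else nrow(indels[[sp]])
  intact <- function(sp) {
    if (sp == aln$reference) return(ns[[sp]] == 0L)
    ns[[sp]] == 0L && all(indels[[sp]]$frame_preserving)
  }
  per <- data.frame(
    species = species,
    nonsense_count = as.integer(ns[species]),
    n_indels = vapply(species, n_ind, integer(1)),
    frame_intact = vapply(species, intact, logical(1)),
    row.names = NULL)
  list(per_species = per, indel_events = indels,
       summary = list(n_species = length(species),
                      n_species_frame_intact = sum(per$frame_intact),
                      total_nonsense = sum(per$nonsense_count),
                      total_indels = sum(per$n_indels)))
}

#' Translate an alignment at codon resolution
#'
#' Per species and per reference-frame codon: any gapped column renders
#' `-`, stop codons render `*`, otherwise the standard genetic code.
#' Columns where the reference is gapped (insertions) are skipped, so
#' the output is aligned at codon resolution.
#'
#' @param aln a [species_alignment()].
#' @return named character vector of equal-length amino-acid strings.
#' @export
translate_alignment <- function(aln) {
  trip <- reference_codon_columns(aln)
  m <- aln_matrix(aln)
  code <- Biostrings::GENETIC_CODE
  vapply(rownames(m), function(sp) {
    aa <- vapply(seq_len(nrow(trip)), function(k) {
      cc <- m[sp, trip[k, ]]
      if (any(cc == "-")) return("-")
      codon <- paste(cc, collapse = "")
      if (codon %in% STOP_CODONS) "*"
      else if (codon %in% names(code)) unname(code[codon])
      else "X"  # ambiguous bases
    }, character(1))
    paste(aa, collapse = "")
  }, character(1))
}
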