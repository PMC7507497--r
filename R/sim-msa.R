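#' Generate a multi-species alignment of a readthrough region
#'
#' The reference species carries a stop-free codon sequence (no
#' internal in-frame stop). Non-reference species are derived from it
#' by per-site substitutions that never create an in-frame stop codon;
#' configured nonsense codons and indels are then injected at known
#' positions so downstream frame analysis can be checked against
#' ground truth.
#'
#' Presets:
#' * `"custom"` — substitutions at `config$subst_rate` plus the
#'   injections listed in the config.
#' * `"tarsier_like"` — one non-reference species ("tarsier") carries a
#'   single codon-aligned 3-nt deletion; no nonsense codons. This
#'   mirrors the classic vertebrate readthrough-region alignment in
#'   which the only event is a frame-preserving 3-nt deletion in
#'   Tarsiers.
#'
#' @param config a [sim_config()]; `n_species`, `subst_rate`,
#'   `nonsense_injections` and `indel_injections` are used.
#' @param preset `"custom"` or `"tarsier_like"`.
#' @param n_codons reference length in codons (default 33, the length
#'   of the AGO1 C-terminal extension).
#' @param reference_seq optional explicit reference nucleotide string
#'   (stop-free, length divisible by 3); overrides `n_codons`.
#' @param dir optional output directory; writes `alignment.fa`
#'   (aligned FASTA, reference first).
#' @return list with `alignment` (a [species_alignment()]) and `truth`
#'   (planted nonsense and indel events), plus `alignment_file` when
#'   `dir` is given.
#' @export
gen_msa <- function(config, preset = c("custom", "tarsier_like"),
                    n_codons = 33L, reference_seq = NULL, dir = NULL) {
  validate_sim_config(config)
  preset <- match.arg(preset)
  sim_seed(config, "msa")
  if (is.null(reference_seq)) reference_seq <- random_orf(n_codons)
  if (nchar(reference_seq) %% 3L != 0L)
    stop("configuration error: reference length not divisible by 3",
         call. = FALSE)
  n_codons <- nchar(reference_seq) %/% 3L

  n_sp <- max(config$n_species, 2L)
  species <- c("human", if (preset == "tarsier_like" && n_sp >= 2L) "tarsier",
               sprintf("species_%02d", seq_len(n_sp)))[seq_len(n_sp)]
  ref <- species[1L]

  rows <- stats::setNames(rep(reference_seq, n_sp), species)
  bases <- c("A", "C", "G", "T")

  # per-site substitutions that never spell an in-frame stop codon
  for (sp in species[-1L]) {
    s <- strsplit(rows[[sp]], "")[[1L]]
    hit <- which(runif(length(s)) < config$subst_rate)
    for (p in hit) {
      alt <- sample(setdiff(bases, s[p]))
      for (b in alt) {
        cand <- s
        cand[p] <- b
        ci <- (p - 1L) %/% 3L
        codon <- paste(cand[(3L * ci + 1L):(3L * ci + 3L)], collapse = "")
        if (!codon %in% STOP_CODONS) {
          s <- cand
          break
        }
      }
    }
    rows[[sp]] <- paste(s, collapse = "")
  }

  nonsense <- config$nonsense_injections
  indels <- config$indel_injections
  if (preset == "tarsier_like") {
    del_codon <- sample(seq_len(n_codons), 1L)
    nonsense <- list()
    indels <- list(list(species = "tarsier", codon = del_codon,
                        len = 3L, kind = "deletion"))
  }

  # injections are applied deletions -> nonsense -> insertions, so a
  # nonsense injection can be validated against deletion gaps and codon
  # column indices are not shifted by insertions
  aln <- lapply(rows, function(x) strsplit(x, "")[[1L]])
  planted <- list()
  kind_of <- function(inj) if (is.null(inj$kind)) "deletion" else inj$kind
  check_species <- function(sp) {
    if (!sp %in% species)
      stop("configuration error: unknown species ", sp, call. = FALSE)
  }

  for (inj in Filter(function(x) kind_of(x) == "deletion", indels)) {
    check_species(inj$species)
    len <- as.integer(inj$len)
    start_col <- 3L * (inj$codon - 1L) + 1L
    cols <- start_col:(start_col + len - 1L)
    if (max(cols) > length(aln[[inj$species]]))
      stop("configuration error: deletion extends past alignment end",
           call. = FALSE)
    aln[[inj$species]][cols] <- "-"
    planted <- c(planted, list(list(species = inj$species,
                                    start_col = start_col,
                                    length_nt = len, kind = "deletion")))
  }

  # nonsense injections: overwrite the reference-frame codon with TAG
  for (inj in nonsense) {
    check_species(inj$species)
    cols <- (3L * (inj$codon - 1L) + 1L):(3L * (inj$codon - 1L) + 3L)
    if (any(aln[[inj$species]][cols] == "-"))
      stop("configuration error: nonsense injection at a gap position",
           call. = FALSE)
    aln[[inj$species]][cols] <- c("T", "A", "G")
  }

  # insertions add columns gapped in every other species (including
  # the reference)
  for (inj in Filter(function(x) kind_of(x) == "insertion", indels)) {
    check_species(inj$species)
    len <- as.integer(inj$len)
    start_col <- 3L * (inj$codon - 1L) + 1L
    ins <- sample(bases, len, replace = TRUE)
    aln <- stats::setNames(lapply(names(aln), function(nm)
      append(aln[[nm]], if (nm == inj$species) ins else rep("-", len),
             after = start_col - 1L)), names(aln))
    planted <- c(planted, list(list(species = inj$species,
                                    start_col = start_col,
                                    length_nt = len, kind = "insertion")))
  }

  records <- vapply(aln, paste, character(1), collapse = "")
  alignment <- species_alignment(records, reference = ref)
  truth <- list(planted_nonsense = nonsense, planted_indels = planted,
                reference_seq = reference_seq)
  out <- list(alignment = alignment, truth = truth)
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    out$alignment_file <- file.path(dir, "alignment.fa")
    write_alignment(alignment, out$alignment_file)
  }
  out
}

#' Write an alignment as aligned FASTA (reference record first)
#' @param aln a [species_alignment()].
#' @param path output file.
#' @export
write_alignment <- function(aln, path) {
  ord <- c(aln$reference, setdiff(names(aln$records), aln$reference))
  writeLines(as.vector(rbind(paste0(">", ord), unname(aln$records[ord]))),
             path)
}
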