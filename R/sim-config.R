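#' Configuration for the synthetic-data generators
#'
#' One configuration object drives every generator in the package:
#' transcriptome + conservation track, readthrough-region multiple
#' alignments, two-assay count matrices, and 3D image stacks. All
#' randomness flows from `seed`; each generator draws from its own
#' stream (a fixed offset of `seed`), so regenerating one data type
#' never perturbs another.
#'
#' @param seed integer; master seed for all generator streams.
#' @param n_transcripts number of transcripts in the synthetic genome.
#' @param frac_conserved_tr fraction of transcripts whose readthrough
#'   region is planted as highly conserved.
#' @param frac_no_stop fraction of transcripts deliberately lacking a
#'   downstream in-frame stop codon.
#' @param conserved_score_range,background_score_range score ranges (in
#'   `[0,1]`, as for PhastCons) from which planted-conserved and
#'   background per-base conservation values are drawn.
#' @param track_dropout fraction of exonic bases with no track value.
#' @param n_species number of species in generated alignments
#'   (including the reference).
#' @param subst_rate per-site substitution probability for non-reference
#'   species in generated alignments.
#' @param nonsense_injections list of `list(species=, codon=)` entries:
#'   plant a stop codon (TAG) at that reference-frame codon.
#' @param indel_injections list of `list(species=, codon=, len=, kind=)`
#'   entries (`kind` is `"deletion"` or `"insertion"`, `len` in nt).
#' @param n_genes,n_reps genes and replicates per condition for the
#'   count simulator (conditions: control, mutant1, mutant2; assays:
#'   total, dsrna).
#' @param nb_dispersion negative-binomial dispersion; variance is
#'   `mu + mu^2 * dispersion`.
#' @param mean_log_mu,mean_log_sd log-normal parameters of baseline
#'   expression means.
#' @param lfc_sd SD of the per-gene true log2 fold change of each
#'   mutant versus control (shared between assays for unplanted genes).
#' @param frac_enriched,frac_depleted fractions of genes planted as
#'   dsRNA-enriched / depleted.
#' @param enrichment_lfc_shift log2 shift added to (subtracted from)
#'   the dsRNA fold change of planted enriched (depleted) genes, shared
#'   between the two mutants.
#' @param gc_low,gc_high centres of the G/C proportion distributions of
#'   background and planted genes.
#' @param n_cells number of nuclei per synthetic image stack.
#' @param stack_shape integer triple `(z, y, x)` of the image stacks.
#' @param nucleolar_factor mean signal intensity in nucleoli divided by
#'   the mean in the nucleoplasm, before noise.
#' @param noise_sd SD of additive Gaussian intensity noise (intensities
#'   live in `[0,1]` before 16-bit quantisation).
#' @param foci_per_cell planted foci per cell: a single integer or a
#'   `list(lambda=)` Poisson spec.
#' @param foci_min_sep minimum pairwise separation of planted foci
#'   centres, pixels in projection.
#'
#' @return an object of class `sim_config` (a validated list).
#' @export
sim_config <- function(seed = 1L,
                       n_transcripts = 100L,
                       frac_conserved_tr = 0.05,
                       frac_no_stop = 0.05,
                       conserved_score_range = c(0.8, 1),
                       background_score_range = c(0.02, 0.4),
                       track_dropout = 0.05,
                       n_species = 20L,
                       subst_rate = 0.02,
                       nonsense_injections = list(),
                       indel_injections = list(),
                       n_genes = 2000L,
                       n_reps = 3L,
                       nb_dispersion = 0.05,
                       mean_log_mu = log(200),
                       mean_log_sd = 1,
                       lfc_sd = 0.5,
                       frac_enriched = 0.01,
                       frac_depleted = 0.01,
                       enrichment_lfc_shift = 2,
                       gc_low = 0.4,
                       gc_high = 0.6,
                       n_cells = 20L,
                       stack_shape = c(16L, 256L, 256L),
                       nucleolar_factor = 3,
                       noise_sd = 0.02,
                       foci_per_cell = 3L,
                       foci_min_sep = 6) {
  cfg <- list(
    seed = as.integer(seed),
    n_transcripts = as.integer(n_transcripts),
    frac_conserved_tr = frac_conserved_tr,
    frac_no_stop = frac_no_stop,
    conserved_score_range = conserved_score_range,
    background_score_range = background_score_range,
    track_dropout = track_dropout,
    n_species = as.integer(n_species),
    subst_rate = subst_rate,
    nonsense_injections = nonsense_injections,
    indel_injections = indel_injections,
    n_genes = as.integer(n_genes),
    n_reps = as.integer(n_reps),
    nb_dispersion = nb_dispersion,
    mean_log_mu = mean_log_mu,
    mean_log_sd = mean_log_sd,
    lfc_sd = lfc_sd,
    frac_enriched = frac_enriched,
    frac_depleted = frac_depleted,
    enrichment_lfc_shift = enrichment_lfc_shift,
    gc_low = gc_low,
    gc_high = gc_high,
    n_cells = as.integer(n_cells),
    stack_shape = as.integer(stack_shape),
    nucleolar_factor = nucleolar_factor,
    noise_sd = noise_sd,
    foci_per_cell = foci_per_cell,
    foci_min_sep = foci_min_sep
  )
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  prop <- function(x, what) {
    if (!is.numeric(x) || any(x < 0) || any(x > 1))
      stop("configuration error: ", what, " must lie in [0, 1]", call. = FALSE)
  }
  prop(cfg$frac_conserved_tr, "frac_conserved_tr")
  prop(cfg$frac_no_stop, "frac_no_stop")
  prop(cfg$track_dropout, "track_dropout")
  prop(cfg$conserved_score_range, "conserved_score_range")
  prop(cfg$background_score_range, "background_score_range")
  prop(cfg$subst_rate, "subst_rate")
  prop(cfg$frac_enriched, "frac_enriched")
  prop(cfg$frac_depleted, "frac_depleted")
  prop(cfg$gc_low, "gc_low")
  prop(cfg$gc_high, "gc_high")
  if (cfg$frac_enriched + cfg$frac_depleted >= 1)
    stop("configuration error: frac_enriched + frac_depleted must be < 1",
         call. = FALSE)
  if (cfg$nb_dispersion <= 0)
    stop("configuration error: nb_dispersion must be positive", call. = FALSE)
  if (cfg$nucleolar_factor <= 0)
    stop("configuration error: nucleolar_factor must be positive",
         call. = FALSE)
  if (length(cfg$stack_shape) != 3L || any(cfg$stack_shape < 1L))
    stop("configuration error: stack_shape must be three positive integers",
         call. = FALSE)
  if (cfg$n_transcripts < 1L)
    stop("configuration error: n_transcripts must be >= 1", call. = FALSE)
  invisible(cfg)
}

# Distinct RNG streams per generated data type so each output file is a
# deterministic function of (seed, config) alone.
sim_seed <- function(cfg, stream) {
  offsets <- c(transcriptome = 101L, msa = 211L, counts = 307L,
               stacks = 401L, foci = 503L)
  set.seed(cfg$seed + offsets[[stream]])
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config> seed =", x$seed, "\n")
  cat("  transcriptome:", x$n_transcripts, "transcripts,",
      sprintf("%.0f%% planted conserved", 100 * x$frac_conserved_tr), "\n")
  cat("  msa:", x$n_species, "species, subst_rate", x$subst_rate, "\n")
  cat("  counts:", x$n_genes, "genes x", x$n_reps,
      "reps; dispersion", x$nb_dispersion, "\n")
  cat("  stacks:", x$n_cells, "cells,", paste(x$stack_shape, collapse = "x"),
      "(z,y,x); nucleolar factor", x$nucleolar_factor, "\n")
  invisible(x)
}

# stop codons of the standard genetic code, used throughout
STOP_CODONS <- c("TAA", "TAG", "TGA")

# the 61 sense codons
sense_codons <- function() {
  b <- c("A", "C", "G", "T")
  all <- as.vector(outer(outer(b, b, paste0), b, paste0))
  setdiff(all, STOP_CODONS)
}

# n codons sampled uniformly from the sense codons, as one string
random_orf <- function(n) {
  paste(sample(sense_codons(), n, replace = TRUE), collapse = "")
}
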