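#' Simulate paired total RNA-seq and dsRNA-pulldown count matrices
#'
#' Counts are negative-binomial (variance `mu + mu^2 * dispersion`)
#' around condition means for two assays (total, dsrna) over three
#' conditions (control, mutant1, mutant2) with `n_reps` replicates
#' each. Every gene has a true mutant-vs-control log2 fold change
#' shared between assays, so dsRNA fold changes track total fold
#' changes linearly — except for a planted enriched (depleted) subset
#' whose dsRNA fold change is shifted by `+enrichment_lfc_shift`
#' (`-`), identically in both mutants. Planted genes draw their G/C
#' proportion around `gc_high`, background genes around `gc_low`.
#' Per-sample depth factors are drawn log-normally so size-factor
#' normalisation is exercised.
#'
#' @param config a [sim_config()].
#' @param dir optional output directory; writes `total_counts.tsv`,
#'   `dsrna_counts.tsv`, `samples.tsv` and `gene_gc.tsv`.
#' @return list with `total_counts` and `dsrna_counts` (integer
#'   matrices, genes x samples), `samples` (sample sheet data.frame),
#'   `gene_gc` (named numeric), and `truth` (enriched/depleted ids,
#'   true fold changes, depth factors).
#' @export
gen_counts <- function(config, dir = NULL) {
  validate_sim_config(config)
  if (config$n_reps < 2L)
    stop("configuration error: n_reps must be >= 2 (fold-change SD undefined)",
         call. = FALSE)
  sim_seed(config, "counts")
  ng <- config$n_genes
  nr <- config$n_reps
  genes <- sprintf("G%05d", seq_len(ng))

  n_enr <- round(config$frac_enriched * ng)
  n_dep <- round(config$frac_depleted * ng)
  planted <- sample(genes, n_enr + n_dep)
  enriched_ids <- sort(planted[seq_len(n_enr)])
  depleted_ids <- sort(planted[seq_len(n_dep) + n_enr])
  shift <- stats::setNames(numeric(ng), genes)
  shift[enriched_ids] <- config$enrichment_lfc_shift
  shift[depleted_ids] <- -config$enrichment_lfc_shift

  # baselines: shared expression scale; the pulldown has its own
  # gene-level capture efficiency (cancels in fold changes)
  mu_total <- stats::rlnorm(ng, config$mean_log_mu, config$mean_log_sd)
  capture <- stats::rlnorm(ng, 0, 0.5)
  mu_ds <- mu_total * capture

  # true mutant-vs-control log2 fold changes, shared between assays
  lfc <- cbind(mutant1 = stats::rnorm(ng, 0, config$lfc_sd),
               mutant2 = stats::rnorm(ng, 0, config$lfc_sd))

  conditions <- c("control", "mutant1", "mutant2")
  samples <- expand.grid(replicate = seq_len(nr), condition = conditions,
                         assay = c("total", "dsrna"),
                         KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  samples$sample <- sprintf("%s_%s_%d", samples$assay, samples$condition,
                            samples$replicate)
  samples <- samples[, c("sample", "assay", "condition", "replicate")]
  depth <- stats::setNames(stats::rlnorm(nrow(samples), 0, 0.2),
                           samples$sample)

  cond_mean <- function(assay, condition) {
    base <- if (assay == "total") mu_total else mu_ds
    if (condition == "control") return(base)
    fc <- 2^lfc[, condition]
    if (assay == "dsrna") fc <- fc * 2^shift
    base * fc
  }
  draw <- function(assay) {
    sub <- samples[samples$assay == assay, ]
    m <- vapply(seq_len(nrow(sub)), function(j) {
      mu <- cond_mean(assay, sub$condition[j]) * depth[[sub$sample[j]]]
      stats::rnbinom(ng, mu = mu, size = 1 / config$nb_dispersion)
    }, numeric(ng))
    dimnames(m) <- list(genes, sub$sample)
    storage.mode(m) <- "integer"
    m
  }
  total_counts <- draw("total")
  dsrna_counts <- draw("dsrna")

  # G/C proportions: tight Beta around the class centre
  conc <- 150
  gc <- stats::rbeta(ng, config$gc_low * conc, (1 - config$gc_low) * conc)
  is_planted <- genes %in% planted
  gc[is_planted] <- stats::rbeta(sum(is_planted), config$gc_high * conc,
                                 (1 - config$gc_high) * conc)
  gene_gc <- stats::setNames(gc, genes)

  truth <- list(enriched_ids = enriched_ids, depleted_ids = depleted_ids,
                true_lfc = lfc, true_shift = shift,
                mu_total = stats::setNames(mu_total, genes),
                mu_dsrna = stats::setNames(mu_ds, genes),
                depth = depth)
  out <- list(total_counts = total_counts, dsrna_counts = dsrna_counts,
              samples = samples, gene_gc = gene_gc, truth = truth)
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    write_counts <- function(m, path) {
      df <- data.frame(gene = rownames(m), m, check.names = FALSE)
      utils::write.table(df, path, sep = "\t", quote = FALSE,
                         row.names = FALSE)
    }
    out$total_file <- file.path(dir, "total_counts.tsv")
    out$dsrna_file <- file.path(dir, "dsrna_counts.tsv")
    out$samples_file <- file.path(dir, "samples.tsv")
    out$gc_file <- file.path(dir, "gene_gc.tsv")
    write_counts(total_counts, out$total_file)
    write_counts(dsrna_counts, out$dsrna_file)
    utils::write.table(samples, out$samples_file, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    utils::write.table(data.frame(gene = genes, gc = gene_gc),
                       out$gc_file, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  out
}

#' Read a genes-x-samples count matrix from TSV
#'
#' First column is the gene id; remaining columns are samples.
#' @param path TSV path.
#' @return integer matrix with gene rownames.
#' @export
read_counts <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  storage.mode(m) <- "integer"
  m
}
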