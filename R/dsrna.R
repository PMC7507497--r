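#' Median-of-ratios size factors
#'
#' Per-sample scaling factors computed as the median of gene-wise
#' ratios to the geometric-mean pseudo-reference, over genes with a
#' nonzero count in every sample.
#'
#' @param counts genes x samples matrix of nonnegative counts.
#' @return named numeric vector of positive factors.
#' @export
size_factors <- function(counts) {
  keep <- rowSums(counts == 0) == 0
  if (!any(keep))
    stop("normalization error: no gene with nonzero counts in all samples",
         call. = FALSE)
  lg <- log(counts[keep, , drop = FALSE])
  ref <- rowMeans(lg)  # log geometric mean
  exp(apply(lg - ref, 2, stats::median))
}

#' Per-gene log2 fold change, mutant versus control
#'
#' `log2(mean normalized mutant + pc) - log2(mean normalized control +
#' pc)` over the replicates of one assay.
#'
#' @param counts genes x samples matrix for one assay.
#' @param samples sample sheet data.frame (`sample`, `condition`, ...)
#'   covering the matrix columns.
#' @param mutant mutant condition name.
#' @param control control condition name.
#' @param pseudocount added to both normalized means.
#' @param sf optional precomputed size factors (default:
#'   [size_factors()] of `counts`).
#' @return named numeric vector of log2 fold changes.
#' @export
log2fc <- function(counts, samples, mutant, control = "control",
                   pseudocount = 0.5, sf = NULL) {
  if (is.null(sf)) sf <- size_factors(counts)
  norm <- sweep(counts, 2, sf, "/")
  cols_of <- function(cond) {
    s <- samples$sample[samples$condition == cond]
    s <- intersect(s, colnames(counts))
    if (length(s) == 0L)
      stop("input error: no samples for condition ", cond, call. = FALSE)
    s
  }
  m <- rowMeans(norm[, cols_of(mutant), drop = FALSE])
  c0 <- rowMeans(norm[, cols_of(control), drop = FALSE])
  log2(m + pseudocount) - log2(c0 + pseudocount)
}

#' Fold-change table for one mutant-vs-control comparison
#'
#' @param total_counts,dsrna_counts genes x samples matrices sharing a
#'   gene universe.
#' @param samples sample sheet covering both matrices (`sample`,
#'   `assay`, `condition`, `replicate`).
#' @param mutant mutant condition name.
#' @param pseudocount see [log2fc()].
#' @return data.frame with `gene`, `lfc_total`, `lfc_dsrna`.
#' @export
fold_change_table <- function(total_counts, dsrna_counts, samples, mutant,
                              pseudocount = 0.5) {
  if (!identical(rownames(total_counts), rownames(dsrna_counts)))
    stop("input error: assays must share the gene universe", call. = FALSE)
  st <- samples[samples$assay == "total", ]
  sd_ <- samples[samples$assay == "dsrna", ]
  data.frame(
    gene = rownames(total_counts),
    lfc_total = log2fc(total_counts, st, mutant, pseudocount = pseudocount),
    lfc_dsrna = log2fc(dsrna_counts, sd_, mutant, pseudocount = pseudocount),
    row.names = NULL)
}

#' Residual-based enrichment calls
#'
#' Regresses the dsRNA log2 fold change on the total log2 fold change
#' (ordinary least squares, with intercept) and standardizes the raw
#' residuals by their sample SD. Genes with a standardized residual
#' above `z_threshold` are called `enriched`, below `-z_threshold`
#' `depleted`, otherwise `none`. A degenerate residual SD (all
#' residuals ~0) yields no calls.
#'
#' @param fc fold-change table (see [fold_change_table()]).
#' @param z_threshold call threshold on |standardized residual|.
#' @param studentized use leverage-adjusted (internally studentized)
#'   residuals instead of SD-scaled raw residuals.
#' @return data.frame with `gene`, `lfc_total`, `lfc_dsrna`,
#'   `residual`, `standardized_residual`, `call`; the fitted slope,
#'   intercept and residual SD are attached as attribute `fit`.
#' @export
residual_calls <- function(fc, z_threshold = 2.5, studentized = FALSE) {
  if (nrow(fc) < 3L)
    stop("input error: need at least 3 genes", call. = FALSE)
  if (stats::sd(fc$lfc_total) == 0)
    stop("regression error: lfc_total is constant", call. = FALSE)
  fit <- stats::lm(lfc_dsrna ~ lfc_total, data = fc)
  r <- stats::resid(fit)
  s <- stats::sd(r)
  z <- if (s < 1e-12) rep(0, length(r))
    else if (studentized) stats::rstandard(fit)
    else r / s
  call <- ifelse(z > z_threshold, "enriched",
                 ifelse(z < -z_threshold, "depleted", "none"))
  out <- data.frame(gene = fc$gene, lfc_total = fc$lfc_total,
                    lfc_dsrna = fc$lfc_dsrna, residual = unname(r),
                    standardized_residual = unname(z), call = call,
                    row.names = NULL)
  attr(out, "fit") <- list(intercept = unname(stats::coef(fit)[1]),
                           slope = unname(stats::coef(fit)[2]),
                           residual_sd = s)
  out
}

#' Intersect enrichment calls across two comparisons
#'
#' A gene is consistently enriched (depleted) when both comparisons
#' call it in the same direction.
#'
#' @param calls_m1,calls_m2 call tables from [residual_calls()] over
#'   the same gene universe.
#' @return list with, for each direction, the shared and exclusive
#'   gene sets and their counts (a Venn summary), plus a `consistent`
#'   data.frame (gene, call).
#' @export
consistent_calls <- function(calls_m1, calls_m2) {
  if (!setequal(calls_m1$gene, calls_m2$gene))
    stop("input error: comparisons have different gene universes",
         call. = FALSE)
  venn_of <- function(direction) {
    a <- calls_m1$gene[calls_m1$call == direction]
    b <- calls_m2$gene[calls_m2$call == direction]
    list(m1_only = sort(setdiff(a, b)), m2_only = sort(setdiff(b, a)),
         shared = sort(intersect(a, b)),
         counts = c(m1_only = length(setdiff(a, b)),
                    m2_only = length(setdiff(b, a)),
                    shared = length(intersect(a, b))))
  }
  enr <- venn_of("enriched")
  dep <- venn_of("depleted")
  consistent <- rbind(
    if (length(enr$shared))
      data.frame(gene = enr$shared, call = "enriched"),
    if (length(dep$shared))
      data.frame(gene = dep$shared, call = "depleted"))
  if (is.null(consistent))
    consistent <- data.frame(gene = character(0), call = character(0))
  list(enriched = enr, depleted = dep, consistent = consistent)
}

#' G/C proportion of sequences
#'
#' @param seqs named character vector of nucleotide strings.
#' @return named numeric vector: `(#G + #C) / length` per sequence.
#' @export
gc_proportion <- function(seqs) {
  vapply(seqs, function(s) {
    n <- nchar(s)
    if (n == 0L) return(NA_real_)
    gc <- nchar(gsub("[^GCgc]", "", s))
    gc / n
  }, numeric(1))
}

#' Compare G/C composition of call sets against all genes
#'
#' Two-sided Mann-Whitney U tests of the G/C proportions of the
#' enriched set versus all genes, and of the depleted set versus all
#' genes. Exact when both sets have at most 25 genes and there are no
#' ties; normal approximation with tie correction otherwise.
#'
#' @param enriched,depleted,all_genes gene id vectors (`all_genes` is
#'   the full universe, which includes the call sets).
#' @param gc named numeric vector of per-gene G/C proportions (or a
#'   named character vector of sequences, converted via
#'   [gc_proportion()]).
#' @return data.frame with one row per comparison: set, n, median G/C,
#'   median G/C of all genes, and the Mann-Whitney p-value (NA with a
#'   warning for an empty set).
#' @export
gc_test <- function(enriched, depleted, all_genes, gc) {
  if (is.character(gc)) gc <- gc_proportion(gc)
  missing <- setdiff(all_genes, names(gc))
  if (length(missing))
    stop("input error: no G/C value for ", length(missing), " genes",
         call. = FALSE)
  one <- function(set, label) {
    if (length(set) == 0L) {
      warning("empty ", label, " set; comparison skipped")
      return(data.frame(set = label, n = 0L, median_gc = NA_real_,
                        median_gc_all = stats::median(gc[all_genes]),
                        p_value = NA_real_))
    }
    x <- gc[set]
    y <- gc[all_genes]
    exact <- length(x) <= 25 && length(y) <= 25 &&
      !anyDuplicated(c(x, y))
    p <- stats::wilcox.test(x, y, alternative = "two.sided",
                            exact = exact, correct = TRUE)$p.value
    data.frame(set = label, n = length(set), median_gc = stats::median(x),
               median_gc_all = stats::median(y), p_value = p)
  }
  rbind(one(enriched, "enriched"), one(depleted, "depleted"))
}

#' Full dsRNA-vs-total enrichment analysis
#'
#' Fold changes for both mutants, residual calls, the cross-mutant
#' consistency Venn, and the G/C composition test.
#'
#' @param total_counts,dsrna_counts count matrices.
#' @param samples sample sheet.
#' @param gc per-gene G/C proportions (optional; skips the G/C test
#'   when `NULL`).
#' @param z_threshold see [residual_calls()].
#' @param pseudocount see [log2fc()].
#' @return list with `fold_changes`, `calls` (per mutant), `venn`,
#'   `gc_test`.
#' @export
dsrna_enrichment <- function(total_counts, dsrna_counts, samples, gc = NULL,
                             z_threshold = 2.5, pseudocount = 0.5) {
  mutants <- setdiff(unique(samples$condition), "control")
  fc <- lapply(mutants, function(m)
    fold_change_table(total_counts, dsrna_counts, samples, m,
                      pseudocount = pseudocount))
  names(fc) <- mutants
  calls <- lapply(fc, residual_calls, z_threshold = z_threshold)
  venn <- if (length(mutants) >= 2L)
    consistent_calls(calls[[1L]], calls[[2L]]) else NULL
  gct <- NULL
  if (!is.null(gc) && !is.null(venn)) {
    gct <- gc_test(venn$enriched$shared, venn$depleted$shared,
                   rownames(total_counts), gc)
  }
  list(fold_changes = fc, calls = calls, venn = venn, gc_test = gct)
}
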