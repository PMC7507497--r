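#' Segment nuclei from a DAPI z-stack
#'
#' The three-step z-stack procedure starts from a nuclei projection
#' mask: the per-pixel maximum over z of the DAPI channel is
#' thresholded (Otsu by default), cleaned by morphological opening,
#' labelled, size-filtered, and border-touching labels are removed.
#' The projection mask then constrains per-slice nucleus segmentation:
#' a voxel belongs to nucleus k when its (y, x) lies in projection
#' label k and its DAPI intensity exceeds the threshold.
#'
#' @param dapi 3D array `(y, x, z)`.
#' @param threshold manual global threshold; default Otsu on the
#'   projection.
#' @param opening_radius radius (px) of the disc used for opening.
#' @param min_size minimum projected area (px) of a nucleus.
#' @param exclude_border drop labels touching the image border.
#' @return an object of class `stack_segmentation`: `proj_labels` (2D
#'   integer matrix), `nucleus_voxels` (3D integer label array),
#'   `threshold`.
#' @export
nuclei_mask <- function(dapi, threshold = NULL, opening_radius = 2L,
                        min_size = 500L, exclude_border = TRUE) {
  proj <- apply(dapi, c(1, 2), max)
  thr <- if (is.null(threshold))
    EBImage::otsu(EBImage::Image(proj), range = c(0, 1)) else threshold
  bw <- proj > thr
  bw <- EBImage::opening(bw, EBImage::makeBrush(2L * opening_radius + 1L,
                                                "disc"))
  lab <- EBImage::imageData(EBImage::bwlabel(bw))
  lab <- filter_labels(lab, min_size, exclude_border)
  nvox <- array(0L, dim(dapi))
  for (z in seq_len(dim(dapi)[3])) {
    sl <- lab
    sl[dapi[, , z] <= thr] <- 0L
    nvox[, , z] <- sl
  }
  structure(list(proj_labels = lab, nucleus_voxels = nvox, threshold = thr,
                 nucleolus_proj_labels = NULL, nucleolus_voxels = NULL,
                 assignment = NULL),
            class = "stack_segmentation")
}

# size filter + optional border removal + consecutive relabelling
filter_labels <- function(lab, min_size, exclude_border) {
  if (max(lab) == 0) return(matrix(0L, nrow(lab), ncol(lab)))
  sizes <- tabulate(lab)
  drop <- which(sizes < min_size)
  if (exclude_border) {
    border <- unique(c(lab[1, ], lab[nrow(lab), ], lab[, 1], lab[, ncol(lab)]))
    drop <- union(drop, setdiff(border, 0L))
  }
  lab[lab %in% drop] <- 0L
  old <- sort(setdiff(unique(as.vector(lab)), 0L))
  out <- matrix(0L, nrow(lab), ncol(lab))
  for (i in seq_along(old)) out[lab == old[i]] <- i
  out
}

#' @export
print.stack_segmentation <- function(x, ...) {
  cat("<stack_segmentation>", max(x$proj_labels), "nuclei",
      if (!is.null(x$nucleolus_proj_labels))
        paste(",", max(x$nucleolus_proj_labels), "nucleoli"), "\n")
  invisible(x)
}

#' Segment nucleoli and assign them to nuclei
#'
#' The nucleolin channel is masked by the nuclei projection mask (to
#' remove signal outside nuclei), max-projected, thresholded and
#' labelled with the same procedure as the nuclei but a
#' nucleolus-scale size filter. Each nucleolus is assigned to the
#' nucleus whose projection footprint it overlaps most (ties: larger
#' overlap, then lower nucleus label); fragments overlapping no
#' nucleus are dropped.
#'
#' @param nucleolin 3D array `(y, x, z)`.
#' @param seg a `stack_segmentation` from [nuclei_mask()].
#' @param threshold manual threshold; default Otsu on the masked
#'   projection.
#' @param opening_radius,min_size as in [nuclei_mask()], at nucleolus
#'   scale.
#' @param max_nucleus_fraction drop candidate nucleoli whose projected
#'   area exceeds this fraction of their nucleus footprint; nucleoli
#'   are substructures, so a "nucleolus" filling the nucleus means the
#'   channel has no real nucleolar contrast.
#' @return `seg` with `nucleolus_proj_labels`, `nucleolus_voxels` and
#'   `assignment` (nucleolus label -> nucleus label) filled.
#' @export
nucleoli_labels <- function(nucleolin, seg, threshold = NULL,
                            opening_radius = 1L, min_size = 20L,
                            max_nucleus_fraction = 0.5) {
  mask2d <- seg$proj_labels > 0L
  masked <- nucleolin
  for (z in seq_len(dim(nucleolin)[3]))
    masked[, , z] <- nucleolin[, , z] * mask2d
  proj <- apply(masked, c(1, 2), max)
  thr <- if (is.null(threshold))
    EBImage::otsu(EBImage::Image(proj), range = c(0, 1)) else threshold
  bw <- proj > thr
  bw <- EBImage::opening(bw, EBImage::makeBrush(2L * opening_radius + 1L,
                                                "disc"))
  lab <- EBImage::imageData(EBImage::bwlabel(bw))
  lab <- filter_labels(lab, min_size, exclude_border = FALSE)
  assignment <- integer(0)
  keep <- integer(0)
  for (j in seq_len(max(lab))) {
    over <- seg$proj_labels[lab == j]
    over <- over[over > 0L]
    if (length(over) == 0L) next
    tab <- sort(table(over), decreasing = TRUE)
    best <- min(as.integer(names(tab))[tab == max(tab)])  # tie: lower label
    if (sum(lab == j) > max_nucleus_fraction * sum(seg$proj_labels == best))
      next
    keep <- c(keep, j)
    assignment[as.character(j)] <- best
  }
  lab[!lab %in% keep] <- 0L
  nlvox <- array(0L, dim(nucleolin))
  for (z in seq_len(dim(nucleolin)[3])) {
    sl <- lab
    sl[masked[, , z] <= thr] <- 0L
    nlvox[, , z] <- sl
  }
  seg$nucleolus_proj_labels <- lab
  seg$nucleolus_voxels <- nlvox
  seg$assignment <- assignment
  seg$nucleolus_threshold <- thr
  seg
}

#' Per-cell compartment intensities from the signal channel
#'
#' For every nucleus with at least one assigned nucleolus: the mean
#' signal over its nucleolar voxels, over its nucleoplasm (nucleus
#' voxels minus nucleolar voxels), and their ratio. Cells without a
#' detected nucleolus are skipped with a warning; cells with an empty
#' nucleoplasm are skipped.
#'
#' @param signal 3D array `(y, x, z)`.
#' @param seg a `stack_segmentation` with nucleoli assigned.
#' @return data.frame (class `cell_quant`): `cell_id`,
#'   `nucleolar_mean`, `nucleoplasm_mean`, `ratio`, `n_nucleolar`,
#'   `n_nucleoplasm`.
#' @export
cell_intensity <- function(signal, seg) {
  if (is.null(seg$nucleolus_voxels))
    stop("input error: segment nucleoli first (nucleoli_labels)",
         call. = FALSE)
  cells <- sort(setdiff(unique(as.vector(seg$proj_labels)), 0L))
  rows <- lapply(cells, function(k) {
    in_nucleus <- seg$nucleus_voxels == k
    nl_labels <- as.integer(names(seg$assignment))[seg$assignment == k]
    if (length(nl_labels) == 0L) {
      warning("cell ", k, " has no detected nucleolus; skipped")
      return(NULL)
    }
    nucleolar <- in_nucleus & (seg$nucleolus_voxels %in% nl_labels)
    nucleoplasm <- in_nucleus & seg$nucleolus_voxels == 0L
    if (!any(nucleolar) || !any(nucleoplasm)) return(NULL)
    data.frame(cell_id = k,
               nucleolar_mean = mean(signal[nucleolar]),
               nucleoplasm_mean = mean(signal[nucleoplasm]),
               ratio = mean(signal[nucleolar]) / mean(signal[nucleoplasm]),
               n_nucleolar = sum(nucleolar),
               n_nucleoplasm = sum(nucleoplasm))
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(cell_id = integer(0), nucleolar_mean = numeric(0),
                      nucleoplasm_mean = numeric(0), ratio = numeric(0),
                      n_nucleolar = integer(0), n_nucleoplasm = integer(0))
  class(out) <- c("cell_quant", class(out))
  out
}

#' Summary statistics of compartment intensities
#'
#' Means and SDs per compartment, the mean per-cell ratio, and a
#' paired two-tailed t-test of nucleolar versus nucleoplasm means
#' across cells. When the per-cell differences have zero variance the
#' t statistic is undefined; the summary then flags `degenerate` and
#' reports the 0-limit p-value (0 for a nonzero constant difference).
#'
#' @param quants a `cell_quant` data.frame from [cell_intensity()].
#' @return list: `n_cells`, `nucleolar` / `nucleoplasm` (mean, sd),
#'   `mean_ratio`, `p_value`, `degenerate`.
#' @export
ratio_stats <- function(quants) {
  if (nrow(quants) < 2L)
    stop("statistics unavailable: need at least 2 cells", call. = FALSE)
  d <- quants$nucleolar_mean - quants$nucleoplasm_mean
  degenerate <- stats::sd(d) < 1e-12
  p <- if (degenerate) {
    if (abs(mean(d)) > 0) 0 else NA_real_
  } else {
    stats::t.test(quants$nucleolar_mean, quants$nucleoplasm_mean,
                  paired = TRUE, alternative = "two.sided")$p.value
  }
  list(n_cells = nrow(quants),
       nucleolar = c(mean = mean(quants$nucleolar_mean),
                     sd = stats::sd(quants$nucleolar_mean)),
       nucleoplasm = c(mean = mean(quants$nucleoplasm_mean),
                       sd = stats::sd(quants$nucleoplasm_mean)),
       mean_ratio = mean(quants$ratio),
       p_value = p, degenerate = degenerate)
}

#' Count and bin foci per cell
#'
#' The foci channel is max-projected onto one plane, background is
#' removed with a white top-hat, and foci are detected as local maxima
#' above a prominence threshold; "non-overlapping" is realized as a
#' minimum separation between accepted maxima (brighter maxima win).
#' Maxima are attributed to the cell footprint they fall in; counts
#' are binned as `<1` (exactly 0), `1-5`, `>5`.
#'
#' @param foci 3D array `(y, x, z)`.
#' @param footprints 2D integer label matrix of cell footprints (e.g.
#'   `proj_labels` from [nuclei_mask()] run on a cell/DAPI channel).
#' @param tophat_radius structuring-element radius (px) of the white
#'   top-hat.
#' @param min_sep minimum separation (px) between accepted maxima.
#' @param prominence minimum top-hat intensity of an accepted maximum.
#' @return list with `counts` (data.frame: cell_id, count, bin) and
#'   `histogram` (named counts over the three bins; sums to the number
#'   of cells).
#' @export
count_and_bin_foci <- function(foci, footprints, tophat_radius = 4L,
                               min_sep = 3L, prominence = 0.25) {
  proj <- apply(foci, c(1, 2), max)
  th <- EBImage::imageData(EBImage::whiteTopHat(
    EBImage::Image(proj), EBImage::makeBrush(2L * tophat_radius + 1L, "disc")))
  dil <- EBImage::imageData(EBImage::dilate(
    EBImage::Image(th), EBImage::makeBrush(2L * min_sep + 1L, "disc")))
  cand <- which(th >= dil - 1e-9 & th > prominence, arr.ind = TRUE)
  if (nrow(cand) > 0) {
    cand <- cand[order(th[cand], decreasing = TRUE), , drop = FALSE]
    accepted <- matrix(numeric(0), 0, 2)
    for (i in seq_len(nrow(cand))) {
      p <- cand[i, ]
      if (nrow(accepted) == 0 ||
          all(sqrt(rowSums(sweep(accepted, 2, p)^2)) >= min_sep))
        accepted <- rbind(accepted, p)
    }
  } else accepted <- matrix(numeric(0), 0, 2)

  cells <- sort(setdiff(unique(as.vector(footprints)), 0L))
  counts <- stats::setNames(integer(length(cells)), cells)
  if (nrow(accepted) > 0) {
    owner <- footprints[accepted]
    tab <- table(owner[owner > 0L])
    counts[names(tab)] <- as.integer(tab)
  }
  df <- data.frame(cell_id = cells, count = as.integer(counts),
                   bin = bin_foci(counts), row.names = NULL)
  hist <- c("<1" = sum(df$bin == "<1"), "1-5" = sum(df$bin == "1-5"),
            ">5" = sum(df$bin == ">5"))
  list(counts = df, histogram = hist)
}

#' Bin a focus count into the three abundance classes
#' @param count integer vector of per-cell focus counts.
#' @return character vector over `"<1"` (exactly 0), `"1-5"`, `">5"`.
#' @export
bin_foci <- function(count) {
  ifelse(count == 0L, "<1", ifelse(count <= 5L, "1-5", ">5"))
}
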