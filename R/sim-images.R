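#' Simulate multi-channel 3D image stacks of nuclei with nucleoli
#'
#' Nuclei are axis-aligned ellipsoids placed on a jittered grid so they
#' touch neither each other nor the image border; each contains 1-3
#' non-overlapping ellipsoidal nucleoli strictly inside it. Channels
#' (dapi, nucleolin, signal) are built noise-free with the signal
#' channel exactly `nucleolar_factor` times brighter over nucleolar
#' voxels than over the nucleoplasm, then Gaussian noise of SD
#' `noise_sd` is added, intensities clipped to `[0, 1]` and quantised
#' to 16 bits. Ground truth keeps the label volumes and the factor.
#'
#' Arrays are indexed `(y, x, z)`; `config$stack_shape` is `(z, y, x)`.
#'
#' @param config a [sim_config()].
#' @param dir optional output directory; writes `dapi.tif`,
#'   `nucleolin.tif`, `signal.tif` (16-bit multi-page TIFF, one page
#'   per z-slice).
#' @return list with `channels` (named list of 3D arrays), `truth`
#'   (nucleus/nucleolus label volumes, assignment map, factor), and
#'   file paths when `dir` is given.
#' @export
gen_image_stacks <- function(config, dir = NULL) {
  validate_sim_config(config)
  sim_seed(config, "stacks")
  zd <- config$stack_shape[1]
  yd <- config$stack_shape[2]
  xd <- config$stack_shape[3]
  n <- config$n_cells

  geom <- place_nuclei(n, yd, xd, zd)
  nucleus_lab <- array(0L, c(yd, xd, zd))
  nucleolus_lab <- array(0L, c(yd, xd, zd))
  assignment <- integer(0)
  nl_id <- 0L
  for (k in seq_len(n)) {
    g <- geom[[k]]
    vox <- ellipsoid_voxels(g$c, g$r, yd, xd, zd)
    nucleus_lab[vox] <- k
    for (j in seq_len(g$n_nucleoli)) {
      nl <- g$nucleoli[[j]]
      nl_id <- nl_id + 1L
      nv <- ellipsoid_voxels(nl$c, nl$r, yd, xd, zd)
      nucleolus_lab[nv] <- nl_id
      assignment[nl_id] <- k
    }
  }
  in_nucleus <- nucleus_lab > 0L
  in_nucleolus <- nucleolus_lab > 0L

  base <- min(0.15, 0.9 / config$nucleolar_factor)
  dapi <- array(0.02, c(yd, xd, zd))
  dapi[in_nucleus] <- 0.55
  nucleolin <- array(0.02, c(yd, xd, zd))
  nucleolin[in_nucleus] <- 0.06
  nucleolin[in_nucleolus] <- 0.7
  signal <- array(0.02, c(yd, xd, zd))
  signal[in_nucleus] <- base
  signal[in_nucleolus] <- base * config$nucleolar_factor

  finish <- function(x) {
    if (config$noise_sd > 0)
      x <- x + stats::rnorm(length(x), 0, config$noise_sd)
    x <- pmin(pmax(x, 0), 1)
    array(round(x * 65535) / 65535, dim(x))
  }
  channels <- list(dapi = finish(dapi), nucleolin = finish(nucleolin),
                   signal = finish(signal))
  truth <- list(nucleus_labels = nucleus_lab,
                nucleolus_labels = nucleolus_lab,
                nucleolus_to_nucleus = assignment,
                true_nucleolar_factor = config$nucleolar_factor,
                n_cells = n)
  out <- list(channels = channels, truth = truth)
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    for (ch in names(channels)) {
      f <- file.path(dir, paste0(ch, ".tif"))
      write_stack(channels[[ch]], f)
      out[[paste0(ch, "_file")]] <- f
    }
  }
  out
}

# jittered-grid placement of n ellipsoidal nuclei with 1-3 contained,
# non-overlapping nucleoli each
place_nuclei <- function(n, yd, xd, zd) {
  ncol_g <- ceiling(sqrt(n * xd / yd))
  nrow_g <- ceiling(n / ncol_g)
  tw <- xd / ncol_g
  th <- yd / nrow_g
  rmax <- 0.42 * min(tw, th)
  lapply(seq_len(n), function(k) {
    gi <- (k - 1L) %/% ncol_g
    gj <- (k - 1L) %% ncol_g
    cx <- (gj + 0.5) * tw + runif(1, -2, 2)
    cy <- (gi + 0.5) * th + runif(1, -2, 2)
    cz <- zd / 2 + runif(1, -1, 1)
    ry <- runif(1, 0.75, 1) * rmax
    rx <- runif(1, 0.75, 1) * rmax
    rz <- runif(1, 0.28, 0.38) * zd
    n_nl <- sample(1:3, 1L)
    nucleoli <- list()
    for (j in seq_len(n_nl)) {
      placed <- FALSE
      for (try in seq_len(200)) {
        r2 <- c(runif(1, 3.5, 6), runif(1, 3.5, 6), runif(1, 1.8, 2.6))
        d <- c(runif(1, -0.65, 0.65) * ry, runif(1, -0.65, 0.65) * rx,
               runif(1, -0.45, 0.45) * rz)
        # sufficient condition for ellipsoid-in-ellipsoid containment
        ok_in <- sum(((abs(d) + r2) / c(ry, rx, rz))^2) <= 0.85^2
        c2 <- c(cy, cx, cz) + d
        ok_sep <- all(vapply(nucleoli, function(o)
          sqrt(sum((o$c - c2)^2)) > max(o$r) + max(r2) + 1, logical(1)))
        if (ok_in && ok_sep) {
          nucleoli[[j]] <- list(c = c2, r = r2)
          placed <- TRUE
          break
        }
      }
      if (!placed) break
    }
    if (length(nucleoli) == 0L)
      stop("internal error: could not place a nucleolus inside a nucleus")
    list(c = c(cy, cx, cz), r = c(ry, rx, rz),
         n_nucleoli = length(nucleoli), nucleoli = nucleoli)
  })
}

# linear voxel indices of an axis-aligned ellipsoid, array dim (y,x,z)
ellipsoid_voxels <- function(centre, radii, yd, xd, zd) {
  ys <- max(1L, floor(centre[1] - radii[1])):min(yd, ceiling(centre[1] + radii[1]))
  xs <- max(1L, floor(centre[2] - radii[2])):min(xd, ceiling(centre[2] + radii[2]))
  zs <- max(1L, floor(centre[3] - radii[3])):min(zd, ceiling(centre[3] + radii[3]))
  g <- expand.grid(y = ys, x = xs, z = zs)
  inside <- ((g$y - centre[1]) / radii[1])^2 + ((g$x - centre[2]) / radii[2])^2 +
    ((g$z - centre[3]) / radii[3])^2 <= 1
  g <- g[inside, ]
  (g$z - 1L) * yd * xd + (g$x - 1L) * yd + g$y
}

#' Simulate foci-channel image stacks
#'
#' Cells are disk footprints (constant through z); each carries a known
#' number of Gaussian foci placed uniformly inside the footprint with a
#' minimum pairwise centre separation. Ground truth records the exact
#' planted count (and positions) per cell.
#'
#' @param config a [sim_config()]; `foci_per_cell` may be an integer
#'   (fixed count) or `list(lambda=)` (Poisson).
#' @param dir optional output directory; writes `cells.tif` and
#'   `foci.tif`.
#' @return list with `channels` (`cells`, `foci`: 3D arrays), `truth`
#'   (`cell_labels` 2D footprints, `foci_counts`, `foci_positions`).
#' @export
gen_foci_images <- function(config, dir = NULL) {
  validate_sim_config(config)
  sim_seed(config, "foci")
  yd <- config$stack_shape[2]
  xd <- config$stack_shape[3]
  zd <- max(4L, config$stack_shape[1] %/% 2L)
  n <- config$n_cells
  min_sep <- config$foci_min_sep

  ncol_g <- ceiling(sqrt(n * xd / yd))
  nrow_g <- ceiling(n / ncol_g)
  tw <- xd / ncol_g
  th <- yd / nrow_g
  rad <- 0.38 * min(tw, th)

  cell_lab <- matrix(0L, yd, xd)
  cells <- array(0.02, c(yd, xd, zd))
  foci <- array(0.02, c(yd, xd, zd))
  counts <- integer(n)
  positions <- vector("list", n)

  yy <- matrix(seq_len(yd), yd, xd)
  xx <- matrix(seq_len(xd), yd, xd, byrow = TRUE)

  for (k in seq_len(n)) {
    gi <- (k - 1L) %/% ncol_g
    gj <- (k - 1L) %% ncol_g
    cx <- (gj + 0.5) * tw + runif(1, -2, 2)
    cy <- (gi + 0.5) * th + runif(1, -2, 2)
    disk <- (yy - cy)^2 + (xx - cx)^2 <= rad^2
    cell_lab[disk] <- k
    for (z in seq_len(zd)) {
      sl <- cells[, , z]
      sl[disk] <- 0.5
      cells[, , z] <- sl
      fl <- foci[, , z]
      fl[disk] <- 0.04
      foci[, , z] <- fl
    }

    n_foci <- if (is.list(config$foci_per_cell))
      stats::rpois(1L, config$foci_per_cell$lambda)
    else as.integer(config$foci_per_cell)
    pts <- matrix(numeric(0), 0, 2)
    tries <- 0L
    while (nrow(pts) < n_foci) {
      tries <- tries + 1L
      if (tries > 2000L)
        stop("configuration error: foci density incompatible with minimum ",
             "separation", call. = FALSE)
      a <- runif(1, 0, 2 * pi)
      r <- sqrt(runif(1)) * (rad - 4)
      p <- c(cy + r * sin(a), cx + r * cos(a))
      if (nrow(pts) == 0 ||
          all(sqrt(rowSums(sweep(pts, 2, p)^2)) >= min_sep))
        pts <- rbind(pts, p)
    }
    counts[k] <- n_foci
    positions[[k]] <- pts
    if (n_foci > 0) {
      zc <- sample(seq(2L, zd - 1L), n_foci, replace = TRUE)
      for (f in seq_len(n_foci))
        foci <- add_gaussian_spot(foci, c(pts[f, ], zc[f]),
                                  amplitude = 0.6, sigma_xy = 1.3,
                                  sigma_z = 1.0)
    }
  }

  finish <- function(x) {
    if (config$noise_sd > 0)
      x <- x + stats::rnorm(length(x), 0, config$noise_sd)
    x <- pmin(pmax(x, 0), 1)
    array(round(x * 65535) / 65535, dim(x))
  }
  channels <- list(cells = finish(cells), foci = finish(foci))
  truth <- list(cell_labels = cell_lab,
                foci_counts = stats::setNames(counts, seq_len(n)),
                foci_positions = positions)
  out <- list(channels = channels, truth = truth)
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    out$cells_file <- file.path(dir, "cells.tif")
    out$foci_file <- file.path(dir, "foci.tif")
    write_stack(channels$cells, out$cells_file)
    write_stack(channels$foci, out$foci_file)
  }
  out
}

add_gaussian_spot <- function(arr, centre, amplitude, sigma_xy, sigma_z) {
  d <- dim(arr)
  ys <- max(1L, round(centre[1] - 4 * sigma_xy)):min(d[1], round(centre[1] + 4 * sigma_xy))
  xs <- max(1L, round(centre[2] - 4 * sigma_xy)):min(d[2], round(centre[2] + 4 * sigma_xy))
  zs <- max(1L, round(centre[3] - 4 * sigma_z)):min(d[3], round(centre[3] + 4 * sigma_z))
  for (z in zs) {
    g <- exp(-(outer((ys - centre[1])^2, (xs - centre[2])^2, "+") /
                 (2 * sigma_xy^2) + (z - centre[3])^2 / (2 * sigma_z^2)))
    arr[ys, xs, z] <- arr[ys, xs, z] + amplitude * g
  }
  arr
}

#' Write a 3D array as a 16-bit multi-page TIFF (one page per z-slice)
#' @param arr array `(y, x, z)` with intensities in `[0, 1]`.
#' @param path output file.
#' @export
write_stack <- function(arr, path) {
  slices <- lapply(seq_len(dim(arr)[3]), function(z) arr[, , z])
  tiff::writeTIFF(slices, path, bits.per.sample = 16L)
  invisible(path)
}

#' Read a multi-page TIFF into a 3D array `(y, x, z)`
#' @param path TIFF file.
#' @return numeric array with intensities in `[0, 1]`.
#' @export
read_stack <- function(path) {
  slices <- tiff::readTIFF(path, all = TRUE)
  if (is.matrix(slices)) slices <- list(slices)
  arr <- array(0, c(dim(slices[[1]])[1:2], length(slices)))
  for (z in seq_along(slices)) {
    s <- slices[[z]]
    if (length(dim(s)) == 3L) s <- s[, , 1]
    arr[, , z] <- s
  }
  arr
}
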