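#' Multi-channel fluorescence image stack
#'
#' Container for the three channels of an endothelial monolayer image:
#' nuclei (DAPI), actin (phalloidin) and VE-cadherin. Channels are numeric
#' matrices of identical shape with non-negative intensities; `pixel_size`
#' carries the physical scale in micrometres per pixel.
#'
#' @param nuclei,actin,ve_cadherin Numeric intensity matrices, same shape.
#' @param pixel_size Pixel size in um/pixel.
#' @return An object of class `image_stack` with elements `channels`
#'   (named list) and `pixel_size`.
#' @export
image_stack <- function(nuclei, actin, ve_cadherin, pixel_size = 0.16) {
  ch <- list(nuclei = .as_mat(nuclei), actin = .as_mat(actin),
             ve_cadherin = .as_mat(ve_cadherin))
  dims <- vapply(ch, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
    stop("all channels must have identical shape", call. = FALSE)
  if (any(vapply(ch, function(m) any(m < 0), logical(1))))
    stop("intensities must be non-negative", call. = FALSE)
  if (pixel_size <= 0) stop("pixel_size must be > 0", call. = FALSE)
  structure(list(channels = ch, pixel_size = pixel_size),
            class = "image_stack")
}

#' Read a multi-page TIFF as an image stack
#'
#' @param path Path to a multi-page TIFF (one page per channel).
#' @param channel_order Channel names in page order.
#' @param pixel_size Pixel size in um/pixel.
#' @return An [image_stack()].
#' @export
read_image_stack <- function(path,
                             channel_order = c("nuclei", "actin", "ve_cadherin"),
                             pixel_size = 0.16) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (length(pages) < 3) stop("expected >= 3 TIFF pages", call. = FALSE)
  names(pages)[seq_along(channel_order)] <- channel_order
  image_stack(pages[["nuclei"]], pages[["actin"]], pages[["ve_cadherin"]],
              pixel_size = pixel_size)
}

#' Write an image stack to a multi-page 16-bit TIFF
#'
#' Intensities are clipped to \[0, 1\] before writing.
#'
#' @param stack An [image_stack()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_image_stack <- function(stack, path) {
  pages <- lapply(stack$channels, function(m) pmin(pmax(m, 0), 1))
  tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  invisible(path)
}

#' Minimum cross-entropy (Li) threshold
#'
#' Iterative minimum cross-entropy thresholding: starting from the image
#' mean, the threshold is updated as
#' \deqn{t \leftarrow \frac{\mu_1 - \mu_0}{\log \mu_1 - \log \mu_0}}
#' where \eqn{\mu_0, \mu_1} are the means of the pixels at or below / above
#' the current threshold, until the update stalls. This is the fixed point of
#' the cross-entropy criterion between the image and its two-level
#' reconstruction; foreground is `x > threshold`. Scale-equivariant:
#' `li_threshold(k * x)` is `k * li_threshold(x)` for `k > 0`.
#'
#' @param x Numeric matrix or vector with at least two distinct values.
#' @param tol Convergence tolerance, relative to the intensity range.
#' @param max_iter Iteration cap.
#' @return The scalar threshold.
#' @export
li_threshold <- function(x, tol = 1e-7, max_iter = 200L) {
  x <- as.numeric(x)
  x <- x[is.finite(x)]
  rng <- range(x)
  if (rng[1] == rng[2])
    stop("degenerate image: all pixels share one value", call. = FALSE)
  # the mean-ratio update needs strictly positive values; shift off zero by a
  # range-proportional offset so equivariance under scaling is preserved
  off <- if (rng[1] <= 0) (rng[2] - rng[1]) * 1e-6 - rng[1] else 0
  xs <- x + off
  t_cur <- mean(xs)
  for (i in seq_len(max_iter)) {
    lo <- xs[xs <= t_cur]; hi <- xs[xs > t_cur]
    if (!length(lo) || !length(hi)) break
    m0 <- mean(lo); m1 <- mean(hi)
    t_new <- if (m0 == m1) t_cur else (m1 - m0) / (log(m1) - log(m0))
    if (abs(t_new - t_cur) < tol * (rng[2] - rng[1])) { t_cur <- t_new; break }
    t_cur <- t_new
  }
  t_cur - off
}

#' Segment nuclei (primary objects)
#'
#' Li-threshold the nuclei channel, fill holes, label 8-connected components
#' and drop components smaller than `min_area_px`. Optionally declump touching
#' nuclei by a distance-transform watershed (off by default).
#'
#' @param nuclei Nuclei intensity matrix.
#' @param min_area_px Minimum object area in pixels.
#' @param declump Split touching nuclei by watershed on the distance
#'   transform?
#' @return Integer label matrix (0 = background, labels sequential from 1).
#'   Zero surviving objects gives an all-zero map with a warning.
#' @export
segment_primary <- function(nuclei, min_area_px = 50L, declump = FALSE) {
  nuclei <- .as_mat(nuclei)
  mask <- nuclei > li_threshold(nuclei)
  mask <- .as_mat(EBImage::fillHull(mask * 1)) > 0
  lab <- if (declump) {
    w <- .as_mat(EBImage::watershed(EBImage::distmap(mask * 1)))
    storage.mode(w) <- "integer"
    relabel_sequential(w)
  } else label_components(mask, connectivity = 8)
  sizes <- tabulate(lab[lab > 0L])
  drop <- which(sizes < min_area_px)
  if (length(drop)) lab[lab %in% drop] <- 0L
  lab <- relabel_sequential(lab)
  if (max(lab) == 0L) warning("no nuclei found", call. = FALSE)
  lab
}

#' Segment whole cells (secondary objects) from the actin channel
#'
#' The actin foreground (Li threshold, holes filled) is partitioned among the
#' primary objects by seeded propagation on the distance-to-seed landscape:
#' each foreground pixel is assigned to the nucleus it can reach by the
#' shortest within-foreground path, so touching cells split along the
#' distance-transform ridge. Seed pixels are always included even when they
#' fall outside the foreground; such cells are flagged.
#'
#' @param actin Actin intensity matrix.
#' @param primary Nuclei label matrix from [segment_primary()] (>= 1 label).
#' @param lambda Propagation regularisation balancing image-guided and
#'   spatial-distance growth; the small default follows the intensity
#'   landscape (boundaries settle on the bright cortical-actin crest between
#'   cells), while a large value degenerates to a pure distance-to-seed
#'   watershed split.
#' @param smooth_sigma Gaussian sigma (px) applied to the propagation
#'   landscape only (the foreground threshold is computed on the raw image);
#'   damps thin stress fibres so they do not deflect the inter-cell split.
#' @param fill_border_holes Treat the field edge as closed when filling
#'   holes, so that cells cut by the image border keep their interiors
#'   (appropriate for confluent monolayers, where the cortical actin of a
#'   border-cut cell is open only at the field edge). Border-touching cells
#'   are excluded from measurement records regardless.
#' @return Integer cell label matrix sharing ids with `primary`, with
#'   attribute `seed_outside_foreground` listing flagged cell ids.
#' @export
segment_secondary <- function(actin, primary, lambda = 1e-3,
                              smooth_sigma = 1, fill_border_holes = TRUE) {
  actin <- .as_mat(actin)
  if (max(primary) < 1L) stop("need at least one primary object", call. = FALSE)
  mask <- actin > li_threshold(actin)
  if (fill_border_holes) {
    pad <- matrix(1, nrow(mask) + 2L, ncol(mask) + 2L)
    pad[2:(nrow(mask) + 1L), 2:(ncol(mask) + 1L)] <- mask
    pad <- .as_mat(EBImage::fillHull(pad)) > 0
    mask <- pad[2:(nrow(mask) + 1L), 2:(ncol(mask) + 1L)]
  } else {
    mask <- .as_mat(EBImage::fillHull(mask * 1)) > 0
  }
  outside <- sort(unique(primary[primary > 0L & !mask]))
  flagged <- intersect(outside, unique(primary[primary > 0L]))
  mask <- mask | primary > 0L   # seeds always included
  landscape <- if (smooth_sigma > 0)
    .as_mat(EBImage::gblur(actin, smooth_sigma)) else actin
  lab <- .as_mat(EBImage::propagate(landscape, primary, mask = mask,
                                    lambda = lambda))
  storage.mode(lab) <- "integer"
  structure(lab, seed_outside_foreground = as.integer(flagged))
}

#' Cytoplasm (tertiary objects): cell minus nucleus
#'
#' Per-cell set difference `secondary \ primary`, preserving label ids. Every
#' nucleus pixel must lie in the cell with the same id.
#'
#' @param secondary Cell label matrix.
#' @param primary Nuclei label matrix with matching ids.
#' @return Integer cytoplasm label matrix with attribute `empty_cytoplasm`
#'   listing cells whose nucleus fills the whole cell.
#' @export
tertiary_cytoplasm <- function(secondary, primary) {
  if (!identical(dim(secondary), dim(primary)))
    stop("label maps must have identical shape", call. = FALSE)
  inside <- primary > 0L & secondary > 0L
  if (any(primary[inside] != secondary[inside]) ||
      any(primary > 0L & secondary == 0L))
    stop("primary/secondary label ids do not match", call. = FALSE)
  cyto <- secondary
  cyto[primary > 0L] <- 0L
  ids <- setdiff(unique(secondary[secondary > 0L]), unique(cyto[cyto > 0L]))
  structure(cyto, empty_cytoplasm = as.integer(sort(ids)))
}

#' Shrink labelled objects by iterated per-object erosion
#'
#' `n_px` iterations of morphological erosion with the 3x3 (8-connected)
#' structuring element, applied per object so that touching objects erode
#' independently. Objects eroded to extinction are recorded.
#'
#' @param labels Integer label matrix.
#' @param n_px Number of erosion iterations (>= 1).
#' @return Shrunken label matrix with attribute `extinct` (ids eroded away).
#' @export
shrink_labels <- function(labels, n_px) {
  if (n_px < 1L) stop("n_px must be >= 1", call. = FALSE)
  lab <- labels
  storage.mode(lab) <- "integer"
  for (i in seq_len(n_px)) lab <- .erode_labels_once(lab)
  extinct <- setdiff(unique(labels[labels > 0L]), unique(lab[lab > 0L]))
  structure(lab, extinct = as.integer(sort(extinct)))
}

#' Membrane ring: cell minus shrunken cell
#'
#' The cell-membrane compartment of thickness `n_px` is the per-cell set
#' difference between the whole cell and its `n_px`-eroded copy. Cells eroded
#' to extinction keep their whole footprint as the ring and are flagged.
#'
#' @param secondary Cell label matrix.
#' @param n_px Ring thickness in pixels (default 3).
#' @return Integer ring label matrix with attribute `too_small_for_ring`.
#' @export
membrane_ring <- function(secondary, n_px = 3L) {
  shr <- shrink_labels(secondary, n_px)
  ring <- secondary
  storage.mode(ring) <- "integer"
  ring[shr > 0L] <- 0L
  structure(ring, too_small_for_ring = attr(shr, "extinct"))
}

#' Label ids touching the image border
#'
#' @param labels Integer label matrix.
#' @return Sorted integer vector of border-touching ids.
#' @export
border_labels <- function(labels) {
  edge <- c(labels[1, ], labels[nrow(labels), ],
            labels[, 1], labels[, ncol(labels)])
  sort(unique(edge[edge > 0L]))
}

# perimeter of each labelled object as the chain length of its outer contour
# (straight steps 1, diagonal steps sqrt(2))
.perimeters <- function(labels) {
  ids <- sort(unique(labels[labels > 0L]))
  ctr <- EBImage::ocontour(labels)
  out <- rep(4, length(ids))   # fallback: single-pixel object
  names(out) <- ids
  for (nm in names(ctr)) {
    oc <- ctr[[nm]]
    if (is.null(oc) || nrow(oc) < 2) next
    st <- rbind(diff(oc), oc[1, ] - oc[nrow(oc), ])
    out[nm] <- sum(sqrt(rowSums(st^2)))
  }
  out
}

#' Per-object shape measures
#'
#' Area (pixel count and physical), eccentricity of the ellipse with the same
#' normalized second central moments (a 1/12 pixel-variance term accounts for
#' the unit-square support of each pixel, keeping eccentricity in \[0, 1)),
#' perimeter (outer-contour chain length), circularity
#' \eqn{4\pi A / P^2} and its reciprocal, compactness.
#'
#' @param labels Integer label matrix (>= 1 object).
#' @param pixel_size Pixel size in um/pixel for the physical area.
#' @return A data.frame with one row per object: `cell_id`, `area_px`,
#'   `area_um2`, `centroid_x`, `centroid_y`, `eccentricity`, `perimeter_px`,
#'   `circularity`, `compactness`.
#' @export
measure_shape <- function(labels, pixel_size = 1) {
  ids <- sort(unique(labels[labels > 0L]))
  if (!length(ids)) stop("no labelled objects", call. = FALSE)
  idx <- which(labels > 0L, arr.ind = TRUE)
  lb <- labels[labels > 0L]
  f <- factor(lb, levels = ids)
  n <- as.numeric(table(f))
  cx <- tapply(idx[, 2], f, mean)
  cy <- tapply(idx[, 1], f, mean)
  # second central moments of pixel centres + 1/12 per-pixel variance
  vxx <- tapply(idx[, 2], f, stats::var) * (n - 1) / n + 1 / 12
  vyy <- tapply(idx[, 1], f, stats::var) * (n - 1) / n + 1 / 12
  vxx[is.na(vxx)] <- 1 / 12; vyy[is.na(vyy)] <- 1 / 12
  mx <- idx[, 2] - cx[as.integer(f)]
  my <- idx[, 1] - cy[as.integer(f)]
  vxy <- tapply(mx * my, f, sum) / n
  tr <- vxx + vyy
  dt <- sqrt(pmax(0, (vxx - vyy)^2 + 4 * vxy^2))
  l1 <- (tr + dt) / 2; l2 <- pmax((tr - dt) / 2, 0)
  ecc <- sqrt(pmax(0, 1 - l2 / l1))
  per <- .perimeters(labels)
  circ <- 4 * pi * n / per^2
  data.frame(cell_id = ids, area_px = n, area_um2 = n * pixel_size^2,
             centroid_x = as.numeric(cx), centroid_y = as.numeric(cy),
             eccentricity = as.numeric(ecc), perimeter_px = as.numeric(per),
             circularity = as.numeric(circ),
             compactness = as.numeric(1 / circ), row.names = NULL)
}

#' Per-object intensity measures
#'
#' Mean and integrated (summed) fluorescence intensity of one channel over
#' each labelled object.
#'
#' @param labels Integer label matrix.
#' @param channel Intensity matrix of the same shape.
#' @return A data.frame with `cell_id`, `mean_fi`, `integrated_fi`, `n_px`.
#' @export
measure_intensity <- function(labels, channel) {
  channel <- .as_mat(channel)
  if (!identical(dim(labels), dim(channel)))
    stop("label and channel shapes differ", call. = FALSE)
  ids <- sort(unique(labels[labels > 0L]))
  f <- factor(labels[labels > 0L], levels = ids)
  v <- channel[labels > 0L]
  s <- tapply(v, f, sum)
  n <- as.numeric(table(f))
  data.frame(cell_id = ids, mean_fi = as.numeric(s / n),
             integrated_fi = as.numeric(s), n_px = n, row.names = NULL)
}

#' Junctional localisation ratio
#'
#' Membrane-ring mean fluorescence over whole-cell mean fluorescence
#' (VE-cadherin channel): a ratio above 1 indicates junctional enrichment.
#' The mean-based form is insensitive to cell size and to global intensity
#' scaling. Cells with zero whole-cell mean return `NA`.
#'
#' @param membrane_mean,whole_mean Per-cell mean intensities (aligned
#'   vectors).
#' @return Numeric vector of ratios.
#' @export
junctional_ratio <- function(membrane_mean, whole_mean) {
  out <- membrane_mean / whole_mean
  out[!is.finite(out)] <- NA_real_
  out
}

#' Segment a monolayer stack and measure every cell
#'
#' The full compartmented measurement pipeline: nuclei (primary) -> cells
#' (secondary, seeded propagation in the actin foreground) -> cytoplasm
#' (tertiary) and 3-px membrane ring; then shape measures on cells and
#' mean/integrated intensity of every channel over every compartment.
#' Cells touching the image border are excluded from the returned records
#' and listed in `labels$border_excluded`.
#'
#' @param stack An [image_stack()].
#' @param min_nucleus_area,min_cell_area Minimum areas in pixels.
#' @param ring_px Membrane ring thickness in pixels.
#' @param declump Declump touching nuclei (see [segment_primary()]).
#' @param exclude_border Drop border-touching cells from the records?
#' @return A list with `labels` (primary/secondary/tertiary/membrane label
#'   maps, `border_excluded`, `flags`) and `cells`, a data.frame of per-cell
#'   records: shape columns plus `<channel>_<compartment>_mean`/`_integrated`
#'   for all three channels over whole/cytoplasm/membrane, and
#'   `junctional_ratio` (mean-based) plus `junctional_ratio_integrated`.
#' @export
measure_cells <- function(stack, min_nucleus_area = 50L, min_cell_area = 200L,
                          ring_px = 3L, declump = FALSE,
                          exclude_border = TRUE) {
  stopifnot(inherits(stack, "image_stack"))
  primary <- segment_primary(stack$channels$nuclei, min_nucleus_area,
                             declump = declump)
  secondary <- segment_secondary(stack$channels$actin, primary)
  sizes <- tabulate(secondary[secondary > 0L])
  small <- which(sizes > 0 & sizes < min_cell_area)
  if (length(small)) {
    secondary[secondary %in% small] <- 0L
    primary[primary %in% small] <- 0L
  }
  if (max(secondary) == 0L) stop("no cells recovered", call. = FALSE)
  tertiary <- tertiary_cytoplasm(secondary, primary)
  membrane <- membrane_ring(secondary, ring_px)
  border <- border_labels(secondary)

  shape <- measure_shape(secondary, stack$pixel_size)
  comps <- list(whole = secondary, cytoplasm = tertiary, membrane = membrane)
  cells <- shape
  for (ch in names(stack$channels)) {
    for (cp in names(comps)) {
      mi <- measure_intensity(comps[[cp]], stack$channels[[ch]])
      key <- sub("ve_cadherin", "vecad", ch)
      m <- mi$mean_fi[match(cells$cell_id, mi$cell_id)]
      s <- mi$integrated_fi[match(cells$cell_id, mi$cell_id)]
      cells[[paste0(key, "_", cp, "_mean")]] <- m
      cells[[paste0(key, "_", cp, "_integrated")]] <- s
    }
  }
  cells$junctional_ratio <- junctional_ratio(cells$vecad_membrane_mean,
                                             cells$vecad_whole_mean)
  cells$junctional_ratio_integrated <-
    junctional_ratio(cells$vecad_membrane_integrated,
                     cells$vecad_whole_integrated)
  cells$seed_outside_foreground <-
    cells$cell_id %in% attr(secondary, "seed_outside_foreground")
  cells$ring_is_whole_cell <-
    cells$cell_id %in% attr(membrane, "too_small_for_ring")
  if (exclude_border && length(border))
    cells <- cells[!cells$cell_id %in% border, , drop = FALSE]
  rownames(cells) <- NULL
  list(labels = list(primary = primary, secondary = secondary,
                     tertiary = tertiary, membrane = membrane,
                     border_excluded = border,
                     flags = list(
                       seed_outside_foreground =
                         attr(secondary, "seed_outside_foreground"),
                       empty_cytoplasm = attr(tertiary, "empty_cytoplasm"),
                       too_small_for_ring = attr(membrane, "too_small_for_ring"))),
       cells = cells)
}
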