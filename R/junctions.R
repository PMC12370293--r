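#' Line intensity profile across a cell-cell junction
#'
#' Samples every channel of the stack by bilinear interpolation at unit
#' spacing along the segment `p0 -> p1`, averaging over `width_px`
#' perpendicular offsets (the digital equivalent of drawing a straight line
#' of finite width across a junction).
#'
#' @param stack An [image_stack()].
#' @param p0,p1 Segment endpoints as `c(x, y)` pixel coordinates (1-based),
#'   inside the image.
#' @param width_px Averaging width in pixels (>= 1).
#' @param spacing Sample spacing along the line in pixels.
#' @return An object of class `junction_profile`: list with `distance`
#'   (px from `p0`), `intensities` (named list of per-channel vectors),
#'   `endpoints`, `width_px`, `spacing`.
#' @export
line_profile <- function(stack, p0, p1, width_px = 1L, spacing = 1) {
  stopifnot(inherits(stack, "image_stack"), width_px >= 1, spacing > 0)
  nr <- nrow(stack$channels[[1]]); nc <- ncol(stack$channels[[1]])
  for (p in list(p0, p1))
    if (p[1] < 1 || p[1] > nc || p[2] < 1 || p[2] > nr)
      stop("profile endpoint outside the image", call. = FALSE)
  d <- p1 - p0
  len <- sqrt(sum(d^2))
  tt <- if (len == 0) 0 else seq(0, len, by = spacing)
  dir <- if (len == 0) c(1, 0) else d / len
  nrm <- c(-dir[2], dir[1])
  offs <- seq(-(width_px - 1) / 2, (width_px - 1) / 2, length.out = width_px)
  xs <- outer(tt, offs, function(t, o) p0[1] + t * dir[1] + o * nrm[1])
  ys <- outer(tt, offs, function(t, o) p0[2] + t * dir[2] + o * nrm[2])
  prof <- lapply(stack$channels, function(ch) {
    v <- matrix(bilinear_interp(ch, as.vector(xs), as.vector(ys)),
                nrow = length(tt))
    rowMeans(v)
  })
  structure(list(distance = tt, intensities = prof,
                 endpoints = list(p0 = p0, p1 = p1),
                 width_px = width_px, spacing = spacing),
            class = "junction_profile")
}

#' Pearson colocalization of two channels along a profile
#'
#' @param profile A [line_profile()] result (>= 3 samples).
#' @param chA,chB Channel names to correlate.
#' @return Pearson r, or `NA` (with a warning) when either sequence has zero
#'   variance.
#' @export
profile_colocalization <- function(profile, chA = "ve_cadherin",
                                   chB = "actin") {
  stopifnot(inherits(profile, "junction_profile"))
  a <- profile$intensities[[chA]]; b <- profile$intensities[[chB]]
  if (length(a) < 3) stop("need >= 3 profile samples", call. = FALSE)
  if (stats::sd(a) == 0 || stats::sd(b) == 0) {
    warning("zero variance along the profile; colocalization undefined",
            call. = FALSE)
    return(NA_real_)
  }
  stats::cor(a, b)
}

#' VE-cadherin-positive band along cell-cell boundaries
#'
#' Cell-cell boundaries are the interfaces between distinct positive labels
#' of the segmentation (represented by a one-pixel centreline on the
#' lower-label side of each interface, grouped into edges by the unordered
#' label pair). The band is the Li-threshold foreground of the VE-cadherin
#' channel within Chebyshev distance `search_d` of any boundary pixel, with
#' each band pixel assigned to its nearest boundary edge.
#'
#' @param vecad VE-cadherin intensity matrix.
#' @param secondary Cell label matrix.
#' @param search_d Search distance from the boundary in pixels.
#' @param threshold Optional fixed foreground threshold; default Li.
#' @return An object of class `junction_band`: `band` (logical mask),
#'   `edge_map` (integer per-pixel edge index over the band and boundary),
#'   `boundary` (logical centreline mask), and `edges`, a data.frame with
#'   `edge_id`, `label_a`, `label_b`, `n_boundary_px` and `coverage` (the
#'   fraction of the edge's boundary pixels that are VE-cadherin-positive).
#'   An image with no cell-cell interfaces yields an empty band.
#' @export
junction_band <- function(vecad, secondary, search_d = 5L, threshold = NULL) {
  vecad <- .as_mat(vecad)
  lab <- secondary
  storage.mode(lab) <- "integer"
  # centreline: pixel on the lower-label side of a 4-neighbour interface
  centre <- matrix(FALSE, nrow(lab), ncol(lab))
  other <- matrix(0L, nrow(lab), ncol(lab))
  for (k in seq_len(nrow(.NBR4))) {
    sh <- .shift_mat(lab, .NBR4[k, 1], .NBR4[k, 2], 0L)
    sel <- lab > 0L & sh > lab
    centre[sel] <- TRUE
    other[sel] <- sh[sel]
  }
  empty <- structure(list(band = matrix(FALSE, nrow(lab), ncol(lab)),
                          edge_map = matrix(0L, nrow(lab), ncol(lab)),
                          boundary = centre,
                          edges = data.frame(edge_id = integer(),
                                             label_a = integer(),
                                             label_b = integer(),
                                             n_boundary_px = integer(),
                                             coverage = numeric()),
                          threshold = NA_real_, search_d = search_d),
                     class = "junction_band")
  if (!any(centre)) return(empty)
  pair_a <- lab[centre]; pair_b <- other[centre]
  key <- paste(pair_a, pair_b, sep = "-")
  ukey <- sort(unique(key))
  edge_id <- match(key, ukey)
  edge_map <- matrix(0L, nrow(lab), ncol(lab))
  edge_map[centre] <- edge_id

  th <- if (is.null(threshold)) {
    if (length(unique(as.vector(vecad))) < 2) Inf else li_threshold(vecad)
  } else threshold
  fg <- vecad > th
  within <- .as_mat(EBImage::dilate(
    centre * 1, EBImage::makeBrush(2L * as.integer(search_d) + 1L,
                                   shape = "box"))) > 0
  band <- fg & within
  edge_map <- grow_labels(edge_map, band | centre,
                          max_iter = 2L * as.integer(search_d) + 2L)
  ab <- do.call(rbind, strsplit(ukey, "-", fixed = TRUE))
  nbp <- tabulate(edge_id, nbins = length(ukey))
  cov <- tapply(fg[centre], factor(edge_id, levels = seq_along(ukey)), mean)
  edges <- data.frame(edge_id = seq_along(ukey),
                      label_a = as.integer(ab[, 1]),
                      label_b = as.integer(ab[, 2]),
                      n_boundary_px = nbp,
                      coverage = as.numeric(cov), row.names = NULL)
  structure(list(band = band, edge_map = edge_map, boundary = centre,
                 edges = edges, threshold = th, search_d = search_d),
            class = "junction_band")
}

#' Mean VE-cadherin stain width at cell-cell junctions
#'
#' The band mask is reduced to its medial axis (Zhang-Suen thinning); at
#' each medial pixel the band width is estimated as twice the Euclidean
#' distance to the nearest background pixel minus one (so a band drawn
#' `w` pixels wide measures `w`). Widths are averaged per edge and globally.
#'
#' @param band A [junction_band()] with a non-empty band.
#' @param pixel_size Pixel size in um/pixel.
#' @return A list with `mean_width_px`, `mean_width_um` and `per_edge`
#'   (data.frame: `edge_id`, `width_px`, `width_um`, `n_medial_px`).
#' @export
stain_width <- function(band, pixel_size = 1) {
  stopifnot(inherits(band, "junction_band"))
  if (!any(band$band)) {
    warning("empty band; stain width undefined", call. = FALSE)
    return(list(mean_width_px = NA_real_, mean_width_um = NA_real_,
                per_edge = data.frame(edge_id = integer(),
                                      width_px = numeric(),
                                      width_um = numeric(),
                                      n_medial_px = integer())))
  }
  skel <- thin_mask(band$band)
  d <- .as_mat(EBImage::distmap(band$band * 1))
  wpx <- 2 * d[skel] - 1
  eid <- band$edge_map[skel]
  keep <- eid > 0L
  per <- if (any(keep)) {
    f <- factor(eid[keep])
    data.frame(edge_id = as.integer(levels(f)),
               width_px = as.numeric(tapply(wpx[keep], f, mean)),
               n_medial_px = as.integer(table(f)), row.names = NULL)
  } else data.frame(edge_id = integer(), width_px = numeric(),
                    n_medial_px = integer())
  per$width_um <- per$width_px * pixel_size
  list(mean_width_px = mean(wpx), mean_width_um = mean(wpx) * pixel_size,
       per_edge = per[, c("edge_id", "width_px", "width_um", "n_medial_px")])
}

# geodesic arc length (8-connected, diagonal steps sqrt(2)) from `from` to
# `to` within the pixel set `cells` (matrix of arr.ind rows); small sets only
.geodesic_length <- function(cells, from, to) {
  n <- nrow(cells)
  key <- paste(cells[, 1], cells[, 2])
  dist <- rep(Inf, n)
  start <- match(paste(from[1], from[2]), key)
  dist[start] <- 0
  active <- start
  while (length(active)) {
    nxt <- integer(0)
    for (i in active) {
      for (k in seq_len(nrow(.NBR8))) {
        r <- cells[i, 1] + .NBR8[k, 1]; c <- cells[i, 2] + .NBR8[k, 2]
        j <- match(paste(r, c), key)
        if (!is.na(j)) {
          w <- if (.NBR8[k, 1] != 0 && .NBR8[k, 2] != 0) sqrt(2) else 1
          if (dist[i] + w < dist[j] - 1e-9) {
            dist[j] <- dist[i] + w
            nxt <- c(nxt, j)
          }
        }
      }
    }
    active <- unique(nxt)
  }
  dist[match(paste(to[1], to[2]), key)]
}

#' Detect finger-like protrusions from cell-cell junctions
#'
#' Skeletonizes the supplied foreground mask (VE-cadherin band for
#' VE-cadherin fingers; actin foreground for filopodial protrusions) and
#' keeps the skeleton pixels farther than `baseline_w / 2` from the junction
#' boundary. Each connected group of such pixels is a protrusion; its length
#' is the geodesic arc length along the skeleton from the base (the pixel
#' nearest the baseline corridor) to the tip, plus the base's distance to the
#' boundary, i.e. the full boundary-to-tip extent. Records shorter than
#' `min_len` are discarded.
#'
#' @param mask Logical foreground mask containing the protrusions.
#' @param band A [junction_band()] providing the boundary and edge map.
#' @param baseline_w Baseline corridor width in px; defaults to the measured
#'   mean stain width of the band (or 3 if that is unavailable).
#' @param min_len Minimum reported length in px.
#' @param pixel_size Pixel size in um/pixel.
#' @param channel Label stored in the records (`"ve_cadherin"` fingers or
#'   `"actin"` filopodia).
#' @return A data.frame of finger records: `finger_id`, `edge_id`,
#'   `base_x/base_y`, `tip_x/tip_y`, `length_px`, `length_um`, `channel`.
#'   Zero rows when no protrusion exceeds `min_len`.
#' @export
detect_protrusions <- function(mask, band, baseline_w = NULL, min_len = 3,
                               pixel_size = 1, channel = "ve_cadherin") {
  stopifnot(inherits(band, "junction_band"))
  mask <- .as_mat(mask) > 0
  if (is.null(baseline_w)) {
    bw <- suppressWarnings(stain_width(band)$mean_width_px)
    baseline_w <- if (is.finite(bw)) bw else 3
  }
  empty <- data.frame(finger_id = integer(), edge_id = integer(),
                      base_x = numeric(), base_y = numeric(),
                      tip_x = numeric(), tip_y = numeric(),
                      length_px = numeric(), length_um = numeric(),
                      channel = character())
  if (!any(mask) || !any(band$boundary)) return(empty)
  d2b <- dist_to_set(band$boundary)
  d_mask <- .as_mat(EBImage::distmap(mask * 1))
  skel <- thin_mask(mask)
  prot <- skel & d2b > baseline_w / 2
  if (!any(prot)) return(empty)
  comp <- label_components(prot, connectivity = 8)
  edge_full <- grow_labels(band$edge_map, matrix(TRUE, nrow(mask), ncol(mask)),
                           max_iter = 64L)
  recs <- lapply(seq_len(max(comp)), function(i) {
    px <- which(comp == i, arr.ind = TRUE)
    dd <- d2b[px]
    base <- px[which.min(dd), ]; tip <- px[which.max(dd), ]
    arc <- .geodesic_length(px, base, tip)
    if (!is.finite(arc)) arc <- sqrt(sum((tip - base)^2))
    # the skeleton endpoint sits about half a stroke width short of the mask
    # tip; add the tip's inscribed radius to recover the full extent
    tip_r <- max(d_mask[tip[1], tip[2]] - 0.5, 0)
    len <- arc + d2b[base[1], base[2]] + tip_r
    data.frame(finger_id = i,
               edge_id = edge_full[base[1], base[2]],
               base_x = base[2], base_y = base[1],
               tip_x = tip[2], tip_y = tip[1],
               length_px = len, length_um = len * pixel_size,
               channel = channel)
  })
  out <- do.call(rbind, recs)
  out <- out[out$length_px >= min_len, , drop = FALSE]
  if (nrow(out)) out$finger_id <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

#' Junction-level metrics for a segmented stack
#'
#' Convenience wrapper: builds the VE-cadherin junction band from the cell
#' labels, measures per-edge coverage and stain width, and detects
#' VE-cadherin fingers (from the band foreground) and actin filopodial
#' protrusions (from the Li-threshold actin foreground).
#'
#' @param stack An [image_stack()].
#' @param secondary Cell label matrix (e.g. from [measure_cells()]).
#' @param search_d Band search distance in px.
#' @param min_len Minimum protrusion length in px.
#' @param baseline_w Baseline corridor width in px; `NULL` uses the measured
#'   stain width.
#' @return A list with `band`, `width` (see [stain_width()]), `fingers`,
#'   `filopodia` and `edges` (per-edge data.frame joining coverage, width,
#'   and finger counts/mean lengths).
#' @export
measure_junctions <- function(stack, secondary, search_d = 5L, min_len = 3,
                              baseline_w = NULL) {
  vecad <- stack$channels$ve_cadherin
  band <- junction_band(vecad, secondary, search_d = search_d)
  wid <- suppressWarnings(stain_width(band, stack$pixel_size))
  # fingers are detected on the full VE-cadherin foreground (not the band,
  # which is clipped at search_d and would truncate long protrusions)
  vecad_fg <- if (is.finite(band$threshold)) vecad > band$threshold
              else matrix(FALSE, nrow(vecad), ncol(vecad))
  fingers <- detect_protrusions(vecad_fg, band, baseline_w = baseline_w,
                                min_len = min_len,
                                pixel_size = stack$pixel_size,
                                channel = "ve_cadherin")
  actin_fg <- stack$channels$actin > li_threshold(stack$channels$actin)
  filo <- detect_protrusions(actin_fg, band, baseline_w = baseline_w,
                             min_len = min_len,
                             pixel_size = stack$pixel_size,
                             channel = "actin")
  edges <- band$edges
  edges$width_px <- wid$per_edge$width_px[match(edges$edge_id,
                                                wid$per_edge$edge_id)]
  fc <- table(factor(fingers$edge_id, levels = edges$edge_id))
  edges$n_fingers <- as.integer(fc)
  fl <- tapply(fingers$length_px,
               factor(fingers$edge_id, levels = edges$edge_id), mean)
  edges$mean_finger_len_px <- as.numeric(fl)
  list(band = band, width = wid, fingers = fingers, filopodia = filo,
       edges = edges)
}
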