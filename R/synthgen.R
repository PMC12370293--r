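#' Specification of a synthetic endothelial monolayer image
#'
#' Parameters of the seeded generator in [generate_monolayer()]. The defaults
#' emulate a confocal field of a confluent HUVEC monolayer (1024 x 1024 px at
#' 0.16 um/px, ~90 polygonal cells) with a continuous VE-cadherin junction
#' phenotype.
#'
#' @param size Image size `c(rows, cols)` in pixels.
#' @param pixel_size Pixel size in um/pixel.
#' @param n_cells Number of cells (>= 1).
#' @param phenotype Junction phenotype: `"continuous"` (uniform VE-cadherin
#'   band along every shared edge), `"fingers"` (band plus perpendicular
#'   spikes protruding into neighbouring cells), or `"disrupted"` (band
#'   attenuated by `disruption_factor` plus cytoplasmic puncta).
#' @param band_width Drawn VE-cadherin band width in px (odd values
#'   rasterize exactly).
#' @param finger_density Expected fingers per boundary pixel of each edge
#'   (Poisson).
#' @param finger_length_mean,finger_length_sd Normal finger length
#'   parameters in px (truncated at >= 1).
#' @param intensities Named list of rendered intensity levels in \[0, 1\]:
#'   `nucleus`, `actin_fiber`, `cortical_actin`, `cytoplasm_actin`,
#'   `membrane_vecad`, `cytoplasm_vecad`, `background`.
#' @param disruption_factor Band attenuation \eqn{\delta \in [0, 1]} for the
#'   disrupted phenotype (1 = no attenuation).
#' @param puncta_count,puncta_radius Cytoplasmic VE-cadherin puncta
#'   (disrupted phenotype).
#' @param gaussian_noise_sd Additive Gaussian noise sd (intensity units).
#' @param poisson_noise Apply Poisson photon resampling before the Gaussian
#'   term?
#' @param poisson_scale Photons per unit intensity for the Poisson stage.
#' @param aspect Anisotropic stretch of the tessellation along x (> 1 gives
#'   elongated cells, emulating flow-aligned monolayers).
#' @param rng_seed Integer seed; the whole render is deterministic given the
#'   spec.
#' @return An object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(size = c(1024L, 1024L), pixel_size = 0.16,
                           n_cells = 90L,
                           phenotype = c("continuous", "fingers", "disrupted"),
                           band_width = 5L, finger_density = 0.03,
                           finger_length_mean = 10, finger_length_sd = 2,
                           intensities = list(), disruption_factor = 0.25,
                           puncta_count = 120L, puncta_radius = 2,
                           gaussian_noise_sd = 0, poisson_noise = FALSE,
                           poisson_scale = 500, aspect = 1, rng_seed = 1L) {
  phenotype <- match.arg(phenotype)
  base_int <- list(nucleus = 0.8, actin_fiber = 0.4, cortical_actin = 0.5,
                   cytoplasm_actin = 0.12, membrane_vecad = 0.75,
                   cytoplasm_vecad = 0.15, background = 0.02)
  base_int[names(intensities)] <- intensities
  if (n_cells < 1L) stop("n_cells must be >= 1", call. = FALSE)
  if (band_width < 1L) stop("band_width must be >= 1", call. = FALSE)
  if (disruption_factor < 0 || disruption_factor > 1)
    stop("disruption_factor must be in [0, 1]", call. = FALSE)
  if (any(unlist(base_int) < 0)) stop("intensities must be >= 0", call. = FALSE)
  if (aspect <= 0) stop("aspect must be > 0", call. = FALSE)
  structure(list(size = as.integer(size), pixel_size = pixel_size,
                 n_cells = as.integer(n_cells), phenotype = phenotype,
                 band_width = as.integer(band_width),
                 finger_density = finger_density,
                 finger_length_mean = finger_length_mean,
                 finger_length_sd = finger_length_sd,
                 intensities = base_int,
                 disruption_factor = disruption_factor,
                 puncta_count = as.integer(puncta_count),
                 puncta_radius = puncta_radius,
                 gaussian_noise_sd = gaussian_noise_sd,
                 poisson_noise = isTRUE(poisson_noise),
                 poisson_scale = poisson_scale, aspect = aspect,
                 rng_seed = as.integer(rng_seed)),
            class = "synthetic_spec")
}

# minimum-distance rejection sampling of cell seed points in the anisotropic
# metric; errors after a bounded number of failed draws
.place_seeds <- function(nr, nc, n, aspect, max_tries = 2000L) {
  if (n * 9 > nr * nc)
    stop("infeasible packing: too many cells for the minimum seed distance",
         call. = FALSE)
  min_d <- max(2, 0.55 * sqrt(nr * nc / aspect / n))
  sx <- numeric(0); sy <- numeric(0)
  tries <- 0L
  while (length(sx) < n) {
    tries <- tries + 1L
    if (tries > max_tries * n)
      stop("infeasible packing: too many cells for the minimum seed distance",
           call. = FALSE)
    x <- stats::runif(1, 1, nc); y <- stats::runif(1, 1, nr)
    if (length(sx)) {
      d2 <- ((x - sx) / aspect)^2 + (y - sy)^2
      if (min(d2) < min_d^2) next
    }
    sx <- c(sx, x); sy <- c(sy, y)
  }
  cbind(x = sx, y = sy)
}

# nearest-seed (discrete Voronoi) labelling in the anisotropic metric; also
# returns the distance to the bisector between the two nearest seeds,
# (d2 - d1) / 2, which is the sub-pixel distance of each pixel centre to the
# true inter-cell boundary
.assign_cells <- function(nr, nc, seeds, aspect) {
  gx <- matrix(rep(seq_len(nc), each = nr), nr)
  gy <- matrix(rep(seq_len(nr), times = nc), nr)
  best <- matrix(Inf, nr, nc)
  second <- matrix(Inf, nr, nc)
  lab <- matrix(0L, nr, nc)
  for (i in seq_len(nrow(seeds))) {
    d2 <- ((gx - seeds[i, 1]) / aspect)^2 + (gy - seeds[i, 2])^2
    take <- d2 < best
    second[take] <- best[take]
    best[take] <- d2[take]
    lab[take] <- i
    mid <- !take & d2 < second
    second[mid] <- d2[mid]
  }
  list(labels = lab, boundary_dist = (sqrt(second) - sqrt(best)) / 2)
}

#' Render a synthetic endothelial monolayer with ground truth
#'
#' Deterministic given the spec's seed. Construction: (1) cell seeds by
#' minimum-distance rejection sampling, one Lloyd relaxation step, and a
#' discrete (pixel-grid) Voronoi tessellation, anisotropically scaled by
#' `aspect`; (2) nuclei as filled ellipses (~15% of cell area, randomized
#' orientation) at cell centroids; (3) actin as a cortical rim tracing each
#' cell polygon plus random interior stress-fibre chords over a dim
#' cytoplasmic level; (4) VE-cadherin by phenotype: a band of the drawn width
#' along every shared edge, optionally with perpendicular finger spikes
#' (Poisson positions, truncated-normal lengths) or attenuated with
#' cytoplasmic puncta; (5) optional Poisson-then-Gaussian noise, clipped at
#' zero.
#'
#' @param spec A [synthetic_spec()].
#' @return A list with `stack` (an [image_stack()]) and `truth`, containing
#'   `cell_labels`, `nuclei_labels`, `cells` (per-cell data.frame with
#'   centroid, area, border flag and the true junctional ratio measured on
#'   the noise-free render over the true 3-px membrane ring), `edges`
#'   (per-edge drawn band width), `fingers` (drawn spike positions/lengths),
#'   `phenotype`, `spec`, and the noise-free `clean_ve_cadherin` channel.
#' @export
generate_monolayer <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  with_seed(spec$rng_seed, {
    nr <- spec$size[1]; nc <- spec$size[2]
    ints <- spec$intensities
    seeds <- .place_seeds(nr, nc, spec$n_cells, spec$aspect)
    cells <- .assign_cells(nr, nc, seeds, spec$aspect)$labels
    # one Lloyd step: move seeds to region centroids, re-tessellate
    idx <- which(cells > 0L, arr.ind = TRUE)
    f <- factor(cells[cells > 0L], levels = seq_len(spec$n_cells))
    seeds <- cbind(x = as.numeric(tapply(idx[, 2], f, mean)),
                   y = as.numeric(tapply(idx[, 1], f, mean)))
    vor <- .assign_cells(nr, nc, seeds, spec$aspect)
    cells <- vor$labels
    # sub-pixel distance of each pixel centre to the true inter-cell
    # boundary: bands and rims are rendered symmetric about the boundary so
    # the drawn geometry and the label map agree at the half-pixel level
    d2b <- vor$boundary_dist

    # boundary centreline (lower-label side of each 4-neighbour interface),
    # used for per-edge bookkeeping
    centre <- matrix(FALSE, nr, nc)
    other <- matrix(0L, nr, nc)
    for (k in seq_len(nrow(.NBR4))) {
      sh <- .shift_mat(cells, .NBR4[k, 1], .NBR4[k, 2], 0L)
      sel <- cells > 0L & sh > cells
      centre[sel] <- TRUE
      other[sel] <- sh[sel]
    }

    # nuclei: filled ellipses at centroids, ~15% of cell area
    idx <- which(cells > 0L, arr.ind = TRUE)
    f <- factor(cells[cells > 0L], levels = seq_len(spec$n_cells))
    area <- tabulate(cells, nbins = spec$n_cells)
    cx <- as.numeric(tapply(idx[, 2], f, mean))
    cy <- as.numeric(tapply(idx[, 1], f, mean))
    nuclei_lab <- matrix(0L, nr, nc)
    for (i in seq_len(spec$n_cells)) {
      ab <- 0.15 * area[i] / pi
      q <- stats::runif(1, 1.2, 2.2)
      a <- sqrt(ab * q); b <- sqrt(ab / q)
      th <- stats::runif(1, 0, pi)
      r0 <- max(1, floor(cy[i] - a)); r1 <- min(nr, ceiling(cy[i] + a))
      c0 <- max(1, floor(cx[i] - a)); c1 <- min(nc, ceiling(cx[i] + a))
      gx <- matrix(rep(c0:c1, each = r1 - r0 + 1), r1 - r0 + 1) - cx[i]
      gy <- matrix(rep(r0:r1, times = c1 - c0 + 1), r1 - r0 + 1) - cy[i]
      u <- gx * cos(th) + gy * sin(th)
      v <- -gx * sin(th) + gy * cos(th)
      inside <- (u / a)^2 + (v / b)^2 <= 1 &
        cells[r0:r1, c0:c1] == i
      sub <- nuclei_lab[r0:r1, c0:c1]
      sub[inside] <- i
      nuclei_lab[r0:r1, c0:c1] <- sub
      if (!any(inside))
        nuclei_lab[round(cy[i]), round(cx[i])] <- i
    }

    # actin: cytoplasmic level + cortical rim + stress-fibre chords
    actin <- matrix(ints$cytoplasm_actin, nr, nc)
    actin[d2b <= 1.5] <- ints$cortical_actin   # 3-px cortical rim
    cell_px <- split(seq_len(nr * nc), factor(as.vector(cells),
                                              levels = seq_len(spec$n_cells)))
    for (i in seq_len(spec$n_cells)) {
      px <- cell_px[[i]]
      if (length(px) < 10) next
      nf <- sample(3:8, 1)
      for (j in seq_len(nf)) {
        pq <- sample(px, 2)
        p0 <- c((pq[1] - 1) %/% nr + 1, (pq[1] - 1) %% nr + 1)  # (x, y)
        p1 <- c((pq[2] - 1) %/% nr + 1, (pq[2] - 1) %% nr + 1)
        actin <- draw_segment(actin, p0, p1, 0.8, ints$actin_fiber)
      }
    }

    # VE-cadherin band + phenotype features
    vecad <- matrix(ints$cytoplasm_vecad, nr, nc)
    band_mask <- d2b <= spec$band_width / 2
    band_level <- if (spec$phenotype == "disrupted")
      ints$membrane_vecad * spec$disruption_factor else ints$membrane_vecad
    vecad[band_mask] <- pmax(vecad[band_mask], band_level)

    # per-edge boundary pixel lists
    key <- paste(cells[centre], other[centre], sep = "-")
    bpix <- which(centre, arr.ind = TRUE)
    edges <- data.frame(edge_key = sort(unique(key)),
                        stringsAsFactors = FALSE)
    edges$n_boundary_px <- as.integer(table(key)[edges$edge_key])
    edges$band_width <- spec$band_width
    edges$band_level <- band_level

    fingers <- data.frame(edge_key = character(), x = numeric(),
                          y = numeric(), length_px = numeric(),
                          angle = numeric(), stringsAsFactors = FALSE)
    if (spec$phenotype == "fingers") {
      for (e in edges$edge_key) {
        ep <- bpix[key == e, , drop = FALSE]
        k <- stats::rpois(1, spec$finger_density * nrow(ep))
        if (k == 0) next
        for (j in seq_len(k)) {
          at <- ep[sample(nrow(ep), 1), ]
          # local tangent from nearby boundary pixels, normal is perpendicular
          near <- ep[abs(ep[, 1] - at[1]) <= 3 & abs(ep[, 2] - at[2]) <= 3, ,
                     drop = FALSE]
          if (nrow(near) >= 2) {
            pc <- stats::prcomp(near[, c(2, 1)])$rotation[, 1]
          } else pc <- c(1, 0)
          nrm <- c(-pc[2], pc[1]) * sample(c(-1, 1), 1)
          len <- max(1, stats::rnorm(1, spec$finger_length_mean,
                                     spec$finger_length_sd))
          p0 <- c(at[2], at[1])
          p1 <- p0 + len * nrm
          p1 <- pmin(pmax(p1, 1), c(nc, nr))
          vecad <- draw_segment(vecad, p0, p1, 1, ints$membrane_vecad)
          # fingers are actin-rich: draw the colocalized actin protrusion
          actin <- draw_segment(actin, p0, p1, 1, ints$cortical_actin)
          ang <- atan2(nrm[2], nrm[1])
          fingers <- rbind(fingers,
                           data.frame(edge_key = e, x = p0[1], y = p0[2],
                                      length_px = len, angle = ang,
                                      stringsAsFactors = FALSE))
        }
      }
    }
    if (spec$phenotype == "disrupted" && spec$puncta_count > 0) {
      deep <- which(d2b > spec$band_width / 2 + spec$puncta_radius + 1 &
                      nuclei_lab == 0L)
      if (length(deep)) {
        at <- sample(deep, min(spec$puncta_count, length(deep)))
        for (p in at) {
          pxy <- c((p - 1) %/% nr + 1, (p - 1) %% nr + 1)
          vecad <- draw_segment(vecad, pxy, pxy, spec$puncta_radius,
                                ints$membrane_vecad)
        }
      }
    }

    nuclei_ch <- matrix(ints$background, nr, nc)
    nuclei_ch[nuclei_lab > 0L] <- ints$nucleus

    clean_vecad <- vecad

    # ground truth: junctional ratio on the noise-free render over the true
    # 3-px membrane ring of the true cell labels
    ring <- membrane_ring(cells, 3L)
    f_ring <- factor(ring[ring > 0L], levels = seq_len(spec$n_cells))
    f_cell <- factor(cells[cells > 0L], levels = seq_len(spec$n_cells))
    ring_mean <- as.numeric(tapply(clean_vecad[ring > 0L], f_ring, mean))
    cell_mean <- as.numeric(tapply(clean_vecad[cells > 0L], f_cell, mean))
    border <- border_labels(cells)
    truth_cells <- data.frame(cell_id = seq_len(spec$n_cells),
                              centroid_x = cx, centroid_y = cy,
                              area_px = area,
                              border = seq_len(spec$n_cells) %in% border,
                              true_junctional_ratio = ring_mean / cell_mean)

    add_noise <- function(img) {
      if (spec$poisson_noise)
        img <- matrix(stats::rpois(length(img),
                                   pmax(img, 0) * spec$poisson_scale) /
                        spec$poisson_scale, nr, nc)
      if (spec$gaussian_noise_sd > 0)
        img <- img + matrix(stats::rnorm(length(img), 0,
                                         spec$gaussian_noise_sd), nr, nc)
      pmax(img, 0)
    }
    stack <- image_stack(add_noise(nuclei_ch), add_noise(actin),
                         add_noise(vecad), pixel_size = spec$pixel_size)
    list(stack = stack,
         truth = list(cell_labels = cells, nuclei_labels = nuclei_lab,
                      cells = truth_cells, edges = edges, fingers = fingers,
                      phenotype = spec$phenotype, spec = spec,
                      clean_ve_cadherin = clean_vecad))
  })
}

# md5 of the canonical JSON encoding of a spec
.spec_hash <- function(spec) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(as.character(jsonlite::toJSON(unclass(spec), auto_unbox = TRUE,
                                           digits = NA)), tmp)
  unname(tools::md5sum(tmp))
}

#' Render a batch of synthetic monolayers to disk
#'
#' Writes, per spec: the multi-channel 16-bit TIFF stack, cell and nuclei
#' ground-truth label TIFFs, a per-cell truth CSV, and (when present) the
#' drawn finger CSV; plus a JSON manifest of seeds, spec hashes, paths and
#' file checksums so a benchmark suite can be reproduced exactly.
#'
#' @param specs A list of [synthetic_spec()] objects (>= 1).
#' @param out_dir Output directory (created if needed).
#' @return The manifest data.frame (one row per spec), invisibly; also
#'   written to `manifest.json` in `out_dir`.
#' @export
sweep_monolayers <- function(specs, out_dir) {
  if (inherits(specs, "synthetic_spec")) specs <- list(specs)
  if (!length(specs)) stop("need at least one spec", call. = FALSE)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  rows <- lapply(seq_along(specs), function(i) {
    spec <- specs[[i]]
    res <- generate_monolayer(spec)
    stem <- sprintf("monolayer_%03d", i)
    stack_path <- file.path(out_dir, paste0(stem, "_stack.tif"))
    cells_path <- file.path(out_dir, paste0(stem, "_cells.tif"))
    nuc_path <- file.path(out_dir, paste0(stem, "_nuclei.tif"))
    truth_path <- file.path(out_dir, paste0(stem, "_truth.csv"))
    write_image_stack(res$stack, stack_path)
    tiff::writeTIFF(res$truth$cell_labels / 65535, cells_path,
                    bits.per.sample = 16L)
    tiff::writeTIFF(res$truth$nuclei_labels / 65535, nuc_path,
                    bits.per.sample = 16L)
    utils::write.csv(res$truth$cells, truth_path, row.names = FALSE)
    files <- c(stack_path, cells_path, nuc_path, truth_path)
    if (nrow(res$truth$fingers)) {
      fp <- file.path(out_dir, paste0(stem, "_fingers.csv"))
      utils::write.csv(res$truth$fingers, fp, row.names = FALSE)
      files <- c(files, fp)
    }
    data.frame(index = i, seed = spec$rng_seed, phenotype = spec$phenotype,
               spec_hash = .spec_hash(spec),
               stack = basename(stack_path),
               checksum = unname(tools::md5sum(stack_path)),
               stringsAsFactors = FALSE)
  })
  manifest <- do.call(rbind, rows)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       dataframe = "rows", auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}
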