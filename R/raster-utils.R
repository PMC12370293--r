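# Low-level raster helpers shared by the segmentation, junction and synthetic
# modules. Images are plain numeric matrices indexed [row = y, col = x]; label
# maps are integer matrices with 0 = background. All kernels used here are
# isotropic, so the row/column convention never leaks into results.

# shift a matrix by (dr, dc), padding with `fill`
.shift_mat <- function(m, dr, dc, fill = 0) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(fill, nr, nc)
  rs <- max(1, 1 + dr):min(nr, nr + dr)
  cs <- max(1, 1 + dc):min(nc, nc + dc)
  out[rs, cs] <- m[rs - dr, cs - dc]
  out
}

.NBR8 <- cbind(dr = c(-1, -1, -1, 0, 0, 1, 1, 1),
               dc = c(-1, 0, 1, -1, 1, -1, 0, 1))
.NBR4 <- cbind(dr = c(-1, 1, 0, 0), dc = c(0, 0, -1, 1))

.as_mat <- function(x) {
  if (inherits(x, "Image")) x <- EBImage::imageData(x)
  as.matrix(x)
}

# connected-component labeling; EBImage::bwlabel is 4-connected, so for
# 8-connectivity labels that touch diagonally are merged with a union-find
# pass over the (small) label graph
label_components <- function(mask, connectivity = 8) {
  mask <- .as_mat(mask) > 0
  lab <- .as_mat(EBImage::bwlabel(mask))
  storage.mode(lab) <- "integer"
  n <- max(lab)
  if (connectivity == 8 && n > 1) {
    parent <- seq_len(n)
    find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
    for (k in 1:4) {  # 4 diagonal directions suffice (symmetric pairs)
      sh <- .shift_mat(lab, c(-1, -1, 1, 1)[k], c(-1, 1, -1, 1)[k], 0L)
      sel <- lab > 0L & sh > 0L & lab != sh
      if (any(sel)) {
        prs <- unique(cbind(lab[sel], sh[sel]))
        for (r in seq_len(nrow(prs))) {
          a <- find(prs[r, 1]); b <- find(prs[r, 2])
          if (a != b) parent[max(a, b)] <- min(a, b)
        }
      }
    }
    root <- vapply(seq_len(n), find, integer(1))
    lab[lab > 0L] <- root[lab[lab > 0L]]
  }
  relabel_sequential(lab)
}

# renumber positive labels to 1..k preserving order of first appearance by id
relabel_sequential <- function(lab) {
  ids <- sort(unique(lab[lab > 0L]))
  if (!length(ids)) return(lab)
  map <- integer(max(ids)); map[ids] <- seq_along(ids)
  lab[lab > 0L] <- map[lab[lab > 0L]]
  storage.mode(lab) <- "integer"
  lab
}

# one step of per-object erosion with the 3x3 8-connected structuring element;
# outside the image counts as background
.erode_labels_once <- function(lab) {
  keep <- lab > 0L
  for (k in seq_len(nrow(.NBR8))) {
    sh <- .shift_mat(lab, .NBR8[k, 1], .NBR8[k, 2], 0L)
    keep <- keep & sh == lab
  }
  out <- lab; out[!keep] <- 0L
  out
}

# Euclidean distance of every pixel to the nearest TRUE pixel of `set`
dist_to_set <- function(set) {
  set <- .as_mat(set) > 0
  if (!any(set)) return(matrix(Inf, nrow(set), ncol(set)))
  .as_mat(EBImage::distmap(1 - set))
}

# grow integer labels outward over `allowed` pixels, 8-connected, one pixel
# per iteration (Chebyshev-nearest assignment); used to assign band pixels to
# boundary edges
grow_labels <- function(seed_lab, allowed, max_iter = 64L) {
  lab <- seed_lab
  for (it in seq_len(max_iter)) {
    unassigned <- allowed & lab == 0L
    if (!any(unassigned)) break
    changed <- FALSE
    for (k in seq_len(nrow(.NBR8))) {
      sh <- .shift_mat(lab, .NBR8[k, 1], .NBR8[k, 2], 0L)
      take <- unassigned & lab == 0L & sh > 0L
      if (any(take)) { lab[take] <- sh[take]; changed <- TRUE }
    }
    if (!changed) break
  }
  lab
}

# Zhang-Suen binary thinning to a 1-px skeleton (8-connected foreground)
thin_mask <- function(mask, max_iter = 1000L) {
  m <- (.as_mat(mask) > 0) * 1L
  if (!any(m > 0)) return(m > 0)
  nbrs <- function(m) {
    list(P2 = .shift_mat(m, 1, 0),  P3 = .shift_mat(m, 1, -1),
         P4 = .shift_mat(m, 0, -1), P5 = .shift_mat(m, -1, -1),
         P6 = .shift_mat(m, -1, 0), P7 = .shift_mat(m, -1, 1),
         P8 = .shift_mat(m, 0, 1),  P9 = .shift_mat(m, 1, 1))
  }
  for (it in seq_len(max_iter)) {
    changed <- FALSE
    for (step in 1:2) {
      p <- nbrs(m)
      B <- p$P2 + p$P3 + p$P4 + p$P5 + p$P6 + p$P7 + p$P8 + p$P9
      seq9 <- list(p$P2, p$P3, p$P4, p$P5, p$P6, p$P7, p$P8, p$P9, p$P2)
      A <- matrix(0L, nrow(m), ncol(m))
      for (i in 1:8) A <- A + (seq9[[i]] == 0L & seq9[[i + 1]] == 1L)
      if (step == 1) {
        cond <- p$P2 * p$P4 * p$P6 == 0L & p$P4 * p$P6 * p$P8 == 0L
      } else {
        cond <- p$P2 * p$P4 * p$P8 == 0L & p$P2 * p$P6 * p$P8 == 0L
      }
      del <- m == 1L & B >= 2L & B <= 6L & A == 1L & cond
      if (any(del)) { m[del] <- 0L; changed <- TRUE }
    }
    if (!changed) break
  }
  m > 0
}

# bilinear interpolation of img at fractional (x, y) pixel coordinates
# (1-based, x = column, y = row); vectorised
bilinear_interp <- function(img, x, y) {
  nr <- nrow(img); nc <- ncol(img)
  x <- pmin(pmax(x, 1), nc); y <- pmin(pmax(y, 1), nr)
  x0 <- pmin(floor(x), nc - 1); y0 <- pmin(floor(y), nr - 1)
  fx <- x - x0; fy <- y - y0
  i00 <- img[cbind(y0, x0)];     i01 <- img[cbind(y0, x0 + 1)]
  i10 <- img[cbind(y0 + 1, x0)]; i11 <- img[cbind(y0 + 1, x0 + 1)]
  i00 * (1 - fx) * (1 - fy) + i01 * fx * (1 - fy) +
    i10 * (1 - fx) * fy + i11 * fx * fy
}

# set pixels within `radius` of the segment p0-p1 (x, y pixel coords) to
# pmax(current, value); returns the modified image
draw_segment <- function(img, p0, p1, radius, value) {
  nr <- nrow(img); nc <- ncol(img)
  r0 <- max(1, floor(min(p0[2], p1[2]) - radius - 1))
  r1 <- min(nr, ceiling(max(p0[2], p1[2]) + radius + 1))
  c0 <- max(1, floor(min(p0[1], p1[1]) - radius - 1))
  c1 <- min(nc, ceiling(max(p0[1], p1[1]) + radius + 1))
  if (r0 > r1 || c0 > c1) return(img)
  gx <- matrix(rep(c0:c1, each = r1 - r0 + 1), r1 - r0 + 1)
  gy <- matrix(rep(r0:r1, times = c1 - c0 + 1), r1 - r0 + 1)
  d <- p1 - p0
  len2 <- sum(d^2)
  if (len2 == 0) {
    dist <- sqrt((gx - p0[1])^2 + (gy - p0[2])^2)
  } else {
    t <- ((gx - p0[1]) * d[1] + (gy - p0[2]) * d[2]) / len2
    t <- pmin(pmax(t, 0), 1)
    dist <- sqrt((gx - (p0[1] + t * d[1]))^2 + (gy - (p0[2] + t * d[2]))^2)
  }
  sub <- img[r0:r1, c0:c1]
  sub[dist <= radius] <- pmax(sub[dist <= radius], value)
  img[r0:r1, c0:c1] <- sub
  img
}

# evaluate `code` under a fixed RNG seed, restoring the caller's RNG state
with_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}
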