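# Independent oracles used by the test suite. These deliberately share no
# code with the package implementation.

# Finite-difference solution of the duct Poisson problem: -grad^2 u = C with
# no-slip walls on [-W, W] x [-H, H], then rescaled so the cross-sectional
# integral equals Q. Returns the grid and the scaled velocity field.
fd_duct_solution <- function(W, H, Q, nx = 401L, ny = 41L) {
  x <- seq(-W, W, length.out = nx)
  y <- seq(-H, H, length.out = ny)
  dx <- x[2] - x[1]; dy <- y[2] - y[1]
  ix <- 2:(nx - 1); iy <- 2:(ny - 1)
  nxi <- length(ix); nyi <- length(iy)
  n <- nxi * nyi
  k <- seq_len(n)
  gi <- (k - 1L) %% nxi + 1L   # index along x
  gj <- (k - 1L) %/% nxi + 1L  # index along y
  ii <- c(k, k[gi > 1], k[gi < nxi], k[gj > 1], k[gj < nyi])
  jj <- c(k, k[gi > 1] - 1L, k[gi < nxi] + 1L,
          k[gj > 1] - nxi, k[gj < nyi] + nxi)
  vv <- c(rep(2 / dx^2 + 2 / dy^2, n),
          rep(-1 / dx^2, sum(gi > 1) + sum(gi < nxi)),
          rep(-1 / dy^2, sum(gj > 1) + sum(gj < nyi)))
  A <- Matrix::sparseMatrix(i = ii, j = jj, x = vv, dims = c(n, n))
  u_int <- as.numeric(Matrix::solve(A, rep(1, n)))
  u <- matrix(0, nx, ny)
  u[ix, iy] <- matrix(u_int, nxi, nyi)
  # trapezoidal cross-sectional flux (u = 0 on the walls)
  wx <- rep(1, nx); wx[c(1, nx)] <- 0.5
  wy <- rep(1, ny); wy[c(1, ny)] <- 0.5
  flux <- as.numeric(t(wx) %*% u %*% wy) * dx * dy
  u <- u * Q / flux
  list(x = x, y = y, u = u, dx = dx, dy = dy)
}

# wall shear stress magnitude on the bottom wall from the FD field, using a
# second-order one-sided difference (u = 0 on the wall itself)
fd_wss_bottom <- function(fd, mu) {
  u1 <- fd$u[, 2]; u2 <- fd$u[, 3]
  abs(mu * (4 * u1 - u2) / (2 * fd$dy))
}

# brute-force minimum cross-entropy threshold: minimize the Li criterion over
# every candidate split between consecutive unique values
li_bruteforce <- function(x) {
  x <- as.numeric(x)
  off <- if (min(x) <= 0) diff(range(x)) * 1e-6 - min(x) else 0
  xs <- sort(x + off)
  u <- unique(xs)
  cand <- (u[-1] + u[-length(u)]) / 2
  crit <- vapply(cand, function(t) {
    lo <- xs[xs <= t]; hi <- xs[xs > t]
    -(sum(lo) * log(mean(lo)) + sum(hi) * log(mean(hi)))
  }, numeric(1))
  cand[which.min(crit)] - off
}

# brute-force per-object erosion with the 3x3 structuring element, written as
# an explicit pixel loop (independent of the vectorised implementation)
erode_labels_bruteforce <- function(lab, n_px) {
  for (it in seq_len(n_px)) {
    out <- lab
    nr <- nrow(lab); nc <- ncol(lab)
    for (r in seq_len(nr)) {
      for (c in seq_len(nc)) {
        if (lab[r, c] == 0L) next
        for (dr in -1:1) {
          for (dc in -1:1) {
            rr <- r + dr; cc <- c + dc
            v <- if (rr < 1 || rr > nr || cc < 1 || cc > nc) 0L
                 else lab[rr, cc]
            if (v != lab[r, c]) out[r, c] <- 0L
          }
        }
      }
    }
    lab <- out
  }
  lab
}

# rasterized disk mask
disk_mask <- function(n, r, cx = (n + 1) / 2, cy = (n + 1) / 2) {
  xy <- expand.grid(row = seq_len(n), col = seq_len(n))
  matrix((xy$col - cx)^2 + (xy$row - cy)^2 <= r^2, n, n)
}
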