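# Thresholding, compartmented segmentation and per-cell measurement.

test_that("Li threshold agrees with brute-force cross-entropy minimisation", {
  # two-valued image: threshold must separate the two populations
  x <- c(rep(10, 900), rep(200, 100))
  t_it <- li_threshold(x)
  t_bf <- li_bruteforce(x)
  expect_gt(t_it, 10); expect_lt(t_it, 200)
  expect_gt(t_bf, 10); expect_lt(t_bf, 200)
  # both choose the same partition
  expect_identical(x > t_it, x > t_bf)
  # bimodal image: same partition as the brute-force oracle
  set.seed(42)
  y <- c(rnorm(800, 30, 5), rnorm(200, 150, 20))
  y <- pmax(round(y), 0)
  t_it <- li_threshold(y)
  t_bf <- li_bruteforce(y)
  expect_identical(y > t_it, y > t_bf)
})

test_that("Li threshold is scale-equivariant and rejects constant images", {
  x <- c(rep(10, 900), rep(200, 100))
  expect_equal(li_threshold(3 * x), 3 * li_threshold(x), tolerance = 1e-4)
  expect_error(li_threshold(rep(5, 100)), "degenerate")
})

test_that("primary segmentation: disks are counted, bridges merge, dust drops", {
  img <- matrix(0.02, 120, 120)
  centers <- cbind(c(20, 20, 60, 100, 100), c(20, 100, 60, 20, 100))
  for (i in seq_len(5)) {
    d <- disk_mask(120, 8, centers[i, 1], centers[i, 2])
    img[d] <- 0.8
  }
  lab <- segment_primary(img, min_area_px = 50L)
  expect_equal(max(lab), 5L)
  # a 1-px bridge merges two disks into one object (no declumping)
  img2 <- matrix(0.02, 120, 120)
  img2[disk_mask(120, 8, 40, 60)] <- 0.8
  img2[disk_mask(120, 8, 80, 60)] <- 0.8
  img2[60, 40:80] <- 0.8
  expect_equal(max(segment_primary(img2, min_area_px = 50L)), 1L)
  # objects below min_area vanish
  img3 <- matrix(0.02, 60, 60)
  img3[disk_mask(60, 3, 30, 30)] <- 0.8
  expect_warning(lab3 <- segment_primary(img3, min_area_px = 50L), "no nuclei")
  expect_equal(max(lab3), 0L)
})

test_that("secondary segmentation splits a dumbbell along the distance ridge", {
  # uniform intensity inside the dumbbell: propagation cost reduces to
  # spatial distance, so the split must fall on the bridge midline
  # disks centred at (row 15, col 30) and (row 45, col 30), joined by a
  # vertical bridge along col 28:32
  n <- 60
  img <- matrix(0.01, n, n)
  img[disk_mask(n, 10, 30, 15)] <- 0.6
  img[disk_mask(n, 10, 30, 45)] <- 0.6
  img[15:45, 28:32] <- 0.6
  nuc <- matrix(0, n, n)
  nuc[disk_mask(n, 3, 30, 15)] <- 0.9
  nuc[disk_mask(n, 3, 30, 45)] <- 0.9
  prim <- segment_primary(nuc, min_area_px = 10L)
  expect_equal(max(prim), 2L)
  sec <- segment_secondary(img, prim, fill_border_holes = FALSE)
  expect_setequal(unique(as.vector(sec[sec > 0L])), c(1L, 2L))
  # each secondary contains its seed, secondaries partition the foreground
  expect_true(all(sec[prim == 1L] == 1L))
  expect_true(all(sec[prim == 2L] == 2L))
  fg <- img > li_threshold(img)
  expect_true(all(sec[fg] > 0L))
  # balanced split: the bridge divides close to its midpoint
  expect_lt(abs(sum(sec == 1L) - sum(sec == 2L)) / sum(sec > 0L), 0.1)
  # ridge position: the bridge column splits near row 30
  bridge_rows <- sec[15:45, 30]
  expect_lt(abs(sum(bridge_rows == 1L) - sum(bridge_rows == 2L)), 5)
})

test_that("a seed outside the actin foreground is still grown and flagged", {
  n <- 40
  img <- matrix(0.01, n, n)
  img[disk_mask(n, 8, 20, 12)] <- 0.6
  nuc <- matrix(0, n, n)
  nuc[disk_mask(n, 3, 20, 12)] <- 0.9
  nuc[disk_mask(n, 3, 20, 32)] <- 0.9    # seed in background
  prim <- segment_primary(nuc, min_area_px = 10L)
  sec <- segment_secondary(img, prim, fill_border_holes = FALSE)
  flagged <- attr(sec, "seed_outside_foreground")
  expect_equal(length(flagged), 1L)
  expect_true(all(sec[prim == flagged] == flagged))
})

test_that("tertiary cytoplasm is the per-cell set difference", {
  sec <- matrix(0L, 20, 20); sec[3:18, 3:18] <- 1L
  prim <- matrix(0L, 20, 20); prim[8:12, 8:12] <- 1L
  cyto <- tertiary_cytoplasm(sec, prim)
  expect_equal(sum(cyto == 1L), sum(sec == 1L) - sum(prim == 1L))
  expect_true(all(cyto[prim == 1L] == 0L))
  # nucleus filling the whole cell leaves an empty, flagged cytoplasm
  cyto2 <- tertiary_cytoplasm(prim, prim)
  expect_equal(sum(cyto2), 0)
  expect_equal(attr(cyto2, "empty_cytoplasm"), 1L)
  # mismatched ids are an invariant violation
  prim_bad <- prim; prim_bad[prim_bad == 1L] <- 2L
  expect_error(tertiary_cytoplasm(sec, prim_bad), "match")
})

test_that("shrink_labels matches explicit erosion and composes", {
  lab <- matrix(0L, 20, 20)
  lab[5:13, 5:13] <- 1L                       # 9x9 square
  s3 <- shrink_labels(lab, 3L)
  expect_equal(sum(s3 == 1L), 9)              # 3x3 core
  expect_equal(s3, erode_labels_bruteforce(lab, 3L), ignore_attr = TRUE)
  # 5x5 square erodes to extinction at 3 px
  lab2 <- matrix(0L, 12, 12); lab2[4:8, 4:8] <- 1L
  s <- shrink_labels(lab2, 3L)
  expect_equal(sum(s), 0)
  expect_equal(attr(s, "extinct"), 1L)
  # shrink(shrink(x, 1), 1) == shrink(x, 2), also for touching objects
  lab3 <- matrix(0L, 24, 24)
  lab3[4:20, 4:11] <- 1L; lab3[4:20, 12:20] <- 2L
  expect_equal(shrink_labels(shrink_labels(lab3, 1L), 1L),
               shrink_labels(lab3, 2L), ignore_attr = TRUE)
  expect_equal(shrink_labels(lab3, 2L),
               erode_labels_bruteforce(lab3, 2L), ignore_attr = TRUE)
})

test_that("membrane ring: 9x9 square gives the exact 72-pixel ring", {
  lab <- matrix(0L, 20, 20); lab[5:13, 5:13] <- 1L
  ring <- membrane_ring(lab, 3L)
  expect_equal(sum(ring == 1L), 81 - 9)
  # ring and shrunk partition the cell
  shr <- shrink_labels(lab, 3L)
  expect_true(all((ring > 0L) != (shr > 0L) | lab == 0L))
  expect_equal(sum(ring > 0L) + sum(shr > 0L), sum(lab > 0L))
  # disk: ring pixel count matches brute-force erosion
  disk <- matrix(0L, 25, 25); disk[disk_mask(25, 10)] <- 1L
  ring_d <- membrane_ring(disk, 3L)
  core <- erode_labels_bruteforce(disk, 3L)
  expect_equal(sum(ring_d > 0L), sum(disk > 0L) - sum(core > 0L))
  # too-small cell keeps its whole footprint as the ring, flagged
  small <- matrix(0L, 10, 10); small[4:6, 4:6] <- 1L
  ring_s <- membrane_ring(small, 3L)
  expect_equal(sum(ring_s > 0L), 9)
  expect_equal(attr(ring_s, "too_small_for_ring"), 1L)
})

test_that("shape measures: disk, line and physical area scaling", {
  disk <- matrix(0L, 45, 45); disk[disk_mask(45, 20)] <- 1L
  sh <- measure_shape(disk, pixel_size = 1)
  expect_lt(sh$eccentricity, 0.1)
  expect_gt(sh$circularity, 0.85)
  expect_lte(sh$circularity, 1.05)
  expect_equal(sh$compactness, 1 / sh$circularity)
  # a 1xN line approaches eccentricity 1 while staying below it
  line <- matrix(0L, 5, 40); line[3, 3:38] <- 1L
  shl <- measure_shape(line)
  expect_gt(shl$eccentricity, 0.99)
  expect_lt(shl$eccentricity, 1)
  # area in physical units
  sq <- matrix(0L, 15, 15); sq[4:12, 4:12] <- 1L
  expect_equal(measure_shape(sq, pixel_size = 0.1)$area_um2, 0.81)
  expect_error(measure_shape(matrix(0L, 5, 5)), "no labelled")
})

test_that("intensity measures: means, integrals, checkerboard", {
  lab <- matrix(0L, 10, 10); lab[3:6, 3:6] <- 1L; lab[8:9, 8:9] <- 2L
  const <- matrix(7, 10, 10)
  mi <- measure_intensity(lab, const)
  expect_equal(mi$mean_fi, c(7, 7))
  expect_equal(mi$integrated_fi, mi$mean_fi * mi$n_px)
  chk <- matrix(rep(c(0, 100), 50), 10, 10)
  mi2 <- measure_intensity(lab, chk)
  expect_equal(mi2$mean_fi[1], 50)
})

test_that("junctional ratio: uniform, ring-confined and degenerate cases", {
  expect_equal(junctional_ratio(5, 5), 1)
  # all signal in the ring: ratio = cell px / ring px
  lab <- matrix(0L, 20, 20); lab[5:13, 5:13] <- 1L
  ring <- membrane_ring(lab, 3L)
  img <- matrix(0, 20, 20); img[ring == 1L] <- 1
  m_r <- measure_intensity(ring, img)$mean_fi
  m_w <- measure_intensity(lab, img)$mean_fi
  expect_equal(junctional_ratio(m_r, m_w), 81 / 72)
  expect_true(is.na(junctional_ratio(0, 0)))
})

test_that("full measurement pipeline recovers interior cells one-to-one", {
  res <- generate_monolayer(synthetic_spec(size = c(256L, 256L),
                                           n_cells = 18L, rng_seed = 3L))
  m <- measure_cells(res$stack)
  tl <- res$truth$cell_labels
  sec <- m$labels$secondary
  interior <- res$truth$cells$cell_id[!res$truth$cells$border]
  matched <- 0L
  for (i in interior) {
    tpx <- tl == i
    ov <- table(sec[tpx]); ov <- ov[names(ov) != "0"]
    if (!length(ov)) next
    cand <- as.integer(names(ov)[which.max(ov)])
    iou <- sum(tpx & sec == cand) / sum(tpx | sec == cand)
    if (iou > 0.7) matched <- matched + 1L
  }
  expect_gte(matched / length(interior), 0.95)
  # compartment partition invariants hold on every cell
  lb <- m$labels
  expect_true(all(lb$tertiary[lb$primary > 0L] == 0L))
  on_cells <- lb$secondary > 0L
  expect_true(all((lb$tertiary[on_cells] > 0L) + (lb$primary[on_cells] > 0L) <= 1))
  ring_or_core <- (lb$membrane > 0L)
  shr <- lb$secondary > 0L & lb$membrane == 0L
  expect_true(all(xor(ring_or_core[on_cells], shr[on_cells])))
  # border-touching cells are excluded from the records
  expect_false(any(m$cells$cell_id %in% lb$border_excluded))
})

test_that("junctional ratio is invariant under channel rescaling", {
  res <- generate_monolayer(synthetic_spec(size = c(192L, 192L),
                                           n_cells = 10L, rng_seed = 5L))
  st <- res$stack
  m1 <- measure_cells(st)
  st2 <- image_stack(st$channels$nuclei, st$channels$actin,
                     st$channels$ve_cadherin * 4.2,
                     pixel_size = st$pixel_size)
  m2 <- measure_cells(st2)
  expect_equal(m2$cells$junctional_ratio, m1$cells$junctional_ratio,
               tolerance = 1e-12)
})
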