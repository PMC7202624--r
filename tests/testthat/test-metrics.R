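full_fov <- function(nr, nc) matrix(TRUE, nr, nc)

seg <- function(m, s = 1, fov = NULL)
  segmentation_mask(m, s, fov %||% full_fov(nrow(m), ncol(m)))
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("skeletonize: thin lines unchanged, rectangles reduce to midline", {
  line <- matrix(FALSE, 9, 30); line[5, 3:28] <- TRUE
  expect_identical(skeletonize(seg(line))$skeleton, line)
  diagl <- matrix(FALSE, 20, 20)
  for (i in 3:17) diagl[i, i] <- TRUE
  expect_identical(skeletonize(seg(diagl))$skeleton, diagl)
  rect <- matrix(FALSE, 9, 25); rect[3:7, 3:23] <- TRUE
  sk <- skeletonize(seg(rect))$skeleton
  pts <- which(sk, arr.ind = TRUE)
  expect_true(all(pts[, 1] == 5))                  # middle row only
  expect_gte(min(pts[, 2]), 3 + 1)
  expect_lte(max(pts[, 2]), 23 - 1)                # central span
})

test_that("skeletonization preserves components and holes", {
  set.seed(40)
  for (s in 1:20) {
    ph <- quick_phantom(s, size = 96, n_seeds = sample(6:26, 1),
                        edge_keep_prob = runif(1, 0.6, 1))
    m <- ph$truth$true_mask
    sk <- skeletonize(seg(m, ph$truth$spacing_um, ph$truth$fov_mask))
    expect_true(all(m[sk$skeleton]))              # skeleton within mask
    expect_equal(attr(pcleQuant:::cpp_label(sk$skeleton, 8L), "n"),
                 attr(pcleQuant:::cpp_label(m, 8L), "n"))
    expect_equal(count_holes_euler(sk$skeleton), count_holes_euler(m))
  }
})

test_that("skeleton length follows the pixel-count convention", {
  horiz <- matrix(FALSE, 5, 110); horiz[3, 4:103] <- TRUE
  sk <- skeletonize(seg(horiz, 1))
  expect_equal(skeleton_length(sk), 100)
  diagl <- matrix(FALSE, 110, 110)
  for (i in 4:103) diagl[i, i] <- TRUE
  skd <- skeletonize(seg(diagl, 1))
  expect_equal(skeleton_length(skd), 100)               # pixel count
  expect_equal(skeleton_length(skd, convention = "weighted"),
               99 * sqrt(2))                            # polyline links
  empty <- skeletonize(seg(matrix(FALSE, 5, 5), 1))
  expect_equal(skeleton_length(empty), 0)
})

test_that("Euler hole count: disk, figure-eight, flood-fill equivalence", {
  n <- 41
  d <- outer((1:n - 21)^2, (1:n - 21)^2, "+") <= 15^2
  expect_equal(count_holes_euler(d), 0)
  # figure-eight: two fused rings
  m <- matrix(FALSE, 30, 50)
  ring <- function(ci, cj) {
    dd <- outer((1:30 - ci)^2, (1:50 - cj)^2, "+")
    dd <= 10^2 & dd >= 6^2
  }
  fe <- ring(15, 15) | ring(15, 28)
  expect_equal(attr(pcleQuant:::cpp_label(fe, 8L), "n"), 1)
  expect_equal(count_holes_euler(fe), 2)
  expect_equal(oracle_hole_count(fe), 2)
  set.seed(41)
  for (s in 1:30) {
    m <- random_blob_mask(sample(48:128, 1), seed = s)
    expect_equal(count_holes_euler(m),
                 oracle_hole_count(m, NULL),
                 label = sprintf("blob seed %d", s))
  }
})

test_that("connectivity is holes per millimetre of skeleton", {
  # annulus with known skeleton: circle of radius ~30 px
  n <- 81
  dd <- outer((1:n - 41)^2, (1:n - 41)^2, "+")
  ann <- dd <= 34^2 & dd >= 26^2
  sm <- seg(ann, 1)
  sk <- skeletonize(sm)
  cs <- connectivity(sm, sk)
  expect_equal(cs, 1 / (skeleton_length(sk) / 1000))
  # solid disk: zero holes
  disk <- seg(dd <= 30^2, 1)
  expect_equal(connectivity(disk, skeletonize(disk)), 0)
  # empty skeleton errors
  expect_error(connectivity(seg(matrix(FALSE, 9, 9)),
                            skeletonize(seg(matrix(FALSE, 9, 9)))),
               "skeleton length is zero")
})

test_that("local thickness doubles the distance to nearest background", {
  # 11 px tall ribbon at 1 um/px: interior T_local = 12 um
  rb <- matrix(FALSE, 15, 60); rb[3:13, ] <- TRUE
  sm <- seg(rb, 1)
  prof <- local_thickness(sm, skeletonize(sm))
  expect_equal(median(prof$T_local_um), 12)
  expect_equal(prof$T_local_um, 2 * prof$d_np_um)
  # solid disk of radius 20: central thickness ~ 40 um within 1 px
  n <- 51
  dd <- outer((1:n - 26)^2, (1:n - 26)^2, "+")
  disk <- seg(dd <= 20^2, 1)
  profd <- local_thickness(disk, skeletonize(disk))
  expect_lt(abs(max(profd$T_local_um) - 40), 2 * 1)
  # brute-force oracle equivalence on random blobs
  set.seed(42)
  for (s in 1:6) {
    m <- random_blob_mask(56, seed = s + 100)
    if (!any(m)) next
    sm2 <- seg(m, 1.3, inscribed_disk_mask(56, 56))
    sk2 <- skeletonize(sm2)
    if (!any(sk2$skeleton)) next
    prof2 <- local_thickness(sm2, sk2)
    want <- oracle_nearest_bg(m, which(sk2$skeleton)) * 1.3
    expect_equal(prof2$d_np_um, want, tolerance = 1e-12)
  }
})

test_that("summarize_thickness: median, population sd, naive oracle", {
  p <- structure(list(T_local_um = c(4, 6, 8), d_np_um = c(2, 3, 4),
                      n_points = 3L, pixels = 1:3),
                 class = "thickness_profile")
  s <- summarize_thickness(p)
  expect_equal(s$T_med_um, 6)
  expect_equal(s$sigma_T_um, sqrt(sum((c(4, 6, 8) - 6)^2) / 3))
  p$T_local_um <- rep(5, 10)
  expect_equal(summarize_thickness(p)$sigma_T_um, 0)
  set.seed(43)
  x <- rexp(501, 0.1)
  p$T_local_um <- x
  s2 <- summarize_thickness(p)
  expect_equal(s2$T_med_um, sort(x)[251])
  expect_equal(s2$sigma_T_um, sqrt(mean((x - mean(x))^2)))
})

test_that("quantify_mask recovers phantom truth and flags empty masks", {
  ph <- quick_phantom(12, size = 128, n_seeds = 16)
  sm <- seg(ph$truth$true_mask, ph$truth$spacing_um, ph$truth$fov_mask)
  got <- quantify_mask(sm, clean = FALSE)
  expect_false(got$excluded)
  expect_equal(got$n_holes, ph$truth$true_hole_count)
  expect_equal(got$C_s_per_mm,
               got$n_holes / (got$skeleton_length_um / 1000))
  # determinism
  expect_identical(unclass(quantify_mask(sm))[1:8], unclass(quantify_mask(sm))[1:8])
  # empty mask excluded
  empty <- seg(matrix(FALSE, 70, 70), 1, inscribed_disk_mask(70, 70))
  flagged <- quantify_mask(empty)
  expect_true(flagged$excluded)
  expect_match(flagged$exclusion_reason, "irregularity")
})
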