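# Multi-scale filter bank for trainable pixel classification.
#
# Seven filter families (Gaussian smoothing, gradient magnitude,
# Laplacian, Hessian eigenvalues, difference-of-Gaussians, local
# variance, local median), each at scales sigma in {1, 2, 4, 8, 16}
# pixels. The bank is fixed and documented rather than tied to any
# particular GUI tool's unstated default; it spans smoothing, edges,
# ridges and texture, which is what separates fibrous elastin from
# hazy background.

.default_scales <- c(1, 2, 4, 8, 16)
.default_families <- c("gauss", "gradmag", "laplacian", "hessian",
                       "dog", "variance", "median")

#' Sampled, normalized 1D Gaussian kernel
#' @param sigma standard deviation in pixels.
#' @return numeric vector of odd length (radius = 3 sigma).
#' @export
gaussian_kernel <- function(sigma) {
  r <- max(1L, ceiling(3 * sigma))
  x <- (-r):r
  k <- exp(-x^2 / (2 * sigma^2))
  k / sum(k)
}

# central-difference derivatives with replicated edges
.diff_x <- function(m) { # along columns (horizontal)
  nc <- ncol(m)
  right <- m[, c(2:nc, nc)]
  left <- m[, c(1, 1:(nc - 1))]
  (right - left) / 2
}
.diff_y <- function(m) { # along rows (vertical)
  nr <- nrow(m)
  down <- m[c(2:nr, nr), ]
  up <- m[c(1, 1:(nr - 1)), ]
  (down - up) / 2
}

#' Compute the per-pixel feature stack of an image
#'
#' Deterministic multi-scale features with reflective boundary padding.
#' Pixels outside the FOV carry features too (they are flagged via the
#' `fov` element and simply forced to background at prediction time).
#'
#' @param image a [pcle_image].
#' @param scales Gaussian scales (pixels).
#' @param families subset of
#'   `c("gauss","gradmag","laplacian","hessian","dog","variance","median")`.
#' @return a `feature_stack`: list with `values` (pixel x feature matrix,
#'   pixels in column-major order), `feature_names`, `dim`, `fov`
#'   (logical vector), `spacing_um`, `bank` (scales/families config).
#' @export
compute_features <- function(image, scales = .default_scales,
                             families = .default_families) {
  stopifnot(inherits(image, "pcle_image"))
  families <- match.arg(families, .default_families, several.ok = TRUE)
  px <- image$pixels
  feats <- list()
  for (s in scales) {
    k <- gaussian_kernel(s)
    g <- cpp_sepconv(px, k)
    gx <- .diff_x(g); gy <- .diff_y(g)
    gxx <- .diff_x(gx); gyy <- .diff_y(gy); gxy <- .diff_y(gx)
    if ("gauss" %in% families)
      feats[[sprintf("gauss_s%g", s)]] <- g
    if ("gradmag" %in% families)
      feats[[sprintf("gradmag_s%g", s)]] <- sqrt(gx^2 + gy^2)
    if ("laplacian" %in% families)
      feats[[sprintf("laplacian_s%g", s)]] <- gxx + gyy
    if ("hessian" %in% families) {
      tr <- gxx + gyy
      disc <- sqrt(pmax((gxx - gyy)^2 + 4 * gxy^2, 0))
      feats[[sprintf("hessmax_s%g", s)]] <- (tr + disc) / 2
      feats[[sprintf("hessmin_s%g", s)]] <- (tr - disc) / 2
    }
    if ("dog" %in% families)
      feats[[sprintf("dog_s%g", s)]] <- g - cpp_sepconv(px, gaussian_kernel(1.6 * s))
    if ("variance" %in% families) {
      m2 <- cpp_sepconv(px^2, k)
      feats[[sprintf("variance_s%g", s)]] <- pmax(m2 - g^2, 0)
    }
    if ("median" %in% families)
      feats[[sprintf("median_s%g", s)]] <- cpp_median_filter(px, ceiling(s))
  }
  values <- vapply(feats, as.vector, numeric(length(px)))
  structure(
    list(values = values, feature_names = colnames(values),
         dim = dim(px), fov = as.vector(image$fov_mask),
         spacing_um = image$spacing_um,
         bank = list(scales = scales, families = families, version = 1L)),
    class = "feature_stack")
}
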