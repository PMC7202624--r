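# Structural readouts from a cleaned mask: topology-preserving
# skeletonization, structural connectivity C_s (holes per mm skeleton),
# and local thickness statistics (T_med, sigma_T).

#' Skeletonize a mask to its medial axis
#'
#' Topology-preserving thinning to a one-pixel-wide medial structure:
#' border pixels are removed one at a time, in order of increasing
#' distance to the background, and only when removal provably does not
#' change the component or hole count (simple-point criterion, foreground
#' 8-connected / background 4-connected). Endpoints are preserved.
#'
#' @param mask a [segmentation_mask] (ideally cleaned, see [clean_mask]).
#' @return a `skeleton_map`: list with `skeleton` (logical matrix),
#'   `spacing_um` and `fov_mask`.
#' @export
skeletonize <- function(mask) {
  stopifnot(inherits(mask, "segmentation_mask"))
  structure(list(skeleton = cpp_thin(mask$mask),
                 spacing_um = mask$spacing_um, fov_mask = mask$fov_mask),
            class = "skeleton_map")
}

#' @export
print.skeleton_map <- function(x, ...) {
  cat(sprintf("skeleton_map: %d px, %.4g um/px\n", sum(x$skeleton),
              x$spacing_um))
  invisible(x)
}

#' Total skeleton length
#'
#' Default convention: pixel count times spacing. The alternative
#' `"weighted"` convention sums 8-neighbour polyline links (orthogonal
#' links at 1 spacing, diagonal at sqrt(2)); it differs from the pixel
#' count by a bounded factor <= sqrt(2).
#'
#' @param skel a `skeleton_map`.
#' @param spacing_um micrometres per pixel (defaults to the skeleton's).
#' @param convention `"pixel"` (default) or `"weighted"`.
#' @return length in micrometres.
#' @export
skeleton_length <- function(skel, spacing_um = skel$spacing_um,
                            convention = c("pixel", "weighted")) {
  convention <- match.arg(convention)
  m <- skel$skeleton
  if (convention == "pixel") return(sum(m) * spacing_um)
  nr <- nrow(m); nc <- ncol(m)
  orth <- sum(m[-nr, ] & m[-1, ]) + sum(m[, -nc] & m[, -1])
  diag1 <- sum(m[-nr, -nc] & m[-1, -1]) + sum(m[-1, -nc] & m[-nr, -1])
  (orth + sqrt(2) * diag1) * spacing_um
}

#' Count enclosed holes via the Euler number
#'
#' holes = (number of 8-connected foreground components) - (2D Euler
#' number of the foreground, 8-connected foreground / 4-connected
#' background). Equals the number of enclosed background components.
#'
#' @param mask a [segmentation_mask] or logical matrix.
#' @return integer hole count, >= 0.
#' @export
count_holes_euler <- function(mask) {
  m <- if (inherits(mask, "segmentation_mask")) mask$mask else mask != 0
  if (!any(m)) return(0L)
  comps <- attr(cpp_label(m, 8L), "n")
  euler <- cpp_euler8(m)
  max(0L, as.integer(comps - euler))
}

#' Structural connectivity C_s
#'
#' C_s = hole count / skeleton length, in holes per millimetre. Higher
#' values indicate a more intricate, disrupted elastin network.
#'
#' @param mask a [segmentation_mask].
#' @param skel the corresponding `skeleton_map`.
#' @param convention skeleton-length convention, see [skeleton_length].
#' @return C_s in 1/mm.
#' @export
connectivity <- function(mask, skel, convention = "pixel") {
  len_um <- skeleton_length(skel, convention = convention)
  if (len_um <= 0)
    stop("undefined metric: skeleton length is zero (empty structure)")
  count_holes_euler(mask) / (len_um / 1000)
}

#' Local thickness profile along the skeleton
#'
#' For each skeleton pixel, d_np is the Euclidean distance (pixel
#' centers, converted to micrometres) to the nearest background pixel;
#' the local thickness is T_local = 2 * d_np. Pixels outside the FOV
#' count as background for this distance (but never as holes).
#'
#' @param mask a [segmentation_mask].
#' @param skel the corresponding `skeleton_map`.
#' @return a `thickness_profile`: list with `d_np_um`, `T_local_um`,
#'   `n_points` and `pixels` (linear indices of the skeleton pixels).
#' @export
local_thickness <- function(mask, skel) {
  stopifnot(inherits(mask, "segmentation_mask"))
  idx <- which(skel$skeleton)
  if (!length(idx)) stop("skeleton is empty")
  if (all(mask$mask)) stop("background is empty")
  d <- sqrt(cpp_edt_sq(!mask$mask)) * mask$spacing_um
  d_np <- d[idx]
  structure(list(d_np_um = d_np, T_local_um = 2 * d_np,
                 n_points = length(idx), pixels = idx),
            class = "thickness_profile")
}

#' Summarize a thickness profile
#'
#' Median (midpoint of the two central order statistics for even n) and
#' population-convention standard deviation (divide by n) of T_local.
#'
#' @param profile a `thickness_profile`.
#' @return list with `T_med_um` and `sigma_T_um`.
#' @export
summarize_thickness <- function(profile) {
  stopifnot(inherits(profile, "thickness_profile"))
  x <- profile$T_local_um
  if (!length(x)) stop("undefined metric: empty thickness profile")
  list(T_med_um = median(x),
       sigma_T_um = sqrt(mean((x - mean(x))^2)))
}

#' Structure metrics of one snapshot mask
#'
#' Runs the measurement half of the pipeline on an existing binary mask:
#' cleaning (optional), skeletonization, connectivity and thickness.
#' Used both by [quantify_snapshot] and for ground-truth phantom masks
#' that bypass the classifier.
#'
#' @param mask a [segmentation_mask].
#' @param clean apply [clean_mask] first (default TRUE).
#' @param merge_distance_um,fill_diameter_um cleaning thresholds.
#' @param convention skeleton-length convention.
#' @return a `structure_metrics` list: `T_med_um`, `sigma_T_um`,
#'   `C_s_per_mm`, `n_holes`, `skeleton_length_um`, `n_points`,
#'   `excluded`, `exclusion_reason`; intermediates (`mask`, `skeleton`,
#'   `profile`) attached as attributes.
#' @export
quantify_mask <- function(mask, clean = TRUE, merge_distance_um = 2,
                          fill_diameter_um = 30, convention = "pixel") {
  stopifnot(inherits(mask, "segmentation_mask"))
  if (clean) mask <- clean_mask(mask, merge_distance_um, fill_diameter_um)
  excluded <- function(reason) {
    structure(list(T_med_um = NA_real_, sigma_T_um = NA_real_,
                   C_s_per_mm = NA_real_, n_holes = NA_integer_,
                   skeleton_length_um = NA_real_, n_points = 0L,
                   excluded = TRUE, exclusion_reason = reason),
              class = "structure_metrics")
  }
  if (!any(mask$mask)) return(excluded("segmentation irregularity: empty mask"))
  skel <- skeletonize(mask)
  len_um <- skeleton_length(skel, convention = convention)
  if (len_um <= 0)
    return(excluded("segmentation irregularity: empty skeleton"))
  profile <- local_thickness(mask, skel)
  th <- summarize_thickness(profile)
  out <- structure(
    list(T_med_um = th$T_med_um, sigma_T_um = th$sigma_T_um,
         C_s_per_mm = connectivity(mask, skel, convention = convention),
         n_holes = count_holes_euler(mask), skeleton_length_um = len_um,
         n_points = profile$n_points, excluded = FALSE,
         exclusion_reason = ""),
    class = "structure_metrics")
  attr(out, "mask") <- mask
  attr(out, "skeleton") <- skel
  attr(out, "profile") <- profile
  out
}

#' @export
print.structure_metrics <- function(x, ...) {
  if (x$excluded) {
    cat("structure_metrics: excluded (", x$exclusion_reason, ")\n", sep = "")
  } else {
    cat(sprintf(
      "structure_metrics: T_med = %.1f um, sigma_T = %.1f um, C_s = %.2f /mm (%d holes, %.0f um skeleton)\n",
      x$T_med_um, x$sigma_T_um, x$C_s_per_mm, x$n_holes,
      x$skeleton_length_um))
  }
  invisible(x)
}

#' Quantify one snapshot end to end
#'
#' Full per-snapshot workflow: feature stack, pixel classification,
#' physical-unit cleaning, skeletonization, connectivity and local
#' thickness. A snapshot whose cleaned mask is empty is flagged as a
#' segmentation irregularity and excluded rather than erroring.
#'
#' @param image a [pcle_image].
#' @param model an `elastin_classifier`.
#' @param config a [pipeline_config] (thresholds, conventions, bank).
#' @return a `structure_metrics` (see [quantify_mask]).
#' @export
quantify_snapshot <- function(image, model, config = pipeline_config()) {
  stopifnot(inherits(image, "pcle_image"))
  stack <- compute_features(image, scales = config$scales,
                            families = config$families)
  mask <- predict_mask(model, stack, threshold = config$decision_threshold)
  quantify_mask(mask, clean = TRUE,
                merge_distance_um = config$merge_distance_um,
                fill_diameter_um = config$fill_diameter_um,
                convention = config$skeleton_length_convention)
}
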