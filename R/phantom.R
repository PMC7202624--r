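# Synthetic pCLE phantom generator.
#
# The alveolar elastin network in a normal snapshot looks like a loop-rich
# web of ribbons bounding alveolar mouths. A Voronoi tessellation of
# random sites reproduces exactly that morphology with a directly
# countable hole ground truth: each bounded Voronoi cell fully inside the
# field of view becomes one enclosed hole, and dropping edges opens loops
# the way disrupted elastin does.

#' Phantom specification
#'
#' @param image_size_px square image side, >= 64 px.
#' @param spacing_um micrometres per pixel. Default renders the clinical
#'   600 um field of view onto the grid.
#' @param n_seeds number of Voronoi sites (network density control),
#'   >= 4.
#' @param width_um_mean,width_um_sd ribbon width distribution in um
#'   (normal, truncated at twice the spacing so ribbons stay resolvable).
#' @param edge_keep_prob fraction of network edges retained, in (0, 1].
#' @param snr peak contrast-to-noise ratio of the rendered image
#'   (linear, > 0); defined as (foreground - background level) / noise
#'   standard deviation.
#' @param seed integer; fully determines all stochastic behaviour.
#' @return a `phantom_spec` list.
#' @export
phantom_spec <- function(image_size_px = 256, spacing_um = 600 / image_size_px,
                         n_seeds = 25, width_um_mean = 12, width_um_sd = 3,
                         edge_keep_prob = 0.9, snr = 8, seed = 1) {
  spec <- list(image_size_px = as.integer(image_size_px),
               spacing_um = spacing_um, n_seeds = as.integer(n_seeds),
               width_um_mean = width_um_mean, width_um_sd = width_um_sd,
               edge_keep_prob = edge_keep_prob, snr = snr,
               seed = as.integer(seed))
  if (spec$image_size_px < 64) stop("image_size_px must be >= 64")
  if (spec$n_seeds < 4) stop("n_seeds must be >= 4")
  if (!(spec$edge_keep_prob > 0 && spec$edge_keep_prob <= 1))
    stop("edge_keep_prob must be in (0, 1]")
  if (spec$snr <= 0) stop("snr must be > 0")
  if (spec$spacing_um <= 0) stop("spacing_um must be > 0")
  if (spec$width_um_mean <= 2 * spec$spacing_um)
    stop("width_um_mean must exceed 2 * spacing_um (ribbons resolvable)")
  structure(spec, class = "phantom_spec")
}

# Flood fill of the mask's background from the FOV exterior, done in plain
# R by iterative frontier expansion (independent of the C++ labelling
# used by the measurement side of the package).
flood_exterior <- function(mask, fov) {
  bg <- !mask
  reached <- bg & !fov               # everything outside the FOV is exterior
  # border pixels of the grid are exterior too (FOV never touches them
  # only when the disk is strictly inside; include for safety)
  reached[1, ] <- reached[1, ] | bg[1, ]
  reached[nrow(bg), ] <- reached[nrow(bg), ] | bg[nrow(bg), ]
  reached[, 1] <- reached[, 1] | bg[, 1]
  reached[, ncol(bg)] <- reached[, ncol(bg)] | bg[, ncol(bg)]
  nr <- nrow(bg); nc <- ncol(bg)
  repeat {
    grown <- reached
    grown[-1, ] <- grown[-1, ] | reached[-nr, ]
    grown[-nr, ] <- grown[-nr, ] | reached[-1, ]
    grown[, -1] <- grown[, -1] | reached[, -nc]
    grown[, -nc] <- grown[, -nc] | reached[, -1]
    grown <- grown & bg
    if (identical(grown, reached)) break
    reached <- grown
  }
  reached
}

# count 4-connected components of a logical matrix in plain R (BFS);
# used only to enumerate ground-truth holes
count_components_r <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  seen <- matrix(FALSE, nr, nc)
  count <- 0L
  todo <- which(mask)
  for (start in todo) {
    if (seen[start]) next
    count <- count + 1L
    frontier <- start
    seen[start] <- TRUE
    while (length(frontier)) {
      i <- (frontier - 1L) %% nr + 1L
      j <- (frontier - 1L) %/% nr + 1L
      nbr <- c(frontier[i > 1] - 1L, frontier[i < nr] + 1L,
               frontier[j > 1] - nr, frontier[j < nc] + nr)
      nbr <- unique(nbr[mask[nbr] & !seen[nbr]])
      seen[nbr] <- TRUE
      frontier <- nbr
    }
  }
  count
}

#' Generate a synthetic elastin phantom
#'
#' Builds a Voronoi tessellation of `n_seeds` random sites inside the
#' field of view, drops each network edge independently with probability
#' `1 - edge_keep_prob`, renders retained edges as ribbons whose widths
#' are drawn per edge from a truncated normal distribution, and composes
#' the intensity image as foreground level on the mask plus a smooth
#' background haze plus additive Gaussian noise scaled to the requested
#' SNR.
#'
#' @param spec a [phantom_spec].
#' @return list with elements `image` (a [pcle_image]) and `truth`
#'   (list: `true_mask`, `true_hole_count`, `true_widths_um`,
#'   `true_skeleton_length_um`, `fov_mask`).
#' @export
generate_phantom <- function(spec) {
  if (!inherits(spec, "phantom_spec")) spec <- do.call(phantom_spec, spec)
  n <- spec$image_size_px
  s <- spec$spacing_um
  fov <- inscribed_disk_mask(n, n)
  with_seed(spec$seed, {
    # sites in a disk of 90% FOV radius (0-based pixel coordinates)
    R <- 0.9 * n / 2
    cc <- (n - 1) / 2
    rr <- R * sqrt(runif(spec$n_seeds))
    th <- runif(spec$n_seeds, 0, 2 * pi)
    sx <- cc + rr * cos(th)   # row coordinate
    sy <- cc + rr * sin(th)   # column coordinate
    # jitter exact duplicates (degenerate for the tessellation)
    dup <- duplicated(cbind(sx, sy))
    sx[dup] <- sx[dup] + runif(sum(dup), -0.5, 0.5)

    vor <- deldir::deldir(sy, sx, rw = c(-1, n, -1, n), suppressMsge = TRUE)
    seg <- vor$dirsgs  # Voronoi edges: (x1, y1, x2, y2) with x = column
    keep <- runif(nrow(seg)) <= spec$edge_keep_prob
    seg <- seg[keep, , drop = FALSE]

    widths <- numeric(nrow(seg))
    wmin <- 2 * s
    for (k in seq_len(nrow(seg))) {
      w <- rnorm(1, spec$width_um_mean, spec$width_um_sd)
      tries <- 0
      while (w < wmin && tries < 1000) {   # truncation at 2 * spacing
        w <- rnorm(1, spec$width_um_mean, spec$width_um_sd)
        tries <- tries + 1
      }
      widths[k] <- max(w, wmin)
    }

    mask <- cpp_render_ribbons(n, n,
                               x0 = seg$y1, y0 = seg$x1,
                               x1 = seg$y2, y1 = seg$x2,
                               halfwidth = (widths / 2) / s)
    mask <- mask & fov

    # ground-truth holes: enclosed background components, by flood fill
    exterior <- flood_exterior(mask, fov)
    enclosed <- !mask & !exterior
    true_holes <- count_components_r(enclosed)

    # ground-truth skeleton length: geometric length of the retained edge
    # network inside the FOV (sampled at quarter-pixel resolution)
    total_len <- 0
    for (k in seq_len(nrow(seg))) {
      dx <- seg$y2[k] - seg$y1[k]; dy <- seg$x2[k] - seg$x1[k]
      len_px <- sqrt(dx^2 + dy^2)
      if (len_px == 0) next
      ts <- seq(0, 1, length.out = max(2, ceiling(len_px * 4)))
      pi_ <- seg$y1[k] + ts * dx
      pj_ <- seg$x1[k] + ts * dy
      inside <- (pi_ - cc)^2 + (pj_ - cc)^2 <= (n / 2)^2
      total_len <- total_len + len_px * mean(inside)
    }

    fg_level <- 200; bg_level <- 30
    haze <- cpp_sepconv(matrix(rnorm(n * n), n, n),
                        gaussian_kernel(n / 16))
    haze <- haze / max(sd(haze), 1e-12) * 8
    noise_sd <- (fg_level - bg_level) / spec$snr
    img <- bg_level + haze + (fg_level - bg_level) * mask +
      matrix(rnorm(n * n, 0, noise_sd), n, n)
    img <- pmin(pmax(img, 0), 255)

    image <- pcle_image(img, s, fov_mask = fov,
                        source_id = sprintf("phantom-seed%d", spec$seed))
    attr(image, "contrast") <- fg_level - bg_level
    list(image = image,
         truth = list(true_mask = mask & TRUE,
                      true_hole_count = true_holes,
                      true_widths_um = widths,
                      true_skeleton_length_um = total_len * s,
                      fov_mask = fov,
                      spacing_um = s))
  })
}

#' Degrade an image to a target SNR
#'
#' Adds zero-mean Gaussian noise with standard deviation
#' (foreground - background level) / `snr` and clips to the valid
#' intensity range. The contrast is taken from the image's `contrast`
#' attribute when present (phantoms carry it), otherwise estimated as the
#' 90th minus 10th intensity percentile inside the FOV.
#'
#' @param image a [pcle_image].
#' @param snr target contrast-to-noise ratio, > 0.
#' @param seed RNG seed.
#' @return a [pcle_image] with added noise.
#' @export
degrade_snr <- function(image, snr, seed = 1) {
  stopifnot(inherits(image, "pcle_image"))
  if (!is.numeric(snr) || snr <= 0) stop("snr must be > 0")
  contrast <- attr(image, "contrast")
  if (is.null(contrast)) {
    v <- image$pixels[image$fov_mask]
    contrast <- diff(quantile(v, c(0.1, 0.9), names = FALSE))
  }
  noise_sd <- contrast / snr
  with_seed(seed, {
    px <- image$pixels + matrix(rnorm(length(image$pixels), 0, noise_sd),
                                nrow(image$pixels))
    px <- pmin(pmax(px, 0), 255)
    out <- pcle_image(px, image$spacing_um, fov_mask = image$fov_mask,
                      source_id = image$source_id)
    attr(out, "contrast") <- contrast
    out
  })
}

#' Derive sparse training labels from phantom ground truth
#'
#' Emulates manual labelling: a random subset of the true foreground is
#' marked elastin (1) and of the true background marked background (2);
#' everything else stays unlabelled (0). Labels never contradict the
#' ground truth.
#'
#' @param truth the `truth` component of [generate_phantom] output.
#' @param fraction fraction of FOV pixels of each class to label, (0, 1].
#' @param seed RNG seed.
#' @return integer label matrix (0 = unlabelled, 1 = elastin,
#'   2 = background).
#' @export
make_training_labels <- function(truth, fraction = 0.1, seed = 1) {
  stopifnot(fraction > 0, fraction <= 1)
  fov <- truth$fov_mask
  labels <- matrix(0L, nrow(truth$true_mask), ncol(truth$true_mask))
  with_seed(seed, {
    fg <- which(truth$true_mask & fov)
    bg <- which(!truth$true_mask & fov)
    take <- function(idx) {
      if (fraction == 1) idx
      else sample(idx, round(fraction * length(idx)))
    }
    labels[take(fg)] <- 1L
    labels[take(bg)] <- 2L
  })
  labels
}
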