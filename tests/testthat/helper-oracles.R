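# Independent oracles used across the suite. These deliberately avoid the
# package's computational paths (Euler counting, EDT, C++ labelling):
# flood fill and brute-force enumeration only.

# multi-source BFS over a logical matrix from a set of start indices,
# 4-connectivity; returns logical matrix of reached pixels
bfs_reach <- function(open, starts) {
  nr <- nrow(open); nc <- ncol(open)
  reached <- matrix(FALSE, nr, nc)
  frontier <- starts[open[starts]]
  reached[frontier] <- TRUE
  while (length(frontier)) {
    i <- (frontier - 1L) %% nr + 1L
    j <- (frontier - 1L) %/% nr + 1L
    nbr <- c(frontier[i > 1] - 1L, frontier[i < nr] + 1L,
             frontier[j > 1] - nr, frontier[j < nc] + nr)
    nbr <- unique(nbr[open[nbr] & !reached[nbr]])
    reached[nbr] <- TRUE
    frontier <- nbr
  }
  reached
}

# flood-fill enumeration of enclosed background components (the holes):
# background not reachable from the image border (nor from outside the
# FOV, when given), counted by repeated BFS
oracle_hole_count <- function(mask, fov = NULL) {
  nr <- nrow(mask); nc <- ncol(mask)
  bg <- !mask
  border <- unique(c(seq_len(nr), (nc - 1L) * nr + seq_len(nr),
                     (seq_len(nc) - 1L) * nr + 1L, (seq_len(nc)) * nr))
  starts <- border
  if (!is.null(fov)) starts <- unique(c(starts, which(!fov)))
  exterior <- bfs_reach(bg, starts)
  enclosed <- bg & !exterior
  count <- 0L
  while (any(enclosed)) {
    count <- count + 1L
    comp <- bfs_reach(enclosed, which(enclosed)[1])
    enclosed <- enclosed & !comp
  }
  count
}

# brute-force nearest-background distance (pixel units) at given indices
oracle_nearest_bg <- function(mask, idx) {
  bg <- which(!mask)
  nr <- nrow(mask)
  bi <- (bg - 1L) %% nr + 1L
  bj <- (bg - 1L) %/% nr + 1L
  vapply(idx, function(p) {
    pi_ <- (p - 1L) %% nr + 1L
    pj_ <- (p - 1L) %/% nr + 1L
    sqrt(min((bi - pi_)^2 + (bj - pj_)^2))
  }, numeric(1))
}

# dense 2D convolution with a separable Gaussian kernel, mirror padding
oracle_gauss_convolve <- function(img, sigma) {
  k <- gaussian_kernel(sigma)
  K <- outer(k, k)
  r <- (length(k) - 1) / 2
  nr <- nrow(img); nc <- ncol(img)
  refl <- function(i, n) {
    while (any(i < 1 | i > n)) {
      i[i < 1] <- 1 - i[i < 1]
      i[i > n] <- 2 * n + 1 - i[i > n]
    }
    i
  }
  out <- matrix(0, nr, nc)
  for (i in seq_len(nr))
    for (j in seq_len(nc)) {
      ii <- refl(i + (-r):r, nr)
      jj <- refl(j + (-r):r, nc)
      out[i, j] <- sum(K * img[ii, jj])
    }
  out
}

# exact two-tailed rank-sum p by enumeration of all rank assignments
oracle_wilcoxon_exact <- function(x, y) {
  nx <- length(x); n <- nx + length(y)
  r <- rank(c(x, y))
  u_obs <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  combos <- utils::combn(n, nx)
  us <- apply(combos, 2, function(s) sum(seq_len(n)[s]) - nx * (nx + 1) / 2)
  mu <- nx * (n - nx) / 2
  mean(abs(us - mu) >= abs(u_obs - mu))
}

# random blob mask: thresholded smoothed noise inside the inscribed disk
random_blob_mask <- function(n, seed, smooth = n / 16, coverage = 0.45) {
  with_seed <- pcleQuant:::with_seed
  with_seed(seed, {
    z <- pcleQuant:::cpp_sepconv(matrix(rnorm(n * n), n, n),
                                 gaussian_kernel(max(1, smooth)))
    fov <- inscribed_disk_mask(n, n)
    m <- z > quantile(z, 1 - coverage)
    m & fov
  })
}

# small phantom helper with shared defaults for test speed; ribbon width
# kept above 2 px at every size used here
quick_phantom <- function(seed, size = 128, n_seeds = 14, snr = 8,
                          width_um_mean = 14, ...) {
  generate_phantom(phantom_spec(image_size_px = size, n_seeds = n_seeds,
                                snr = snr, seed = seed,
                                width_um_mean = width_um_mean, ...))
}

# build a balanced training set from several phantoms (features + labels)
phantom_training_set <- function(seeds, size = 128, snr = 4,
                                 label_fraction = 0.05, seed = 1) {
  sets <- lapply(seeds, function(s) {
    ph <- quick_phantom(s, size = size, snr = snr)
    st <- compute_features(ph$image)
    collect_instances(st, make_training_labels(ph$truth, label_fraction,
                                               seed = s))
  })
  x <- do.call(rbind, lapply(sets, `[[`, "x"))
  y <- unlist(lapply(sets, function(t) as.character(t$y)))
  undersample(pcleQuant:::training_set(x, y), seed = seed)
}
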