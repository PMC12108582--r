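# Independent oracles and small fixture builders shared across tests.

# Brute-force Hildebrand-Rueegsegger local thickness: for every structure
# voxel, the inscribed-sphere radius is the distance to the nearest
# background voxel centre minus half a voxel; the thickness at x is twice the
# largest radius among spheres covering x. Direct O(n^2) scans, no distance
# transform, no painting -- independent of the compiled implementation.
bf_local_thickness <- function(mask) {
  d <- dim(mask)
  th <- array(0, d)
  co <- which(mask == 1, arr.ind = TRUE)
  bg <- which(mask == 0, arr.ind = TRUE)
  if (nrow(co) == 0L) return(th)
  if (nrow(bg) == 0L) stop("oracle needs at least one background voxel")
  r <- vapply(seq_len(nrow(co)), function(i) {
    sqrt(min(colSums((t(bg) - co[i, ])^2))) - 0.5
  }, numeric(1))
  for (i in seq_len(nrow(co))) {
    d2 <- colSums((t(co) - co[i, ])^2)
    covered <- d2 <= r^2 + 1e-9
    th[co[i, 1], co[i, 2], co[i, 3]] <- 2 * max(r[covered])
  }
  th
}

# brute-force summary statistics by sort-and-scan, no stats:: helpers
bf_summary <- function(x, pop_sd = TRUE) {
  xs <- sort(x)
  n <- length(xs)
  m <- sum(xs) / n
  ss <- sum((xs - m)^2)
  list(n = n, mean = m,
       sd = if (n < 2) NA_real_ else sqrt(ss / if (pop_sd) n else n - 1),
       min = xs[1], max = xs[n])
}

# random 0/1 mask of given dims
random_mask <- function(dims, p = 0.5) {
  label_mask(array(as.integer(runif(prod(dims)) < p), dims))
}

# plate phantom plus a period-aligned interior cylindrical ROI, for
# parameter-recovery tests: the ROI spans exactly two lattice periods along
# the slice axis, one period in from each volume face, so closed-form
# expectations apply without face effects.
plate_recovery_case <- function(t, p, spacing, roi_radius = 1.0,
                                lateral_mm = 2.4, noise_sd = 0, seed = 1) {
  nz <- round((3 * p + t) / spacing)
  n <- round(lateral_mm / spacing)
  spec <- phantom_spec(shape = c(nz, n, n), spacing = spacing,
                       plate_thickness_t = t, plate_period_p = p,
                       noise_sd = noise_sd, seed = seed)
  ph <- make_lattice_phantom(spec)
  ctr <- c(n, n) / 2 * spacing
  rc <- (seq_len(n) - 0.5) * spacing
  disc <- outer((rc - ctr[1])^2, (rc - ctr[2])^2, `+`) <= roi_radius^2
  z <- (seq_len(nz) - 0.5) * spacing
  zin <- z >= p & z < 3 * p
  roi <- array(0L, dim(ph$grid))
  roi[zin, , ] <- rep(disc * 1L, each = sum(zin))
  list(phantom = ph, roi = label_mask(roi), spec = spec)
}

table4_fixture_path <- function() {
  system.file("extdata", "table4_cohort.csv", package = "tunnelmorph")
}
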