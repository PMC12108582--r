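#' Specification of a synthetic trabecular-plate phantom
#'
#' The phantom emulates the appearance of HR-pQCT trabecular bone around a
#' graft tunnel: a bright parallel-plate lattice (plates perpendicular to the
#' slice axis, thickness `t` repeating with period `p`) on a dark background,
#' optionally with a slice-aligned cylindrical tunnel carved out and partially
#' refilled with bone to mimic post-operative regrowth. Every morphometric
#' index of the plate lattice has a closed form ([expected_lattice_metrics()]),
#' which is what makes the phantom usable as a ground-truth oracle for the
#' whole downstream pipeline.
#'
#' @param shape integer `(slices, rows, cols)`.
#' @param spacing voxel edge, mm.
#' @param lattice_kind only `"plates"` carries a closed-form oracle.
#' @param plate_thickness_t,plate_period_p plate thickness and repeat period,
#'   mm; requires `0 < t < p`.
#' @param bone_intensity,background_intensity grayscale levels (8-bit-like
#'   scale by convention); bone must be brighter.
#' @param noise_sd zero-mean Gaussian noise SD added to both levels.
#' @param tunnel_center `(row, col)` of the tunnel axis in mm from the volume
#'   origin, or `NULL` for the grid centre.
#' @param tunnel_radius tunnel radius, mm (0 = no tunnel).
#' @param refill_fraction fraction of carved voxels restored to bone, in
#'   \[0,1\].
#' @param seed integer; all phantom randomness is a pure function of it.
#' @return a `phantom_spec` list.
#' @export
phantom_spec <- function(shape = c(32L, 64L, 64L), spacing = 0.0607,
                         lattice_kind = c("plates", "rods"),
                         plate_thickness_t = 0.12, plate_period_p = 0.45,
                         bone_intensity = 180, background_intensity = 40,
                         noise_sd = 8, tunnel_center = NULL,
                         tunnel_radius = 0, refill_fraction = 0,
                         seed = 1L) {
  lattice_kind <- match.arg(lattice_kind)
  if (length(shape) != 3L || any(shape < 1L)) abort("shape must be 3 positive integers")
  if (spacing <= 0) abort("bad spacing")
  if (!(plate_thickness_t > 0 && plate_thickness_t < plate_period_p))
    abort("spec error: need 0 < plate_thickness_t < plate_period_p")
  if (bone_intensity <= background_intensity)
    abort("bone_intensity must exceed background_intensity")
  if (tunnel_radius < 0) abort("tunnel_radius must be >= 0")
  if (refill_fraction < 0 || refill_fraction > 1)
    abort("refill_fraction must be in [0,1]")
  if (noise_sd < 0) abort("noise_sd must be >= 0")
  structure(list(shape = as.integer(shape), spacing = spacing,
                 lattice_kind = lattice_kind,
                 plate_thickness_t = plate_thickness_t,
                 plate_period_p = plate_period_p,
                 bone_intensity = bone_intensity,
                 background_intensity = background_intensity,
                 noise_sd = noise_sd, tunnel_center = tunnel_center,
                 tunnel_radius = tunnel_radius,
                 refill_fraction = refill_fraction, seed = as.integer(seed)),
            class = "phantom_spec")
}

# run code under a given RNG seed without disturbing the caller's stream
with_local_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Generate a plate-lattice phantom volume (no tunnel yet)
#'
#' Bone occupies voxels whose centre position along the slice axis satisfies
#' `(z mod p) < t`; intensities are the two grayscale levels plus seeded
#' zero-mean Gaussian noise. The result is bit-identical for a fixed spec.
#'
#' @param spec a [phantom_spec()].
#' @return a `phantom_sample`: list with `grid` ([voxel_grid()]),
#'   `bone_truth` and `tunnel_truth` (3D [label_mask()]), and `spec`.
#' @examples
#' ph <- make_lattice_phantom(phantom_spec(shape = c(8, 16, 16), noise_sd = 0))
#' mean(ph$bone_truth)
#' @export
make_lattice_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  if (spec$lattice_kind != "plates")
    abort("oracle not defined: only the plate lattice is implemented")
  d <- spec$shape
  z <- (seq_len(d[1]) - 0.5) * spec$spacing       # slice-axis voxel centres
  bone_layer <- (z %% spec$plate_period_p) < spec$plate_thickness_t
  bone <- array(rep(bone_layer, times = d[2] * d[3]), d)
  vals <- ifelse(bone, spec$bone_intensity, spec$background_intensity)
  if (spec$noise_sd > 0)
    vals <- vals + with_local_seed(spec$seed,
                                   array(rnorm(length(vals), 0, spec$noise_sd), d))
  vals <- pmax(vals, 0)
  sample <- list(grid = voxel_grid(vals, spacing = spec$spacing),
                 bone_truth = label_mask(bone),
                 tunnel_truth = label_mask(array(0L, d)),
                 spec = spec)
  class(sample) <- "phantom_sample"
  if (spec$tunnel_radius > 0)
    sample <- carve_tunnel(sample, center = spec$tunnel_center,
                           radius = spec$tunnel_radius,
                           refill_fraction = spec$refill_fraction)
  sample
}

#' @export
print.phantom_sample <- function(x, ...) {
  d <- dim(x$grid)
  cat(sprintf("<phantom_sample> %s, %.0f%% bone, %d tunnel voxels\n",
              paste(d, collapse = " x "), 100 * mean(x$bone_truth),
              sum(x$tunnel_truth)))
  invisible(x)
}

#' Carve a slice-aligned cylindrical tunnel into a phantom
#'
#' Voxels whose in-slice centre lies within `radius` of the axis are set to
#' background intensity and flagged in `tunnel_truth`; a seeded uniform
#' fraction of the carved voxels is then restored to bone intensity to mimic
#' early bone fill, with `bone_truth` kept consistent. `radius = 0` leaves
#' the sample untouched.
#'
#' @param sample a `phantom_sample`.
#' @param center `(row, col)` axis position in mm; `NULL` = grid centre.
#' @param radius tunnel radius, mm.
#' @param refill_fraction fraction of carved voxels restored to bone.
#' @return the modified `phantom_sample`.
#' @export
carve_tunnel <- function(sample, center = NULL, radius,
                         refill_fraction = 0) {
  stopifnot(inherits(sample, "phantom_sample"))
  if (radius < 0) abort("radius must be >= 0")
  if (radius == 0) return(sample)
  spec <- sample$spec
  d <- dim(sample$grid)
  sp <- grid_spacing(sample$grid)
  if (is.null(center)) center <- c(d[2], d[3]) / 2 * sp
  if (center[1] < 0 || center[1] > d[2] * sp ||
      center[2] < 0 || center[2] > d[3] * sp)
    abort("tunnel axis lies outside the grid")
  rc <- (seq_len(d[2]) - 0.5) * sp
  cc <- (seq_len(d[3]) - 0.5) * sp
  d2 <- outer((rc - center[1])^2, (cc - center[2])^2, `+`)
  disc <- d2 <= radius^2                            # in-slice cross-section
  cyl <- aperm(array(disc, c(d[2], d[3], d[1])), c(3, 1, 2))
  idx <- which(cyl)
  grid_vals <- unclass(sample$grid)
  bone <- unclass(sample$bone_truth)
  with_local_seed(spec$seed + 1L, {
    grid_vals[idx] <- pmax(spec$background_intensity +
                             if (spec$noise_sd > 0)
                               rnorm(length(idx), 0, spec$noise_sd) else 0, 0)
    bone[idx] <- 0L
    if (refill_fraction > 0 && length(idx) > 0) {
      n_fill <- round(refill_fraction * length(idx))
      fill <- base::sample(idx, n_fill)   # `sample` arg shadows base::sample
      grid_vals[fill] <- pmax(spec$bone_intensity +
                                if (spec$noise_sd > 0)
                                  rnorm(n_fill, 0, spec$noise_sd) else 0, 0)
      bone[fill] <- 1L
    }
  })
  sample$grid <- voxel_grid(grid_vals, spacing = sp)
  sample$bone_truth <- label_mask(bone)
  sample$tunnel_truth <- label_mask(cyl * 1L)
  sample$spec$tunnel_radius <- radius
  sample$spec$tunnel_center <- center
  sample$spec$refill_fraction <- refill_fraction
  sample
}

#' Closed-form expected morphometry of a plate phantom
#'
#' For a parallel-plate lattice of thickness `t` and period `p` the
#' morphometric indices are exact: BV/TV = t/p, Tb.Th = t, Tb.Sp = p - t,
#' Tb.N = 1/p. Volume is the carved-tunnel voxel volume when a carved sample
#' is supplied, else the whole-grid volume.
#'
#' @param spec a [phantom_spec()] with `lattice_kind = "plates"`.
#' @param sample optional carved `phantom_sample` for the tunnel volume.
#' @return a one-row [morphometry_result()] tibble.
#' @examples
#' expected_lattice_metrics(phantom_spec(plate_thickness_t = 0.3,
#'                                       plate_period_p = 1.0))
#' @export
expected_lattice_metrics <- function(spec, sample = NULL) {
  stopifnot(inherits(spec, "phantom_spec"))
  if (spec$lattice_kind != "plates")
    abort("oracle not defined for the rod lattice")
  t <- spec$plate_thickness_t
  p <- spec$plate_period_p
  vol <- if (!is.null(sample) && sum(sample$tunnel_truth) > 0)
    sum(sample$tunnel_truth) * spec$spacing^3
  else prod(spec$shape) * spec$spacing^3
  morphometry_result(bvtv = t / p, tb_th = t, tb_sp = p - t, tb_n = 1 / p,
                     volume = vol)
}

#' Draw a seeded set of (slice image, tunnel mask) training pairs
#'
#' Each pair is one slice from a fresh phantom whose tunnel axis position and
#' radius are jittered around the base spec, paired with its ground-truth
#' tunnel cross-section. This stands in for an annotated HR-pQCT training
#' corpus: the network sees a dark round tunnel punched into a bright lattice
#' at varying positions and sizes.
#'
#' @param spec base [phantom_spec()]; its `tunnel_radius` (or a quarter of the
#'   in-slice extent if unset) anchors the jitter.
#' @param n number of pairs.
#' @param seed integer controlling the whole draw.
#' @return list of `n` lists with elements `image` (matrix) and `mask`
#'   (2D [label_mask()]).
#' @export
make_training_set <- function(spec, n, seed = 1L) {
  stopifnot(inherits(spec, "phantom_spec"))
  if (n < 0) abort("n must be >= 0")
  if (n == 0) return(list())
  d <- spec$shape
  sp <- spec$spacing
  extent <- c(d[2], d[3]) * sp
  r0 <- if (spec$tunnel_radius > 0) spec$tunnel_radius else min(extent) / 8
  with_local_seed(seed, {
    draws <- lapply(seq_len(n), function(i) {
      list(center = c(runif(1, 0.3, 0.7) * extent[1],
                      runif(1, 0.3, 0.7) * extent[2]),
           radius = r0 * runif(1, 0.7, 1.3),
           slice = sample.int(d[1], 1),
           sub_seed = sample.int(.Machine$integer.max - 2L, 1))
    })
    lapply(draws, function(dr) {
      s2 <- spec
      s2$seed <- dr$sub_seed
      s2$tunnel_center <- dr$center
      s2$tunnel_radius <- dr$radius
      ph <- make_lattice_phantom(s2)
      list(image = unclass(ph$grid)[dr$slice, , ],
           mask = label_mask(unclass(ph$tunnel_truth)[dr$slice, , ]))
    })
  })
}
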