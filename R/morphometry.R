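#' Construct a morphometry result row
#'
#' One tunnel's trabecular indices, with the units used in clinical HR-pQCT
#' reports: BV/TV unitless in \[0,1\], Tb.Th and Tb.Sp in mm, Tb.N in 1/mm,
#' volume in mm3, mGV in raw intensity units.
#'
#' @param bvtv,tb_th,tb_sp,tb_n,volume,mgv scalar index values.
#' @param patient_id,compartment optional identifiers.
#' @return a one-row tibble of class `morphometry_result`.
#' @export
morphometry_result <- function(bvtv, tb_th, tb_sp, tb_n, volume,
                               mgv = NA_real_, patient_id = NA_character_,
                               compartment = NA_character_) {
  if (bvtv < 0 || bvtv > 1) abort("bvtv must lie in [0,1]")
  if (tb_th < 0 || tb_sp < 0 || tb_n < 0 || volume < 0)
    abort("tb_th, tb_sp, tb_n and volume must be non-negative")
  out <- tibble(patient_id = patient_id, compartment = compartment,
                bvtv = bvtv, tb_th = tb_th, tb_sp = tb_sp, tb_n = tb_n,
                volume = volume, mgv = mgv)
  class(out) <- c("morphometry_result", class(out))
  out
}

#' Tunnel volume from a binary mask
#'
#' Exactly `voxel count * spacing^3` -- the 3D surrogate for overall tunnel
#' size.
#'
#' @param mask 3D [label_mask()] (or 0/1 array).
#' @param spacing voxel edge, mm.
#' @return volume in mm3.
#' @examples
#' tunnel_volume(array(1, c(10, 10, 10)), spacing = 0.0607)
#' @export
tunnel_volume <- function(mask, spacing) {
  if (spacing <= 0) abort("bad spacing")
  sum(mask != 0) * spacing^3
}

#' Otsu threshold of an intensity sample
#'
#' Classic between-class-variance maximisation over a fixed-bin histogram of
#' the sample. Used to separate mineralized voxels from marrow/void inside
#' the tunnel without a calibration.
#'
#' @param x numeric vector of intensities.
#' @param levels number of histogram bins.
#' @return threshold value on the intensity scale; voxels `>=` threshold are
#'   bone.
#' @export
otsu_threshold <- function(x, levels = 256L) {
  x <- x[is.finite(x)]
  if (length(x) == 0L) abort("empty intensity sample")
  lo <- min(x); hi <- max(x)
  if (lo == hi) return(lo)
  breaks <- seq(lo, hi, length.out = levels + 1L)
  h <- tabulate(findInterval(x, breaks, all.inside = TRUE), nbins = levels)
  w <- h / sum(h)
  mids <- (breaks[-1] + breaks[-length(breaks)]) / 2
  omega <- cumsum(w)
  mu <- cumsum(w * mids)
  mu_t <- mu[levels]
  sigma_b <- (mu_t * omega - mu)^2 / (omega * (1 - omega))
  sigma_b[!is.finite(sigma_b)] <- -Inf
  k <- which.max(sigma_b)
  breaks[k + 1L]          # class boundary: bin k and below are background
}

#' Bone voxels inside a tunnel
#'
#' Thresholds the grid intensities within the tunnel mask; the result is
#' always a subset of the tunnel. The default threshold is Otsu's method
#' computed from the tunnel-interior intensities only, so it adapts per
#' tunnel; a fixed intensity can be supplied instead.
#'
#' @param grid [voxel_grid()].
#' @param tunnel nonempty 3D [label_mask()] matching the grid.
#' @param method `"otsu"` or `"fixed"`.
#' @param threshold intensity cutoff for `method = "fixed"` (bone is
#'   `>= threshold`).
#' @return 3D [label_mask()] of bone voxels, subset of `tunnel`.
#' @export
bone_in_tunnel <- function(grid, tunnel, method = c("otsu", "fixed"),
                           threshold = NULL) {
  method <- match.arg(method)
  check_same_shape(grid, tunnel, "grid and tunnel")
  if (sum(tunnel) == 0) abort("empty tunnel mask")
  thr <- bone_threshold(grid, tunnel, method, threshold)
  label_mask((unclass(grid) >= thr) & (tunnel > 0))
}

bone_threshold <- function(grid, tunnel, method, threshold) {
  if (method == "fixed") {
    if (is.null(threshold)) abort("method 'fixed' needs a threshold value")
    threshold
  } else {
    otsu_threshold(unclass(grid)[tunnel > 0])
  }
}

#' Local thickness map of a 3D structure
#'
#' Model-independent thickness in the sense of Hildebrand and Rueegsegger:
#' the value at voxel `x` is the diameter of the largest sphere that fits
#' entirely inside the structure and contains `x`. Computed as an exact
#' Euclidean distance transform followed by maximal-sphere painting (compiled
#' code). Structures touching the volume face are treated as continuing past
#' it; pad with background where that is not wanted.
#'
#' @param mask 3D [label_mask()] (or 0/1 array).
#' @param spacing voxel edge, mm.
#' @return array of class `thickness_map`: thickness in mm inside the
#'   structure, 0 outside; spacing kept as an attribute.
#' @examples
#' slab <- array(0L, c(9, 8, 8)); slab[3:7, , ] <- 1L   # 5-voxel slab
#' tm <- local_thickness_map(slab, spacing = 0.1)
#' mean(tm[slab == 1])   # ~0.5 mm
#' @export
local_thickness_map <- function(mask, spacing) {
  if (spacing <= 0) abort("bad spacing")
  if (is.null(dim(mask)) || length(dim(mask)) != 3L) abort("mask must be 3D")
  m <- array(as.integer(mask != 0), dim(mask))
  edt2 <- cpp_edt_sq(as.integer(m), dim(m))
  th <- cpp_local_thickness(as.integer(m), edt2, dim(m))
  out <- array(th * spacing, dim(m))
  structure(out, spacing = spacing, class = c("thickness_map", "array"))
}

#' @export
print.thickness_map <- function(x, ...) {
  inside <- x[x > 0]
  cat(sprintf("<thickness_map> %s, %d structure voxels, mean %.4g mm\n",
              paste(dim(x), collapse = " x "), length(inside),
              if (length(inside)) mean(inside) else NA_real_))
  invisible(x)
}

#' Full trabecular morphometry of a segmented tunnel
#'
#' The in-package replacement for the bone-texture stage: stacked per-slice
#' tunnel masks define the 3D region of interest, the bone phase inside it is
#' thresholded ([bone_in_tunnel()]), and the standard indices are computed:
#'
#' * `bvtv` -- exact voxel-count ratio of bone to tunnel;
#' * `tb_th` -- volume-weighted mean local thickness of the bone phase;
#' * `tb_sp` -- volume-weighted mean local thickness of the non-bone phase;
#' * `tb_n` -- trabecular number, see `tb_n_method`;
#' * `volume` -- tunnel voxel volume, mm3; `mgv` -- sequence mean grayscale.
#'
#' Thickness maps are computed on whole-grid phase masks (same threshold) and
#' averaged over the tunnel interior, so inscribed spheres may extend past
#' the ROI wall; this avoids clipping bias at the tunnel boundary. `tb_n`
#' methods: `"direct"` (default) is the reciprocal of the mean mid-axis
#' spacing of the bone phase, estimated as `1 / (tb_th + tb_sp)`; `"plate"`
#' is the plate-model `bvtv / tb_th`; `"inverse_separation"` is `1 / tb_sp`.
#'
#' @inheritParams bone_in_tunnel
#' @param tb_n_method `"direct"`, `"plate"` or `"inverse_separation"`.
#' @param mgv_weighting passed to [mean_grayscale()].
#' @param patient_id,compartment carried into the result row; defaults taken
#'   from the grid's metadata.
#' @return a one-row [morphometry_result()] tibble.
#' @export
morphometry_report <- function(grid, tunnel, method = c("otsu", "fixed"),
                               threshold = NULL,
                               tb_n_method = c("direct", "plate",
                                               "inverse_separation"),
                               mgv_weighting = "slice",
                               patient_id = NULL, compartment = NULL) {
  method <- match.arg(method)
  tb_n_method <- match.arg(tb_n_method)
  check_same_shape(grid, tunnel, "grid and tunnel")
  if (sum(tunnel) == 0) abort("empty tunnel mask")
  sp <- grid_spacing(grid)
  thr <- bone_threshold(grid, tunnel, method, threshold)
  in_tunnel <- tunnel > 0
  bone_global <- unclass(grid) >= thr
  bone_tun <- bone_global & in_tunnel
  bvtv <- sum(bone_tun) / sum(in_tunnel)

  tb_th <- phase_mean_thickness(bone_global, bone_tun, sp)
  tb_sp <- phase_mean_thickness(!bone_global, (!bone_global) & in_tunnel, sp)

  tb_n <- switch(tb_n_method,
    direct = if (tb_th + tb_sp > 0) 1 / (tb_th + tb_sp) else 0,
    plate = if (tb_th > 0) bvtv / tb_th else 0,
    inverse_separation = if (tb_sp > 0) 1 / tb_sp else 0)

  mgv <- mean_grayscale(grid, label_mask(in_tunnel), weighting = mgv_weighting)$mgv
  morphometry_result(
    bvtv = bvtv, tb_th = tb_th, tb_sp = tb_sp, tb_n = tb_n,
    volume = tunnel_volume(tunnel, sp), mgv = mgv,
    patient_id = patient_id %||% attr(grid, "patient_id") %||% NA_character_,
    compartment = compartment %||% attr(grid, "compartment") %||% NA_character_)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# mean local thickness of a (whole-grid) phase over an ROI subset of it
phase_mean_thickness <- function(phase, roi_subset, spacing) {
  if (!any(roi_subset)) return(0)
  tm <- local_thickness_map(array(as.integer(phase), dim(phase)), spacing)
  mean(tm[roi_subset])
}
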