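#' Voxel grid: a 3D CT intensity volume with isotropic spacing
#'
#' The basic image container of the package. Intensities are stored as a
#' numeric 3D array indexed `(slice, row, col)`; the voxel edge length is a
#' single isotropic scalar in millimetres. The default spacing, 0.0607 mm,
#' is the native voxel size of second-generation HR-pQCT (XtremeCT-II) knee
#' acquisitions.
#'
#' @param intensities numeric 3D array `(slice, row, col)`; finite,
#'   non-negative.
#' @param spacing voxel edge length in mm (> 0).
#' @param patient_id optional opaque label.
#' @param compartment optional; `"femur"` or `"tibia"`.
#' @return An object of class `voxel_grid`: the array with attributes
#'   `spacing`, `patient_id`, `compartment`.
#' @examples
#' g <- voxel_grid(array(0, c(2, 4, 4)), spacing = 0.0607)
#' dim(g)
#' @export
voxel_grid <- function(intensities, spacing = 0.0607, patient_id = NULL,
                       compartment = NULL) {
  if (!is.array(intensities) || length(dim(intensities)) != 3L)
    abort("intensities must be a 3D array (slice, row, col)")
  if (any(dim(intensities) < 1L))
    abort("all three dimensions must be >= 1")
  if (!all(is.finite(intensities)))
    abort("intensities must be finite")
  if (!is.numeric(spacing) || length(spacing) != 1L || !is.finite(spacing) ||
      spacing <= 0)
    abort("bad spacing: must be a single positive number (mm)")
  if (!is.null(compartment))
    compartment <- match.arg(compartment, c("femur", "tibia"))
  structure(intensities * 1.0,
            spacing = spacing,
            patient_id = patient_id,
            compartment = compartment,
            class = c("voxel_grid", "array"))
}

#' @export
print.voxel_grid <- function(x, ...) {
  d <- dim(x)
  cat(sprintf("<voxel_grid> %d slices x %d x %d, spacing %.4g mm\n",
              d[1], d[2], d[3], grid_spacing(x)))
  if (!is.null(attr(x, "patient_id")))
    cat("  patient:", attr(x, "patient_id"),
        if (!is.null(attr(x, "compartment"))) attr(x, "compartment") else "",
        "\n")
  cat(sprintf("  intensity range [%g, %g]\n", min(x), max(x)))
  invisible(x)
}

#' Voxel spacing of a grid or mask, in mm
#' @param x a `voxel_grid`.
#' @return scalar spacing in mm.
#' @export
grid_spacing <- function(x) {
  s <- attr(x, "spacing")
  if (is.null(s)) abort("object carries no spacing attribute")
  s
}

#' Binary label mask aligned to a grid or slice
#'
#' Masks are plain integer arrays over \{0, 1\}: 2D for one slice, 3D for a
#' stack. When constructed against a paired grid the shapes must match.
#'
#' @param values 2D or 3D array; coerced to integer 0/1. Logical input is
#'   accepted.
#' @param paired optional array/grid whose shape the mask must match.
#' @return array of class `label_mask` over \{0,1\}.
#' @examples
#' m <- label_mask(array(c(0, 1), c(1, 2, 1)))
#' sum(m)
#' @export
label_mask <- function(values, paired = NULL) {
  if (is.logical(values)) {
    dv <- dim(values)
    values <- array(as.integer(values), dv)
  }
  if (!is.array(values) || !(length(dim(values)) %in% c(2L, 3L)))
    abort("mask must be a 2D or 3D array")
  if (!all(values %in% c(0, 1)))
    abort("mask values must all be 0 or 1")
  if (!is.null(paired) && !identical(dim(values), dim(paired)))
    abort("mask shape does not match its paired grid")
  structure(array(as.integer(values), dim(values)),
            class = c("label_mask", "array"))
}

#' @export
print.label_mask <- function(x, ...) {
  d <- dim(x)
  cat(sprintf("<label_mask> %s, %d foreground of %d\n",
              paste(d, collapse = " x "), sum(x), length(x)))
  invisible(x)
}

# internal: strict shape check with a readable message
check_same_shape <- function(a, b, what = "masks") {
  if (!identical(dim(a), dim(b)))
    abort(sprintf("shape mismatch: %s have dims (%s) vs (%s)", what,
                  paste(dim(a), collapse = ","),
                  paste(dim(b), collapse = ",")))
  invisible(TRUE)
}

#' Plot one slice of a grid with an optional mask overlay
#'
#' @param grid a [voxel_grid()].
#' @param mask optional 3D [label_mask()] of the same shape; foreground is
#'   overlaid translucently.
#' @param slice slice index.
#' @return a ggplot object.
#' @export
plot_slice <- function(grid, mask = NULL, slice = 1L) {
  d <- dim(grid)
  if (slice < 1L || slice > d[1]) abort("slice index out of range")
  df <- expand.grid(row = seq_len(d[2]), col = seq_len(d[3]))
  df$intensity <- as.vector(unclass(grid)[slice, , ])
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row)) +
    ggplot2::geom_raster(ggplot2::aes(fill = .data$intensity)) +
    ggplot2::scale_fill_gradient(low = "black", high = "white") +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = NULL, y = NULL, fill = "GV",
                  title = sprintf("slice %d", slice)) +
    ggplot2::theme_minimal()
  if (!is.null(mask)) {
    check_same_shape(grid, mask, "grid and mask")
    dm <- df[as.vector(mask[slice, , ]) == 1, c("row", "col")]
    if (nrow(dm) > 0)
      p <- p + ggplot2::geom_tile(data = dm, fill = "red", alpha = 0.35)
  }
  p
}
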