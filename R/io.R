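#' Read a CT slice stack from a directory of images or a NIfTI volume
#'
#' Directories may hold PNG or TIFF slices (one per file, all with identical
#' dimensions); slices are stacked in lexicographic filename order so that a
#' re-read of the same directory is always identical. 8- and 16-bit integer
#' intensities are recovered bit-exactly. A `.nii`/`.nii.gz` path is read as
#' a volume in its native slice order (third dimension = slice axis).
#'
#' @param path directory of slice images, or a NIfTI file.
#' @param spacing isotropic voxel edge length, mm. Never inferred from file
#'   headers; the caller owns it.
#' @param patient_id,compartment optional metadata stored on the grid.
#' @return a [voxel_grid()] of shape `(slice, row, col)`.
#' @seealso [write_mask_stack()], [read_mask_stack()]
#' @export
read_slice_stack <- function(path, spacing = 0.0607, patient_id = NULL,
                             compartment = NULL) {
  if (!is.numeric(spacing) || length(spacing) != 1L || !is.finite(spacing) ||
      spacing <= 0)
    abort("bad spacing: must be a single positive number (mm)")
  if (!file.exists(path)) abort(sprintf("path does not exist: %s", path))
  if (dir.exists(path)) {
    files <- sort(list.files(path, pattern = "\\.(png|tif|tiff)$",
                             ignore.case = TRUE, full.names = TRUE))
    if (length(files) == 0L) abort("no slices: directory contains no image files")
    slices <- lapply(files, read_slice_image)
    dims <- vapply(slices, dim, integer(2))
    if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
      abort("ragged stack: slices do not share dimensions")
    arr <- array(0, c(length(slices), dims[1, 1], dims[2, 1]))
    for (i in seq_along(slices)) arr[i, , ] <- slices[[i]]
  } else {
    vol <- RNifti::readNifti(path)
    v <- as.array(vol)
    if (length(dim(v)) == 4L && dim(v)[4] == 1L) dim(v) <- dim(v)[1:3]
    if (length(dim(v)) != 3L) abort("volume file is not 3D")
    arr <- aperm(v, c(3, 1, 2))
  }
  voxel_grid(arr, spacing = spacing, patient_id = patient_id,
             compartment = compartment)
}

# read one grayscale slice, preserving integer intensities exactly
read_slice_image <- function(f) {
  ext <- tolower(tools::file_ext(f))
  if (ext == "png") {
    img <- png::readPNG(f, info = TRUE)
    depth <- attr(img, "info")$bit.depth
    if (is.null(depth)) depth <- 8L
    if (length(dim(img)) == 3L) img <- img[, , 1L]   # first channel of RGB(A)
    round(img * (2^depth - 1))
  } else {
    img <- tiff::readTIFF(f, as.is = TRUE)
    if (length(dim(img)) == 3L) img <- img[, , 1L]
    img
  }
}

#' Write a 3D binary mask as a PNG slice stack or a NIfTI volume
#'
#' The PNG dialect stores foreground as 255 on an 8-bit scale (one file per
#' slice, zero-padded names so lexicographic order is slice order); the NIfTI
#' dialect stores 0/1 in a single volume. Both round-trip exactly through
#' [read_mask_stack()].
#'
#' @param mask a 3D [label_mask()] (or 0/1 array), shape `(slice, row, col)`.
#' @param path output directory (PNG) or file path (NIfTI; `.nii`/`.nii.gz`
#'   appended if absent).
#' @param dialect `"png255"` or `"nifti"`.
#' @return invisibly, the written file path(s).
#' @export
write_mask_stack <- function(mask, path, dialect = c("png255", "nifti")) {
  dialect <- match.arg(dialect)
  if (is.null(dim(mask)) || length(dim(mask)) != 3L)
    abort("mask must be 3D")
  mask <- label_mask(mask)
  if (dialect == "png255") {
    if (!dir.exists(path)) dir.create(path, recursive = TRUE)
    n <- dim(mask)[1]
    files <- file.path(path, sprintf("mask_%04d.png", seq_len(n) - 1L))
    for (i in seq_len(n))
      png::writePNG(mask[i, , ] * 1.0, target = files[i])
    invisible(files)
  } else {
    if (!grepl("\\.nii(\\.gz)?$", path)) path <- paste0(path, ".nii.gz")
    RNifti::writeNifti(aperm(unclass(mask), c(2, 3, 1)), path)
    invisible(path)
  }
}

#' Read a binary mask stack written by [write_mask_stack()]
#'
#' PNG pixels with stored value >= 128 (on the 8-bit scale) are read as
#' foreground, so masks survive editors that slightly perturb levels.
#'
#' @param path PNG directory or NIfTI file.
#' @return a 3D [label_mask()].
#' @export
read_mask_stack <- function(path) {
  if (dir.exists(path)) {
    files <- sort(list.files(path, pattern = "\\.png$", ignore.case = TRUE,
                             full.names = TRUE))
    if (length(files) == 0L) abort("no slices: directory contains no PNG files")
    slices <- lapply(files, function(f) {
      img <- png::readPNG(f)
      if (length(dim(img)) == 3L) img <- img[, , 1L]
      (img * 255) >= 128
    })
    dims <- vapply(slices, dim, integer(2))
    if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
      abort("ragged stack: slices do not share dimensions")
    arr <- array(0L, c(length(slices), dims[1, 1], dims[2, 1]))
    for (i in seq_along(slices)) arr[i, , ] <- as.integer(slices[[i]])
    label_mask(arr)
  } else {
    v <- as.array(RNifti::readNifti(path))
    if (length(dim(v)) == 4L && dim(v)[4] == 1L) dim(v) <- dim(v)[1:3]
    label_mask(aperm(v, c(3, 1, 2)) != 0)
  }
}

cohort_required_cols <- c("patient_id", "compartment", "bvtv", "tb_th",
                          "tb_sp", "tb_n", "volume")

#' Load a per-tunnel cohort morphometry table
#'
#' One row per (patient, compartment) with the five morphometric indices:
#' BV/TV (fraction), Tb.Th and Tb.Sp (mm), Tb.N (1/mm), tunnel volume (mm3),
#' and optionally the mean grayscale value `mgv`. The package ships a
#' 48-row worked-example cohort (24 patients x femur/tibia) at
#' `system.file("extdata", "table4_cohort.csv", package = "tunnelmorph")`.
#'
#' @param path CSV with header
#'   `patient_id,compartment,bvtv,tb_th,tb_sp,tb_n,volume[,mgv]`.
#' @return a tibble, validated: unique (patient_id, compartment) keys,
#'   `bvtv` in \[0,1\], non-negative indices.
#' @examples
#' tab <- load_cohort_table(system.file("extdata", "table4_cohort.csv",
#'                                      package = "tunnelmorph"))
#' dplyr::filter(tab, patient_id == "1")
#' @export
load_cohort_table <- function(path) {
  if (!file.exists(path)) abort(sprintf("path does not exist: %s", path))
  raw <- read.csv(path, stringsAsFactors = FALSE, colClasses = "character")
  missing <- setdiff(cohort_required_cols, names(raw))
  if (length(missing) > 0L)
    abort(sprintf("schema error: missing column(s) %s",
                  paste(missing, collapse = ", ")))
  num_cols <- setdiff(names(raw), c("patient_id", "compartment"))
  for (cc in num_cols) {
    v <- suppressWarnings(as.numeric(raw[[cc]]))
    bad <- which(is.na(v) & nzchar(trimws(raw[[cc]])))
    if (length(bad) > 0L || anyNA(v))
      abort(sprintf("parse error: non-numeric value in column '%s', row %d",
                    cc, if (length(bad)) bad[1] else which(is.na(v))[1]))
    raw[[cc]] <- v
  }
  tab <- as_tibble(raw)
  key <- paste(tab$patient_id, tab$compartment)
  if (anyDuplicated(key))
    abort(sprintf("duplicate (patient_id, compartment) key: %s",
                  key[duplicated(key)][1]))
  if (!all(tab$compartment %in% c("femur", "tibia")))
    abort("compartment must be 'femur' or 'tibia'")
  if (any(tab$bvtv < 0 | tab$bvtv > 1)) abort("bvtv out of [0,1]")
  for (cc in c("tb_th", "tb_sp", "tb_n", "volume"))
    if (any(tab[[cc]] < 0)) abort(sprintf("%s must be non-negative", cc))
  tab
}
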