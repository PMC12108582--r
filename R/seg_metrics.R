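#' Confusion counts for a binary mask pair
#'
#' @param pred,truth [label_mask()]s (or 0/1 arrays) of identical shape.
#' @return named integer vector `(tp, fp, fn, tn)`; always sums to the pixel
#'   count.
#' @export
confusion <- function(pred, truth) {
  check_same_shape(pred, truth)
  p <- as.logical(pred)
  t <- as.logical(truth)
  c(tp = sum(p & t), fp = sum(p & !t), fn = sum(!p & t), tn = sum(!p & !t))
}

#' Segmentation scores for a mask pair
#'
#' Precision, recall, intersection-over-union (Jaccard), pixel accuracy and
#' dice, all in \[0,1\]. Empty-denominator convention: precision (recall) is
#' 1 when both masks are empty and 0 when only the prediction (truth) is
#' empty; the IoU and dice of two empty masks are 1. This keeps the identity
#' `scores(m, m) = 1` for every mask including the empty one.
#'
#' @inheritParams confusion
#' @return one-row tibble with columns `precision`, `recall`, `iou`,
#'   `pixel_accuracy`, `dice`.
#' @examples
#' a <- label_mask(matrix(c(1, 1, 0, 0), 2))
#' b <- label_mask(matrix(c(1, 0, 1, 0), 2))
#' segmentation_scores(a, b)
#' @export
segmentation_scores <- function(pred, truth) {
  k <- confusion(pred, truth)
  tp <- k[["tp"]]; fp <- k[["fp"]]; fn <- k[["fn"]]; tn <- k[["tn"]]
  both_empty <- (tp + fp + fn) == 0
  safe <- function(num, den) if (den == 0) as.numeric(both_empty) else num / den
  tibble(precision = safe(tp, tp + fp),
         recall = safe(tp, tp + fn),
         iou = safe(tp, tp + fp + fn),
         pixel_accuracy = (tp + tn) / sum(k),
         dice = safe(2 * tp, 2 * tp + fp + fn))
}

# coerce a mask collection (3D array or list of 2D masks) to a named list
as_slice_list <- function(x, name) {
  if (is.list(x)) {
    if (is.null(names(x))) names(x) <- sprintf("slice_%04d", seq_along(x))
    return(x)
  }
  if (is.array(x) && length(dim(x)) == 3L) {
    out <- lapply(seq_len(dim(x)[1]), function(i) x[i, , ])
    names(out) <- sprintf("slice_%04d", seq_along(out))
    return(out)
  }
  abort(sprintf("mask collection '%s' must be a 3D array or list of 2D masks",
                name))
}

#' Pairwise agreement table across annotators and predictions
#'
#' Scores every unordered pair of mask sources (e.g. the network's detection
#' results `DR` against each expert annotator `D1`, `D2`, `D3`, and the
#' annotators among themselves — the inter-observer layout) on a common set
#' of slices. Per-slice metrics are macro-averaged by default; micro pooling
#' accumulates confusion counts over all pixels first.
#'
#' @param sets named list of mask collections; each collection is a 3D mask
#'   array or a named list of 2D masks. All collections must cover identical
#'   slice identifiers.
#' @param pooling `"macro"` (mean of per-slice metrics) or `"micro"` (pooled
#'   confusion counts).
#' @return tibble with one row per unordered source pair: `source_a`,
#'   `source_b`, `pair`, `precision`, `recall`, `miou`, `mpa`, `mdice`,
#'   `n_slices`. Precision/recall are directional (a predicts b): swapping
#'   the pair order swaps them.
#' @export
pairwise_agreement <- function(sets, pooling = c("macro", "micro")) {
  pooling <- match.arg(pooling)
  if (!is.list(sets) || is.null(names(sets)) || length(sets) < 2L)
    abort("sets must be a named list of at least two mask collections")
  sets <- Map(as_slice_list, sets, names(sets))
  ids <- lapply(sets, names)
  ref <- ids[[1]]
  for (i in seq_along(ids)) {
    missing <- union(setdiff(ref, ids[[i]]), setdiff(ids[[i]], ref))
    if (length(missing) > 0L)
      abort(sprintf("mask collections cover different slices; mismatched: %s",
                    paste(missing, collapse = ", ")))
  }
  pairs <- utils::combn(names(sets), 2, simplify = FALSE)
  rows <- lapply(pairs, function(pr) {
    a <- sets[[pr[1]]]; b <- sets[[pr[2]]]
    if (pooling == "macro") {
      per <- dplyr::bind_rows(lapply(ref, function(id)
        segmentation_scores(a[[id]], b[[id]])))
      m <- colMeans(per)
    } else {
      k <- Reduce(`+`, lapply(ref, function(id) confusion(a[[id]], b[[id]])))
      tp <- k[["tp"]]; fp <- k[["fp"]]; fn <- k[["fn"]]; tn <- k[["tn"]]
      both_empty <- (tp + fp + fn) == 0
      safe <- function(num, den) if (den == 0) as.numeric(both_empty) else num / den
      m <- c(precision = safe(tp, tp + fp), recall = safe(tp, tp + fn),
             iou = safe(tp, tp + fp + fn), pixel_accuracy = (tp + tn) / sum(k),
             dice = safe(2 * tp, 2 * tp + fp + fn))
    }
    tibble(source_a = pr[1], source_b = pr[2],
           pair = paste(pr[1], pr[2], sep = "-"),
           precision = m[["precision"]], recall = m[["recall"]],
           miou = m[["iou"]], mpa = m[["pixel_accuracy"]],
           mdice = m[["dice"]], n_slices = length(ref))
  })
  dplyr::bind_rows(rows)
}

#' Mean grayscale value inside a segmented tunnel
#'
#' The mGV summarises bone distribution inside the tunnel: tissues image dark
#' and mineralized bone gray, so brighter tunnel interiors indicate more bone
#' fill. Per slice, mGV is the mean intensity over masked pixels; slices with
#' an empty mask are skipped. The sequence mGV is the unweighted mean of the
#' per-slice values (a voxel-weighted variant is available).
#'
#' @param grid a [voxel_grid()].
#' @param mask a 3D [label_mask()] of the same shape.
#' @param weighting `"slice"` (unweighted mean over slices, default) or
#'   `"voxel"` (mean over all masked voxels).
#' @return list with `per_slice` (tibble: `slice`, `n_pixels`, `mgv`) and
#'   `mgv` (the sequence value).
#' @export
mean_grayscale <- function(grid, mask, weighting = c("slice", "voxel")) {
  weighting <- match.arg(weighting)
  check_same_shape(grid, mask, "grid and mask")
  n <- dim(grid)[1]
  per <- lapply(seq_len(n), function(i) {
    m <- mask[i, , ] > 0
    if (!any(m)) return(NULL)
    tibble(slice = i, n_pixels = sum(m), mgv = mean(grid[i, , ][m]))
  })
  per <- dplyr::bind_rows(per)
  if (nrow(per) == 0L) abort("no tunnel voxels: mask is empty on every slice")
  seq_mgv <- if (weighting == "slice") mean(per$mgv)
  else sum(per$mgv * per$n_pixels) / sum(per$n_pixels)
  list(per_slice = per, mgv = seq_mgv)
}
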