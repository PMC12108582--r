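#' Specification of the ResNet50-U-net segmentation model
#'
#' The encoder is the standard ResNet50 layout: a 7x7 stride-2 stem
#' convolution plus 3x3 stride-2 max-pool, then four stages of 1x1/3x3/1x1
#' bottleneck triples repeated (3, 4, 6, 3) times with stride-2 spatial
#' reduction entering stages 3-5 -- five downsampling steps in total, so a
#' square input of side H reaches a deepest feature map of side
#' `ceiling(H/32)` (600 -> 19) at 2048 channels. Every convolution is
#' followed by batch normalization and ReLU. The decoder mirrors it with
#' five nearest-neighbour upsampling steps, concatenating the encoder skip
#' features at each resolution, and ends in a 1x1 convolution to 2 class
#' channels at the input size.
#'
#' `variant = "reduced"` keeps the exact stride/shape contract but shrinks
#' widths (base 8) and repeats (1,1,1,1); it exists so that desk-scale
#' training experiments run in seconds on a CPU.
#'
#' @param input_size declared `(H, W)` working resolution (any size >= 32 is
#'   accepted at forward time; this records the intended one).
#' @param num_classes output channels (2: background, tunnel).
#' @param variant `"full"` or `"reduced"`.
#' @param base_width stem width; 64 for the full network.
#' @param repeats bottleneck repeats for the four deep stages.
#' @param decoder_widths five decoder channel widths, deepest first.
#' @param seed initialisation seed (He-normal weights).
#' @return a `segnet_spec` list.
#' @export
model_spec <- function(input_size = c(600L, 600L), num_classes = 2L,
                       variant = c("full", "reduced"),
                       base_width = NULL, repeats = NULL,
                       decoder_widths = NULL, seed = 42L) {
  variant <- match.arg(variant)
  if (is.null(base_width)) base_width <- if (variant == "full") 64L else 8L
  if (is.null(repeats))
    repeats <- if (variant == "full") c(3L, 4L, 6L, 3L) else c(1L, 1L, 1L, 1L)
  if (is.null(decoder_widths))
    decoder_widths <- if (variant == "full") c(256L, 128L, 64L, 32L, 16L)
    else c(32L, 16L, 8L, 8L, 8L)
  stopifnot(length(repeats) == 4L, all(repeats >= 1L),
            length(decoder_widths) == 5L, num_classes == 2L)
  structure(list(input_size = as.integer(input_size),
                 num_classes = as.integer(num_classes), variant = variant,
                 base_width = as.integer(base_width),
                 repeats = as.integer(repeats),
                 decoder_widths = as.integer(decoder_widths),
                 seed = as.integer(seed)),
            class = "segnet_spec")
}

he_init <- function(kh, kw, cin, cout) {
  array(rnorm(kh * kw * cin * cout, 0, sqrt(2 / (kh * kw * cin))),
        c(kh, kw, cin, cout))
}

add_conv <- function(model, name, kh, kw, cin, cout) {
  model$params[[paste0(name, ".w")]] <- nn_param(he_init(kh, kw, cin, cout))
  model$params[[paste0(name, ".b")]] <- nn_param(numeric(cout))
  model$params[[paste0(name, ".g")]] <- nn_param(rep(1, cout))   # BN gamma
  model$params[[paste0(name, ".be")]] <- nn_param(numeric(cout)) # BN beta
  buf <- new.env(parent = emptyenv())
  buf$mean <- numeric(cout)
  buf$var <- rep(1, cout)
  model$buffers[[name]] <- buf
  invisible(model)
}

#' Build a segmentation model from a spec
#'
#' Allocates and seeds all parameters (He-normal convolution weights, unit
#' batch-norm scales). Pretrained encoder weights are not bundled with the
#' package; training always starts from this random initialisation
#' (`pretrained_encoder = TRUE` in [train_config()] is therefore rejected).
#'
#' @param spec a [model_spec()].
#' @return a `segnet_model` environment holding `spec`, `params` and
#'   batch-norm `buffers`.
#' @examples
#' m <- build_model(model_spec(variant = "reduced"))
#' out <- segnet_forward(m, array(0, c(1, 64, 64, 3)))
#' dim(out$logits); out$deepest_shape
#' @export
build_model <- function(spec) {
  stopifnot(inherits(spec, "segnet_spec"))
  model <- new.env(parent = emptyenv())
  model$spec <- spec
  model$params <- list()
  model$buffers <- list()
  class(model) <- "segnet_model"
  w <- spec$base_width
  mids <- w * c(1L, 2L, 4L, 8L)
  outs <- mids * 4L
  with_local_seed(spec$seed, {
    add_conv(model, "stem", 7, 7, 3, w)
    cin <- w
    for (s in 1:4) {
      for (r in seq_len(spec$repeats[s])) {
        nm <- sprintf("enc%d.%d", s, r)
        add_conv(model, paste0(nm, ".c1"), 1, 1, cin, mids[s])
        add_conv(model, paste0(nm, ".c2"), 3, 3, mids[s], mids[s])
        add_conv(model, paste0(nm, ".c3"), 1, 1, mids[s], outs[s])
        if (r == 1L) add_conv(model, paste0(nm, ".sc"), 1, 1, cin, outs[s])
        cin <- outs[s]
      }
    }
    skips <- c(outs[3], outs[2], outs[1], w)    # channels at /16, /8, /4, /2
    dw <- spec$decoder_widths
    cin_d <- outs[4]
    for (i in 1:5) {
      cat_in <- cin_d + if (i <= 4) skips[i] else 0L
      add_conv(model, sprintf("dec%d", i), 3, 3, cat_in, dw[i])
      cin_d <- dw[i]
    }
    model$params[["head.w"]] <- nn_param(he_init(1, 1, cin_d, spec$num_classes))
    model$params[["head.b"]] <- nn_param(numeric(spec$num_classes))
  })
  model
}

#' @export
print.segnet_model <- function(x, ...) {
  npar <- sum(vapply(x$params, function(p) length(p$val), numeric(1)))
  cat(sprintf("<segnet_model> %s variant, %s parameters\n",
              x$spec$variant, format(npar, big.mark = ",")))
  invisible(x)
}

# conv -> BN -> (ReLU) unit
conv_bn <- function(tp, model, name, x, stride = 1L, training = FALSE,
                    relu = TRUE) {
  p <- model$params
  y <- op_conv2d(tp, x, p[[paste0(name, ".w")]], p[[paste0(name, ".b")]],
                 stride = stride)
  y <- op_batchnorm(tp, y, p[[paste0(name, ".g")]], p[[paste0(name, ".be")]],
                    model$buffers[[name]], training = training)
  if (relu) y <- op_relu(tp, y) else y
}

bottleneck <- function(tp, model, nm, x, stride, training) {
  y <- conv_bn(tp, model, paste0(nm, ".c1"), x, 1L, training)
  y <- conv_bn(tp, model, paste0(nm, ".c2"), y, stride, training)
  y <- conv_bn(tp, model, paste0(nm, ".c3"), y, 1L, training, relu = FALSE)
  sc <- if (!is.null(model$params[[paste0(nm, ".sc.w")]]))
    conv_bn(tp, model, paste0(nm, ".sc"), x, stride, training, relu = FALSE)
  else x
  op_relu(tp, op_add(tp, y, sc))
}

#' Forward pass of the segmentation network
#'
#' Maps a batch of `(H, W, 3)` images to per-pixel class scores of the same
#' spatial size with 2 channels, and reports the deepest encoder feature
#' shape (side `ceiling(H/32)` for square inputs).
#'
#' @param model a `segnet_model`.
#' @param x numeric array `(N, H, W, 3)`, `H, W >= 32`.
#' @param training logical; batch statistics vs running statistics in BN.
#' @param tp optional tape (internal; enables backprop).
#' @return list: `logits` array `(N, H, W, 2)` (a node when `tp` is given),
#'   `deepest_shape` integer `(H/32-ish, W/32-ish, channels)`, and
#'   `skip_shapes`.
#' @export
segnet_forward <- function(model, x, training = FALSE, tp = NULL) {
  stopifnot(inherits(model, "segnet_model"))
  d <- dim(x)
  if (length(d) != 4L || d[4] != 3L)
    abort("input must be an (N, H, W, 3) array")
  if (d[2] < 32L || d[3] < 32L) abort("input too small: need H, W >= 32")
  spec <- model$spec
  x0 <- nn_node(NULL, x)
  s1 <- conv_bn(tp, model, "stem", x0, 2L, training)       # /2
  y <- op_maxpool(tp, s1)                                   # /4
  strides <- c(1L, 2L, 2L, 2L)
  stage_out <- vector("list", 4L)
  for (s in 1:4) {
    for (r in seq_len(spec$repeats[s]))
      y <- bottleneck(tp, model, sprintf("enc%d.%d", s, r), y,
                      if (r == 1L) strides[s] else 1L, training)
    stage_out[[s]] <- y
  }
  deepest <- dim(y$val)[c(2, 3, 4)]
  skips <- list(stage_out[[3]], stage_out[[2]], stage_out[[1]], s1)
  sizes <- lapply(skips, function(s) dim(s$val)[2:3])
  sizes[[5]] <- d[2:3]
  for (i in 1:5) {
    y <- op_upsample(tp, y, sizes[[i]][1], sizes[[i]][2])
    if (i <= 4) y <- op_concat(tp, y, skips[[i]])
    y <- conv_bn(tp, model, sprintf("dec%d", i), y, 1L, training)
  }
  logits <- op_conv2d(tp, y, model$params[["head.w"]],
                      model$params[["head.b"]], stride = 1L, pad = 0L)
  list(logits = if (is.null(tp)) logits$val else logits,
       deepest_shape = deepest,
       skip_shapes = lapply(stage_out, function(s) dim(s$val)[2:4]))
}

#' Dice coefficient loss
#'
#' `1 - (2 sum(p t) + eps) / (sum p + sum t + eps)` with `eps = 1e-6`:
#' 0 when the probability map reproduces the truth exactly, 1 when they are
#' disjoint. This is the training criterion of the segmentation stage.
#'
#' @param pred_probs per-pixel foreground probabilities in \[0,1\], any
#'   shape.
#' @param truth 0/1 mask of the same shape.
#' @param eps smoothing constant.
#' @return scalar loss in \[0,1\].
#' @examples
#' m <- matrix(c(1, 1, 0, 0), 2)
#' dice_loss(m, m)
#' @export
dice_loss <- function(pred_probs, truth, eps = 1e-6) {
  if (!identical(dim(pred_probs), dim(truth)) &&
      length(pred_probs) != length(truth))
    abort("shape mismatch between prediction and truth")
  if (any(pred_probs < 0 | pred_probs > 1))
    abort("pred_probs must lie in [0,1]")
  1 - (2 * sum(pred_probs * truth) + eps) /
    (sum(pred_probs) + sum(truth) + eps)
}

#' Training configuration
#'
#' Defaults mirror the reference training recipe: 100 epochs, batch size 12,
#' Adam at learning rate 1e-4 with beta1 0.9 / beta2 0.999 and weight decay
#' 1e-10, and a gradually decaying learning-rate schedule (step decay x0.5
#' every 25 epochs by default).
#'
#' @param epochs,batch_size,learning_rate,beta1,beta2,weight_decay Adam
#'   recipe.
#' @param lr_decay multiplicative decay factor.
#' @param lr_step epochs between decays.
#' @param seed shuffling/initialisation seed for the run.
#' @param pretrained_encoder must be `FALSE`: encoder weights are not
#'   bundled, training starts from random initialisation.
#' @return a `train_config` list.
#' @export
train_config <- function(epochs = 100L, batch_size = 12L,
                         learning_rate = 1e-4, beta1 = 0.9, beta2 = 0.999,
                         weight_decay = 1e-10, lr_decay = 0.5,
                         lr_step = 25L, seed = 1L,
                         pretrained_encoder = FALSE) {
  if (epochs < 0 || batch_size < 1) abort("epochs >= 0 and batch_size >= 1 required")
  if (learning_rate <= 0 || beta1 <= 0 || beta2 <= 0)
    abort("rates must be positive")
  if (isTRUE(pretrained_encoder))
    abort("pretrained encoder weights are not bundled; use pretrained_encoder = FALSE")
  structure(list(epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 learning_rate = learning_rate, beta1 = beta1, beta2 = beta2,
                 weight_decay = weight_decay, lr_decay = lr_decay,
                 lr_step = as.integer(lr_step), seed = as.integer(seed),
                 pretrained_encoder = FALSE),
            class = "train_config")
}

# intensity -> network input scaling (8-bit-like convention)
slice_to_input <- function(img) img / 255

pairs_to_batch <- function(pairs, idx) {
  h <- nrow(pairs[[1]]$image); w <- ncol(pairs[[1]]$image)
  x <- array(0, c(length(idx), h, w, 3))
  t <- array(0, c(length(idx), h, w))
  for (i in seq_along(idx)) {
    im <- slice_to_input(pairs[[idx[i]]]$image)
    x[i, , , 1] <- im; x[i, , , 2] <- im; x[i, , , 3] <- im
    t[i, , ] <- pairs[[idx[i]]]$mask
  }
  list(x = x, truth = t)
}

#' Train the segmentation model with Adam on dice loss
#'
#' @param model a `segnet_model` (modified in place and returned).
#' @param pairs list of `(image, mask)` pairs, e.g. from
#'   [make_training_set()]; all images must share one shape.
#' @param config a [train_config()].
#' @param verbose print one line per epoch.
#' @return list: `model`, `history` (tibble `epoch`, `loss`, `lr`; one row
#'   per epoch, mean batch loss).
#' @export
train_segnet <- function(model, pairs, config = train_config(),
                         verbose = FALSE) {
  stopifnot(inherits(model, "segnet_model"), inherits(config, "train_config"))
  if (config$epochs == 0L)
    return(list(model = model, history = tibble(epoch = integer(),
                                                loss = numeric(),
                                                lr = numeric())))
  if (length(pairs) == 0L) abort("empty training set")
  shp <- vapply(pairs, function(p) dim(p$image), integer(2))
  if (any(shp[1, ] != shp[1, 1]) || any(shp[2, ] != shp[2, 1]))
    abort("training pair shapes are inconsistent")
  mstate <- lapply(model$params, function(p) list(m = 0 * p$val, v = 0 * p$val))
  step <- 0L
  hist <- vector("list", config$epochs)
  with_local_seed(config$seed, {
    for (ep in seq_len(config$epochs)) {
      lr <- config$learning_rate *
        config$lr_decay^((ep - 1L) %/% config$lr_step)
      order_ <- base::sample.int(length(pairs))
      batches <- split(order_, ceiling(seq_along(order_) / config$batch_size))
      losses <- numeric(length(batches))
      for (bi in seq_along(batches)) {
        b <- pairs_to_batch(pairs, batches[[bi]])
        tp <- new_tape()
        out <- segnet_forward(model, b$x, training = TRUE, tp = tp)
        loss <- op_dice_loss(tp, out$logits, b$truth)
        losses[bi] <- loss$val
        zero_grads(model$params)
        nn_backward(tp, loss)
        step <- step + 1L
        b1t <- 1 - config$beta1^step
        b2t <- 1 - config$beta2^step
        for (nm in names(model$params)) {
          p <- model$params[[nm]]
          g <- p$grad
          if (is.null(g)) next
          g <- g + config$weight_decay * p$val
          st <- mstate[[nm]]
          st$m <- config$beta1 * st$m + (1 - config$beta1) * g
          st$v <- config$beta2 * st$v + (1 - config$beta2) * g^2
          mstate[[nm]] <- st
          p$val <- p$val - lr * (st$m / b1t) / (sqrt(st$v / b2t) + 1e-8)
        }
      }
      hist[[ep]] <- tibble(epoch = ep, loss = mean(losses), lr = lr)
      if (verbose)
        cat(sprintf("epoch %3d  loss %.4f  lr %.2e\n", ep, mean(losses), lr))
    }
  })
  list(model = model, history = dplyr::bind_rows(hist))
}

#' Segment every slice of a CT stack
#'
#' Runs the network slice by slice (grayscale replicated to 3 channels,
#' intensities scaled by 1/255) and binarises by per-pixel argmax over the
#' two class channels -- equivalent to a 0.5 probability threshold.
#'
#' @param model a trained `segnet_model`.
#' @param grid a [voxel_grid()] with slices of at least 32 x 32.
#' @param threshold optional foreground-probability cutoff replacing argmax
#'   (argmax == 0.5).
#' @return a 3D [label_mask()] with the grid's shape.
#' @export
predict_stack <- function(model, grid, threshold = NULL) {
  d <- dim(grid)
  if (d[2] < 32L || d[3] < 32L) abort("input too small: slices must be >= 32 x 32")
  out <- array(0L, d)
  for (i in seq_len(d[1])) {
    im <- slice_to_input(unclass(grid)[i, , ])
    x <- array(0, c(1, d[2], d[3], 3))
    x[1, , , 1] <- im; x[1, , , 2] <- im; x[1, , , 3] <- im
    logits <- segnet_forward(model, x, training = FALSE)$logits
    if (is.null(threshold)) {
      out[i, , ] <- (logits[1, , , 2] > logits[1, , , 1]) * 1L
    } else {
      p <- channel_softmax(logits)[1, , , 2]
      out[i, , ] <- (p >= threshold) * 1L
    }
  }
  label_mask(out)
}

#' Stratified train/validation split
#'
#' Splits a labelled collection so that each stratum (femur/tibia) keeps the
#' whole-set proportions to within one item, using largest-remainder
#' allocation of the seeded random draw.
#'
#' @param items data frame with a `compartment` column, or a character
#'   vector of stratum tags.
#' @param train_fraction fraction assigned to training, in (0,1).
#' @param seed integer.
#' @return list with `train` and `val`: row subsets for a data frame input,
#'   index vectors for a tag vector.
#' @examples
#' tags <- rep(c("femur", "tibia"), c(493, 565))
#' sp <- split_stratified(tags, 793 / 1058, seed = 7)
#' lengths(sp)
#' @export
split_stratified <- function(items, train_fraction, seed = 1L) {
  if (!(train_fraction > 0 && train_fraction < 1))
    abort("train_fraction must lie strictly between 0 and 1")
  tags <- if (is.data.frame(items)) {
    if (!"compartment" %in% names(items)) abort("items need a compartment column")
    items$compartment
  } else as.character(items)
  n <- length(tags)
  if (n == 0L) abort("empty input")
  target <- round(train_fraction * n)
  strata <- split(seq_len(n), tags)
  exact <- vapply(strata, length, integer(1)) * train_fraction
  alloc <- floor(exact)
  rem <- target - sum(alloc)
  if (rem > 0) {
    extra <- order(exact - alloc, decreasing = TRUE)[seq_len(rem)]
    alloc[extra] <- alloc[extra] + 1
  }
  train_idx <- with_local_seed(seed, {
    unlist(Map(function(ix, k) ix[base::sample.int(length(ix), k)],
               strata, alloc), use.names = FALSE)
  })
  train_idx <- sort(train_idx)
  val_idx <- setdiff(seq_len(n), train_idx)
  if (is.data.frame(items))
    list(train = items[train_idx, , drop = FALSE],
         val = items[val_idx, , drop = FALSE])
  else list(train = train_idx, val = val_idx)
}

#' Save / load a segmentation model
#'
#' Serialises the spec, parameter values and batch-norm running statistics;
#' [load_segnet()] rebuilds the model environment from them.
#'
#' @param model a `segnet_model`.
#' @param path `.rds` file path.
#' @return `save_segnet` the path, invisibly; `load_segnet` a
#'   `segnet_model`.
#' @export
save_segnet <- function(model, path) {
  stopifnot(inherits(model, "segnet_model"))
  obj <- list(spec = model$spec,
              params = lapply(model$params, function(p) p$val),
              buffers = lapply(model$buffers, function(b)
                list(mean = b$mean, var = b$var)))
  saveRDS(obj, path)
  invisible(path)
}

#' @rdname save_segnet
#' @export
load_segnet <- function(path) {
  obj <- readRDS(path)
  model <- build_model(obj$spec)
  for (nm in names(obj$params)) model$params[[nm]]$val <- obj$params[[nm]]
  for (nm in names(obj$buffers)) {
    model$buffers[[nm]]$mean <- obj$buffers[[nm]]$mean
    model$buffers[[nm]]$var <- obj$buffers[[nm]]$var
  }
  model
}
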