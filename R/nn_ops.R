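# Differentiable tensor ops on (N, H, W, C) arrays. Convolutions are
# evaluated as a sum over kernel offsets of strided-slice matrix products,
# which keeps everything inside BLAS without forming an im2col matrix.

# zero-pad the two spatial dims
pad_spatial <- function(x, pad, fill = 0) {
  if (pad == 0L) return(x)
  d <- dim(x)
  xp <- array(fill, c(d[1], d[2] + 2L * pad, d[3] + 2L * pad, d[4]))
  xp[, pad + seq_len(d[2]), pad + seq_len(d[3]), ] <- x
  xp
}

conv_out_len <- function(n, k, stride, pad) (n + 2L * pad - k) %/% stride + 1L

# 2D convolution; w dims (kh, kw, c_in, c_out), b length c_out.
# pad defaults to "same" arithmetic: for stride 2 this maps H -> ceil(H/2).
op_conv2d <- function(tp, x, w, b, stride = 1L, pad = (dim(w$val)[1] - 1L) %/% 2L) {
  xv <- x$val
  wv <- w$val
  d <- dim(xv)
  kh <- dim(wv)[1]; kw <- dim(wv)[2]
  cin <- dim(wv)[3]; cout <- dim(wv)[4]
  stopifnot(d[4] == cin)
  oh <- conv_out_len(d[2], kh, stride, pad)
  ow <- conv_out_len(d[3], kw, stride, pad)
  xp <- pad_spatial(xv, pad)
  npos <- d[1] * oh * ow
  wmat <- matrix(wv, nrow = kh * kw, ncol = cin * cout)  # rows = offset
  y <- matrix(rep(b$val, each = npos), nrow = npos)
  iy0 <- (seq_len(oh) - 1L) * stride
  ix0 <- (seq_len(ow) - 1L) * stride
  for (dj in seq_len(kw)) {
    ix <- ix0 + dj
    for (di in seq_len(kh)) {
      iy <- iy0 + di
      m <- xp[, iy, ix, , drop = FALSE]
      dim(m) <- c(npos, cin)
      wo <- matrix(wmat[di + (dj - 1L) * kh, ], nrow = cin, ncol = cout)
      y <- y + m %*% wo
    }
  }
  dim(y) <- c(d[1], oh, ow, cout)
  if (is.null(tp)) return(nn_node(NULL, y))
  nn_node(tp, y, parents = list(x, w, b), backfn = function(dy) {
    dim(dy) <- c(npos, cout)
    db <- colSums(dy)
    dw <- array(0, dim(wv))
    dxp <- array(0, dim(xp))
    for (dj in seq_len(kw)) {
      ix <- ix0 + dj
      for (di in seq_len(kh)) {
        iy <- iy0 + di
        m <- xp[, iy, ix, , drop = FALSE]
        dim(m) <- c(npos, cin)
        dw[di, dj, , ] <- crossprod(m, dy)
        wo <- matrix(wmat[di + (dj - 1L) * kh, ], nrow = cin, ncol = cout)
        dm <- dy %*% t(wo)
        dim(dm) <- c(d[1], oh, ow, cin)
        dxp[, iy, ix, ] <- dxp[, iy, ix, , drop = FALSE] + dm
      }
    }
    dx <- if (pad > 0L)
      dxp[, pad + seq_len(d[2]), pad + seq_len(d[3]), , drop = FALSE]
    else dxp
    dim(dx) <- d
    list(dx, dw, db)
  })
}

# batch normalization over (N, H, W) per channel; running stats live in a
# buffer environment (mean, var) updated in training mode
op_batchnorm <- function(tp, x, gamma, beta, buf, training,
                         momentum = 0.1, eps = 1e-5) {
  xv <- x$val
  d <- dim(xv)
  m <- prod(d[1:3])
  xm <- xv
  dim(xm) <- c(m, d[4])
  if (training) {
    mu <- colMeans(xm)
    xc <- sweep(xm, 2L, mu)
    va <- colMeans(xc^2)
    buf$mean <- (1 - momentum) * buf$mean + momentum * mu
    buf$var <- (1 - momentum) * buf$var + momentum * va * m / max(m - 1, 1)
  } else {
    mu <- buf$mean
    va <- buf$var
    xc <- sweep(xm, 2L, mu)
  }
  inv_sd <- 1 / sqrt(va + eps)
  xhat <- sweep(xc, 2L, inv_sd, `*`)
  y <- sweep(sweep(xhat, 2L, gamma$val, `*`), 2L, beta$val, `+`)
  dim(y) <- d
  if (is.null(tp)) return(nn_node(NULL, y))
  nn_node(tp, y, parents = list(x, gamma, beta), backfn = function(dy) {
    dim(dy) <- c(m, d[4])
    dgamma <- colSums(dy * xhat)
    dbeta <- colSums(dy)
    dxhat <- sweep(dy, 2L, gamma$val, `*`)
    if (training) {
      # standard batch-norm backward through the batch statistics
      t1 <- colSums(dxhat)
      t2 <- colSums(dxhat * xhat)
      dx <- sweep(dxhat, 2L, t1 / m) - sweep(xhat, 2L, t2 / m, `*`)
      dx <- sweep(dx, 2L, inv_sd, `*`)
    } else {
      dx <- sweep(dxhat, 2L, inv_sd, `*`)
    }
    dim(dx) <- d
    list(dx, dgamma, dbeta)
  })
}

op_relu <- function(tp, x) {
  y <- pmax(x$val, 0)
  if (is.null(tp)) return(nn_node(NULL, y))
  pos <- x$val > 0
  nn_node(tp, y, parents = list(x),
          backfn = function(dy) list(dy * pos))
}

op_add <- function(tp, a, b) {
  y <- a$val + b$val
  if (is.null(tp)) return(nn_node(NULL, y))
  nn_node(tp, y, parents = list(a, b), backfn = function(dy) list(dy, dy))
}

op_concat <- function(tp, a, b) {
  da <- dim(a$val); db <- dim(b$val)
  stopifnot(all(da[1:3] == db[1:3]))
  y <- array(0, c(da[1:3], da[4] + db[4]))
  y[, , , seq_len(da[4])] <- a$val
  y[, , , da[4] + seq_len(db[4])] <- b$val
  if (is.null(tp)) return(nn_node(NULL, y))
  nn_node(tp, y, parents = list(a, b), backfn = function(dy) {
    list(dy[, , , seq_len(da[4]), drop = FALSE],
         dy[, , , da[4] + seq_len(db[4]), drop = FALSE])
  })
}

# max pooling, pad filled with -Inf so padding never wins
op_maxpool <- function(tp, x, k = 3L, stride = 2L, pad = 1L) {
  xv <- x$val
  d <- dim(xv)
  oh <- conv_out_len(d[2], k, stride, pad)
  ow <- conv_out_len(d[3], k, stride, pad)
  xp <- pad_spatial(xv, pad, fill = -Inf)
  npos <- d[1] * oh * ow
  best <- matrix(-Inf, npos, d[4])
  argo <- matrix(0L, npos, d[4])
  iy0 <- (seq_len(oh) - 1L) * stride
  ix0 <- (seq_len(ow) - 1L) * stride
  o <- 0L
  for (dj in seq_len(k)) for (di in seq_len(k)) {
    o <- o + 1L
    m <- xp[, iy0 + di, ix0 + dj, , drop = FALSE]
    dim(m) <- c(npos, d[4])
    upd <- m > best
    best[upd] <- m[upd]
    argo[upd] <- o
  }
  y <- best
  dim(y) <- c(d[1], oh, ow, d[4])
  if (is.null(tp)) return(nn_node(NULL, y))
  nn_node(tp, y, parents = list(x), backfn = function(dy) {
    dim(dy) <- c(npos, d[4])
    dxp <- array(0, dim(xp))
    o <- 0L
    for (dj in seq_len(k)) for (di in seq_len(k)) {
      o <- o + 1L
      sel <- argo == o
      if (!any(sel)) next
      contrib <- dy * sel
      dim(contrib) <- c(d[1], oh, ow, d[4])
      dxp[, iy0 + di, ix0 + dj, ] <-
        dxp[, iy0 + di, ix0 + dj, , drop = FALSE] + contrib
    }
    dx <- dxp[, pad + seq_len(d[2]), pad + seq_len(d[3]), , drop = FALSE]
    dim(dx) <- d
    list(dx)
  })
}

# nearest-neighbour resize of the spatial dims to an exact target size
op_upsample <- function(tp, x, out_h, out_w) {
  xv <- x$val
  d <- dim(xv)
  iy <- floor((seq_len(out_h) - 1L) * d[2] / out_h) + 1L
  ix <- floor((seq_len(out_w) - 1L) * d[3] / out_w) + 1L
  y <- xv[, iy, ix, , drop = FALSE]
  if (is.null(tp)) return(nn_node(NULL, y))
  grp <- as.vector(outer(iy, (ix - 1L) * d[2], `+`))   # input cell per output cell
  nn_node(tp, y, parents = list(x), backfn = function(dy) {
    dim(dy) <- c(d[1], out_h * out_w, d[4])
    dyp <- aperm(dy, c(2, 1, 3))
    dim(dyp) <- c(out_h * out_w, d[1] * d[4])
    acc <- rowsum(dyp, group = grp)                    # sorted unique groups
    full <- matrix(0, d[2] * d[3], d[1] * d[4])
    full[as.integer(rownames(acc)), ] <- acc
    dim(full) <- c(d[2] * d[3], d[1], d[4])
    dx <- aperm(full, c(2, 1, 3))
    dim(dx) <- d
    list(dx)
  })
}

# softmax over the channel axis (returns probabilities; inference use)
channel_softmax <- function(logits) {
  d <- dim(logits)
  mx <- pmax(logits[, , , 1, drop = FALSE], logits[, , , 2, drop = FALSE])
  e1 <- exp(logits[, , , 1, drop = FALSE] - mx)
  e2 <- exp(logits[, , , 2, drop = FALSE] - mx)
  s <- e1 + e2
  y <- array(0, d)
  y[, , , 1] <- e1 / s
  y[, , , 2] <- e2 / s
  y
}

# dice loss of the foreground softmax channel against a 0/1 truth array
# (N, H, W); scalar node
op_dice_loss <- function(tp, logits, truth, eps = 1e-6) {
  p <- channel_softmax(logits$val)
  pf <- p[, , , 2]
  I <- sum(pf * truth)
  S <- sum(pf) + sum(truth)
  loss <- 1 - (2 * I + eps) / (S + eps)
  if (is.null(tp)) return(nn_node(NULL, loss))
  nn_node(tp, loss, parents = list(logits), backfn = function(dy) {
    den <- S + eps
    g <- -dy * (2 * truth * den - (2 * I + eps)) / den^2   # dL/d pf
    dfg <- g * pf * (1 - pf)
    dl <- array(0, dim(logits$val))
    dl[, , , 2] <- dfg
    dl[, , , 1] <- -dfg
    list(dl)
  })
}
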