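# Minimal reverse-mode automatic differentiation for the segmentation
# network. Tensors are plain numeric arrays with dims (N, H, W, C); a node is
# an environment holding the value, an accumulated gradient, its parent nodes
# and a backward closure. Ops append nodes to a per-forward tape in creation
# order, which is already a topological order, so backpropagation is a single
# reverse sweep. When no tape is supplied, ops run in inference mode and keep
# no caches.

new_tape <- function() {
  tp <- new.env(parent = emptyenv())
  tp$nodes <- list()
  tp$n <- 0L
  tp
}

nn_node <- function(tp, val, parents = list(), backfn = NULL) {
  nd <- new.env(parent = emptyenv())
  nd$val <- val
  nd$grad <- NULL
  if (!is.null(tp)) {
    nd$parents <- parents
    nd$backfn <- backfn
    tp$n <- tp$n + 1L
    tp$nodes[[tp$n]] <- nd
  }
  nd
}

# a leaf holding a learnable parameter (persistent across steps)
nn_param <- function(val) {
  nd <- new.env(parent = emptyenv())
  nd$val <- val
  nd$grad <- NULL
  nd
}

zero_grads <- function(params) {
  for (p in params) p$grad <- NULL
  invisible(NULL)
}

# reverse sweep from a scalar loss node
nn_backward <- function(tp, loss) {
  loss$grad <- 1
  for (i in rev(seq_len(tp$n))) {
    nd <- tp$nodes[[i]]
    if (is.null(nd$grad) || is.null(nd$backfn)) next
    gs <- nd$backfn(nd$grad)
    for (j in seq_along(nd$parents)) {
      g <- gs[[j]]
      if (is.null(g)) next
      p <- nd$parents[[j]]
      p$grad <- if (is.null(p$grad)) g else p$grad + g
    }
    nd$grad <- NULL      # free memory as we go
    nd$backfn <- NULL
  }
  invisible(NULL)
}
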