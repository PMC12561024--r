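# Minimal reverse-mode automatic differentiation.
#
# Values are plain R arrays in (H, W, C, N) layout (or scalars/vectors for
# reduced quantities). Nodes are environments carrying the value `v`, the
# accumulated gradient `g`, parent nodes and a backward closure. A global
# tape records creation order; backward() replays it in reverse. Heavy
# kernels live in src/kernels.cpp; this file only wires gradients.

.ag <- new.env(parent = emptyenv())
.ag$on <- FALSE
.ag$tape <- NULL
.ag$n <- 0L

ag_tape_start <- function() {
  .ag$tape <- vector("list", 1024L)
  .ag$n <- 0L
  .ag$on <- TRUE
  invisible(NULL)
}

ag_tape_stop <- function() {
  .ag$on <- FALSE
  .ag$tape <- NULL
  .ag$n <- 0L
  invisible(NULL)
}

ag_node <- function(value, parents = NULL, backward = NULL) {
  nd <- new.env(parent = emptyenv())
  nd$v <- value
  nd$g <- NULL
  if (.ag$on && !is.null(backward)) {
    nd$parents <- parents
    nd$bw <- backward
    n <- .ag$n + 1L
    if (n > length(.ag$tape)) .ag$tape <- c(.ag$tape, vector("list", length(.ag$tape)))
    .ag$tape[[n]] <- nd
    .ag$n <- n
  }
  nd
}

# Leaf holding trainable values; reused across steps.
ag_param <- function(value) {
  nd <- new.env(parent = emptyenv())
  nd$v <- value
  nd$g <- NULL
  nd$param <- TRUE
  nd
}

ag_const <- function(value) {
  nd <- new.env(parent = emptyenv())
  nd$v <- value
  nd$g <- NULL
  nd
}

ag_accum <- function(node, g) {
  node$g <- if (is.null(node$g)) g else node$g + g
  invisible(NULL)
}

# Reverse sweep from a scalar loss node. Clears the tape afterwards.
ag_backward <- function(loss) {
  if (!.ag$on) stop("no active tape")
  loss$g <- 1
  for (i in seq(.ag$n, 1L)) {
    nd <- .ag$tape[[i]]
    if (is.null(nd$g)) next
    gs <- nd$bw(nd$g)
    for (j in seq_along(nd$parents)) {
      if (!is.null(gs[[j]])) ag_accum(nd$parents[[j]], gs[[j]])
    }
    nd$g <- NULL
  }
  ag_tape_stop()
  invisible(NULL)
}

# ------------------------------------------------------------------- ops ---

op_conv <- function(x, w, b, stride = 1L, pad = 1L) {
  y <- cpp_conv2d(x$v, w$v, b$v, stride, pad)
  ag_node(y, list(x, w, b), function(g) {
    r <- cpp_conv2d_bw(x$v, w$v, g, stride, pad)
    list(r$gx, r$gw, r$gb)
  })
}

op_dwconv3 <- function(x, w, b) {
  y <- cpp_dwconv3(x$v, w$v, b$v)
  ag_node(y, list(x, w, b), function(g) {
    r <- cpp_dwconv3_bw(x$v, w$v, g)
    list(r$gx, r$gw, r$gb)
  })
}

# Batch norm over a layer state (running stats updated in training mode).
op_bn <- function(x, ln, training, momentum = 0.1, eps = 1e-5) {
  if (training) {
    f <- cpp_bn_fwd(x$v, ln$gamma$v, ln$beta$v, eps)
    ln$rmean <- (1 - momentum) * ln$rmean + momentum * f$mean
    m <- prod(dim(x$v)[c(1, 2, 4)])
    unb <- if (m > 1) m / (m - 1) else 1
    ln$rvar <- (1 - momentum) * ln$rvar + momentum * f$var * unb
    ag_node(f$y, list(x, ln$gamma, ln$beta), function(g) {
      r <- cpp_bn_bwd(x$v, ln$gamma$v, f$mean, f$invstd, g)
      list(r$gx, r$ggamma, r$gbeta)
    })
  } else {
    ag_const(cpp_bn_eval(x$v, ln$gamma$v, ln$beta$v, ln$rmean, ln$rvar, eps))
  }
}

op_ln <- function(x, gamma, beta, eps = 1e-6) {
  f <- cpp_ln_fwd(x$v, gamma$v, beta$v, eps)
  ag_node(f$y, list(x, gamma, beta), function(g) {
    r <- cpp_ln_bwd(x$v, gamma$v, f$mean, f$invstd, g)
    list(r$gx, r$ggamma, r$gbeta)
  })
}

op_relu <- function(x) {
  y <- pmax(x$v, 0)
  ag_node(y, list(x), function(g) list(g * (x$v > 0)))
}

op_gelu <- function(x) {
  ag_node(cpp_gelu(x$v), list(x), function(g) list(cpp_gelu_bw(x$v, g)))
}

op_sigmoid <- function(x) {
  s <- cpp_sigmoid(x$v)
  ag_node(s, list(x), function(g) list(g * s * (1 - s)))
}

op_maxpool2 <- function(x) {
  d <- dim(x$v)
  f <- cpp_maxpool2(x$v)
  ag_node(f$y, list(x), function(g) {
    list(cpp_maxpool2_bw(f$idx, g, d[1], d[2], d[3], d[4]))
  })
}

op_pool_same <- function(x, kh, kw, mode = c("max", "min")) {
  mode <- match.arg(mode)
  d <- dim(x$v)
  f <- cpp_pool_same(x$v, kh, kw, if (mode == "max") 0L else 1L)
  ag_node(f$y, list(x), function(g) {
    list(cpp_scatter_bw(f$idx, g, d[1], d[2], d[3], d[4]))
  })
}

op_up2 <- function(x) {
  d <- dim(x$v)
  ag_node(cpp_up2(x$v), list(x), function(g) list(cpp_up2_bw(g, d[1], d[2])))
}

op_shift <- function(x, axis, shifts) {
  ag_node(cpp_shift(x$v, axis, shifts), list(x), function(g) {
    list(cpp_shift(g, axis, -shifts))
  })
}

op_add <- function(a, b) {
  ag_node(a$v + b$v, list(a, b), function(g) list(g, g))
}

op_sub <- function(a, b) {
  ag_node(a$v - b$v, list(a, b), function(g) list(g, -g))
}

op_mul <- function(a, b) {
  ag_node(a$v * b$v, list(a, b), function(g) list(g * b$v, g * a$v))
}

op_div <- function(a, b) {
  ag_node(a$v / b$v, list(a, b),
          function(g) list(g / b$v, -g * a$v / (b$v * b$v)))
}

op_smul <- function(a, s) {
  ag_node(a$v * s, list(a), function(g) list(g * s))
}

op_sadd <- function(a, s) {
  ag_node(a$v + s, list(a), function(g) list(g))
}

# c - x
op_rsub <- function(s, a) {
  ag_node(s - a$v, list(a), function(g) list(-g))
}

op_minimum <- function(a, b) {
  m <- a$v <= b$v
  ag_node(pmin(a$v, b$v), list(a, b), function(g) list(g * m, g * !m))
}

# Per-sample sum of a (H,W,C,N) tensor -> length-N vector.
op_sum_samples <- function(x) {
  d <- dim(x$v)
  pp <- prod(d[1:3])
  y <- colSums(matrix(x$v, nrow = pp))
  ag_node(y, list(x), function(g) {
    gx <- rep(g, each = pp)
    dim(gx) <- d
    list(gx)
  })
}

op_mean <- function(x) {
  n <- length(x$v)
  ag_node(mean(x$v), list(x), function(g) {
    gx <- rep(g / n, n)
    dim(gx) <- dim(x$v)
    list(gx)
  })
}

# Weighted binary cross-entropy on logits (fused forward/backward kernel).
op_wbce <- function(z, target, pos_weight) {
  f <- cpp_wbce(z$v, target, pos_weight)
  ag_node(f$loss, list(z), function(g) list(g * f$gz))
}
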