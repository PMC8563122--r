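# Minimal reverse-mode tape over the handful of array operations the
# network needs. Nodes are environments recorded in creation order, so
# reversing that order is a valid topological order for backprop.
#
# Layout convention: every spatial tensor is an (H, W, C, N) array;
# classifier scores are (K x N) matrices; losses are length-1 numerics.

tape_new <- function() {
  tp <- new.env(parent = emptyenv())
  tp$nodes <- vector("list", 64L)
  tp$n <- 0L
  tp
}

tp_record <- function(tape, value, parents = list(), backfn = NULL) {
  nd <- new.env(parent = emptyenv())
  nd$value <- value
  nd$grad <- NULL
  nd$parents <- parents
  nd$backfn <- backfn
  tape$n <- tape$n + 1L
  if (tape$n > length(tape$nodes))
    length(tape$nodes) <- 2L * length(tape$nodes)
  tape$nodes[[tape$n]] <- nd
  nd
}

tp_leaf <- function(tape, value) tp_record(tape, value)

#' @noRd
tp_backward <- function(tape, out, seed = 1) {
  out$grad <- if (length(out$value) == 1L) seed else stop("backward seed must be scalar")
  for (k in seq(tape$n, 1L)) {
    nd <- tape$nodes[[k]]
    if (is.null(nd$grad) || is.null(nd$backfn)) next
    gs <- nd$backfn(nd$grad)
    for (j in seq_along(nd$parents)) {
      g <- gs[[j]]
      if (is.null(g)) next
      p <- nd$parents[[j]]
      p$grad <- if (is.null(p$grad)) g else p$grad + g
    }
  }
  invisible(out)
}

# ---- elementwise ----

op_relu <- function(tape, x) {
  v <- x$value * (x$value > 0)
  tp_record(tape, v, list(x), function(g) list(g * (v > 0)))
}

op_sigmoid <- function(tape, x) {
  v <- 1 / (1 + exp(-x$value))
  tp_record(tape, v, list(x), function(g) list(g * v * (1 - v)))
}

op_add <- function(tape, x, y) {
  tp_record(tape, x$value + y$value, list(x, y), function(g) list(g, g))
}

op_cmul <- function(tape, x, y) {
  tp_record(tape, x$value * y$value, list(x, y),
            function(g) list(g * y$value, g * x$value))
}

op_scale <- function(tape, x, a) {
  tp_record(tape, a * x$value, list(x), function(g) list(a * g))
}

op_add_const <- function(tape, x, a) {
  tp_record(tape, x$value + a, list(x), function(g) list(g))
}

# ---- shape ----

op_concat_ch <- function(tape, x, y) {
  dx <- dim(x$value); dy <- dim(y$value)
  stopifnot(all(dx[c(1, 2, 4)] == dy[c(1, 2, 4)]))
  v <- array(0, c(dx[1], dx[2], dx[3] + dy[3], dx[4]))
  v[, , seq_len(dx[3]), ] <- x$value
  v[, , dx[3] + seq_len(dy[3]), ] <- y$value
  tp_record(tape, v, list(x, y), function(g) {
    list(g[, , seq_len(dx[3]), , drop = FALSE],
         g[, , dx[3] + seq_len(dy[3]), , drop = FALSE])
  })
}

op_avgpool2 <- function(tape, x) {
  tp_record(tape, avgpool2_fwd_cpp(x$value), list(x),
            function(g) list(avgpool2_bwd_cpp(g)))
}

op_bilinear <- function(tape, x, oh, ow) {
  d <- dim(x$value)
  if (d[1] == oh && d[2] == ow) return(x)
  tp_record(tape, bilinear_fwd_cpp(x$value, oh, ow), list(x),
            function(g) list(bilinear_bwd_cpp(g, d[1], d[2])))
}

op_gap <- function(tape, x) {
  d <- dim(x$value)
  hw <- d[1] * d[2]
  v <- matrix(colSums(matrix(x$value, hw)) / hw, d[3], d[4])
  tp_record(tape, v, list(x),
            function(g) list(array(rep(g, each = hw) / hw, d)))
}

op_select <- function(tape, x, i, j) {
  tp_record(tape, x$value[i, j], list(x), function(g) {
    dg <- matrix(0, nrow(x$value), ncol(x$value))
    dg[i, j] <- g
    list(dg)
  })
}

# ---- convolution ----

op_conv <- function(tape, x, w, b, stride = 1L, pad = 1L) {
  v <- conv2d_fwd_cpp(x$value, w$value, b$value, stride, pad)
  tp_record(tape, v, list(x, w, b), function(g) {
    gr <- conv2d_bwd_cpp(g, x$value, w$value, stride, pad)
    list(gr$dx, gr$dw, gr$db)
  })
}

# ---- batch normalization ----

# Per-channel sum of an (H, W, C, N) array.
chan_sum <- function(a) {
  d <- dim(a)
  rowSums(matrix(colSums(matrix(a, d[1] * d[2])), d[3]))
}

# Broadcast a per-channel vector over an (H, W, C, N) shape.
chan_expand <- function(v, d) {
  rep(rep(v, each = d[1] * d[2]), times = d[4])
}

# Spatial batch normalization over (H, W, N) per channel. `state` is an
# environment holding running mean/var, updated as a side effect in
# training mode (the running stats are bookkeeping, not graph values).
op_bn <- function(tape, x, gamma, beta, state, training,
                  momentum = 0.1, eps = 1e-5) {
  d <- dim(x$value)
  m <- d[1] * d[2] * d[4]
  if (training) {
    mu <- chan_sum(x$value) / m
    xc <- x$value - chan_expand(mu, d)
    var <- chan_sum(xc * xc) / m
    state$mean <- (1 - momentum) * state$mean + momentum * mu
    state$var <- (1 - momentum) * state$var +
      momentum * var * m / max(m - 1, 1)
    istd <- 1 / sqrt(var + eps)
    xhat <- xc * chan_expand(istd, d)
    v <- xhat * chan_expand(gamma$value, d) + chan_expand(beta$value, d)
    tp_record(tape, v, list(x, gamma, beta), function(g) {
      dbeta <- chan_sum(g)
      dgamma <- chan_sum(g * xhat)
      gx <- g * chan_expand(gamma$value, d)
      dxhat_sum <- chan_sum(gx)
      dxhat_dot <- chan_sum(gx * xhat)
      dx <- chan_expand(istd, d) *
        (gx - chan_expand(dxhat_sum / m, d) -
           xhat * chan_expand(dxhat_dot / m, d))
      list(dx, dgamma, dbeta)
    })
  } else {
    istd <- 1 / sqrt(state$var + eps)
    scale <- gamma$value * istd
    shift <- beta$value - gamma$value * state$mean * istd
    v <- x$value * chan_expand(scale, d) + chan_expand(shift, d)
    tp_record(tape, v, list(x, gamma, beta), function(g) {
      xh <- (x$value - chan_expand(state$mean, d)) * chan_expand(istd, d)
      list(g * chan_expand(scale, d), chan_sum(g * xh), chan_sum(g))
    })
  }
}

# ---- losses ----

# Two-class softmax head scored against binary labels with the
# binary cross-entropy of the positive-class probability (row 2).
# Probabilities are clamped at eps before the logs.
op_softmax_bce <- function(tape, scores, y, eps = 1e-7) {
  s <- scores$value
  stopifnot(nrow(s) == 2L, length(y) == ncol(s))
  smax <- pmax(s[1, ], s[2, ])
  e1 <- exp(s[1, ] - smax); e2 <- exp(s[2, ] - smax)
  p <- e2 / (e1 + e2)
  pc <- pmin(pmax(p, eps), 1 - eps)
  n <- length(y)
  v <- -mean(y * log(pc) + (1 - y) * log(1 - pc))
  tp_record(tape, v, list(scores), function(g) {
    dp <- (pc - y) / n          # d/dscore2 of mean BCE via softmax
    list(g * rbind(-dp, dp))
  })
}

# Uncertainty-weighted two-task total: 0.5 e^-eta_h L_h + 0.5 e^-eta_k L_k
# + eta_h + eta_k, with eta = log sigma^2 as free parameters.
op_uncertainty_total <- function(tape, l_h, l_k, eta_h, eta_k) {
  wh <- 0.5 * exp(-eta_h$value)
  wk <- 0.5 * exp(-eta_k$value)
  v <- wh * l_h$value + wk * l_k$value + eta_h$value + eta_k$value
  tp_record(tape, v, list(l_h, l_k, eta_h, eta_k), function(g) {
    list(g * wh, g * wk,
         g * (1 - wh * l_h$value),
         g * (1 - wk * l_k$value))
  })
}
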