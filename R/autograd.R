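# Reverse-mode automatic differentiation on matrices.
#
# Every value on the tape is a numeric matrix.  A node is an environment with
# $value, $grad (accumulated during the backward pass), $parents (list of
# nodes) and $backward (closure mapping the node's output gradient to a list
# of parent gradients, positionally matching $parents).  Nodes carry a
# monotone id from a package-level counter, so reverse-id order is a valid
# topological order and the backward pass is a single reverse sweep.

.ag <- new.env(parent = emptyenv())
.ag$counter <- 0L

ag_node <- function(value, parents = list(), backward = NULL) {
  stopifnot(is.matrix(value))
  e <- new.env(parent = emptyenv())
  e$value <- value
  e$grad <- NULL
  e$parents <- parents
  e$backward <- backward
  .ag$counter <- .ag$counter + 1L
  e$id <- .ag$counter
  class(e) <- "ag_node"
  e
}

ag_const <- function(value) ag_node(as_mat(value))

ag_param <- function(value) {
  n <- ag_node(as_mat(value))
  n$is_param <- TRUE
  n
}

as_mat <- function(x) {
  if (is.matrix(x)) x else matrix(x, nrow = 1L)
}

is_node <- function(x) inherits(x, "ag_node")

#' @noRd
ag_value <- function(x) if (is_node(x)) x$value else x

# Backward pass from a scalar loss node.  Accumulates gradients into every
# reachable node's $grad; parameter gradients are read off afterwards.
ag_backward <- function(loss) {
  stopifnot(is_node(loss), length(loss$value) == 1L)
  # collect reachable nodes (iterative DFS, dedup by id)
  seen <- new.env(parent = emptyenv())
  nodes <- vector("list", 256L)
  n_nodes <- 0L
  stack <- list(loss)
  while (length(stack)) {
    nd <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    key <- as.character(nd$id)
    if (!is.null(seen[[key]])) next
    seen[[key]] <- TRUE
    n_nodes <- n_nodes + 1L
    if (n_nodes > length(nodes)) nodes <- c(nodes, vector("list", length(nodes)))
    nodes[[n_nodes]] <- nd
    for (p in nd$parents) stack[[length(stack) + 1L]] <- p
  }
  nodes <- nodes[seq_len(n_nodes)]
  ord <- order(vapply(nodes, function(n) n$id, integer(1L)), decreasing = TRUE)
  loss$grad <- matrix(1, 1L, 1L)
  for (nd in nodes[ord]) {
    if (is.null(nd$backward) || is.null(nd$grad)) next
    gs <- nd$backward(nd$grad)
    for (i in seq_along(nd$parents)) {
      g <- gs[[i]]
      if (is.null(g)) next
      p <- nd$parents[[i]]
      p$grad <- if (is.null(p$grad)) g else p$grad + g
    }
  }
  invisible(loss)
}

ag_zero_grads <- function(params) {
  for (p in params) p$grad <- NULL
  invisible(NULL)
}

# ---- primitive ops ---------------------------------------------------------

ag_add <- function(a, b) {
  ag_node(a$value + b$value, list(a, b), function(g) list(g, g))
}

ag_scale <- function(a, s) {
  ag_node(a$value * s, list(a), function(g) list(g * s))
}

ag_mul <- function(a, b) {
  av <- a$value; bv <- b$value
  ag_node(av * bv, list(a, b), function(g) list(g * bv, g * av))
}

# x (n x d) times col vector a (n x 1), broadcast across columns
ag_mul_bcast <- function(x, a) {
  xv <- x$value; av <- a$value[, 1L]
  ag_node(xv * av, list(x, a), function(g) {
    list(g * av, matrix(rowSums(g * xv), ncol = 1L))
  })
}

ag_matmul <- function(a, b) {
  av <- a$value; bv <- b$value
  ag_node(av %*% bv, list(a, b), function(g) {
    list(g %*% t(bv), t(av) %*% g)
  })
}

# y = x W + 1 b   (b optional 1 x dout)
ag_linear <- function(x, W, b = NULL) {
  xv <- x$value; Wv <- W$value
  y <- xv %*% Wv
  if (is.null(b)) {
    ag_node(y, list(x, W), function(g) list(g %*% t(Wv), t(xv) %*% g))
  } else {
    y <- sweep(y, 2L, b$value[1L, ], "+")
    ag_node(y, list(x, W, b), function(g) {
      list(g %*% t(Wv), t(xv) %*% g, matrix(colSums(g), nrow = 1L))
    })
  }
}

ag_sigmoid <- function(x) {
  s <- 1 / (1 + exp(-x$value))
  ag_node(s, list(x), function(g) list(g * s * (1 - s)))
}

# exact GELU: x * Phi(x)
ag_gelu <- function(x) {
  xv <- x$value
  ph <- stats::pnorm(xv)
  ag_node(xv * ph, list(x), function(g) list(g * (ph + xv * stats::dnorm(xv))))
}

ag_rowsum <- function(x) {
  xv <- x$value
  ag_node(matrix(rowSums(xv), ncol = 1L), list(x), function(g) {
    matrix(g[, 1L], nrow(xv), ncol(xv))
    list(matrix(g[, 1L], nrow(xv), ncol(xv)))
  })
}

# row-wise layer normalisation with learned gain/shift (1 x d each)
ag_layernorm <- function(x, gamma, beta, eps = 1e-5) {
  xv <- x$value
  d <- ncol(xv)
  mu <- rowMeans(xv)
  xc <- xv - mu
  v <- rowMeans(xc * xc)
  inv <- 1 / sqrt(v + eps)
  xhat <- xc * inv
  gv <- gamma$value[1L, ]
  y <- sweep(xhat, 2L, gv, "*")
  y <- sweep(y, 2L, beta$value[1L, ], "+")
  ag_node(y, list(x, gamma, beta), function(g) {
    dxhat <- sweep(g, 2L, gv, "*")
    # dx = inv/d * (d*dxhat - rowsum(dxhat) - xhat * rowsum(dxhat*xhat))
    s1 <- rowSums(dxhat)
    s2 <- rowSums(dxhat * xhat)
    dx <- (inv / d) * (d * dxhat - s1 - xhat * s2)
    list(dx,
         matrix(colSums(g * xhat), nrow = 1L),
         matrix(colSums(g), nrow = 1L))
  })
}

# Gather rows by integer index; idx == 0L yields a zero row (used for conv
# padding).  Backward scatter-adds into the source.
ag_gather_rows <- function(x, idx) {
  xv <- x$value
  out <- matrix(0, length(idx), ncol(xv))
  nz <- idx > 0L
  out[nz, ] <- xv[idx[nz], , drop = FALSE]
  ag_node(out, list(x), function(g) {
    dx <- matrix(0, nrow(xv), ncol(xv))
    if (any(nz)) {
      acc <- rowsum(g[nz, , drop = FALSE], group = idx[nz])
      dx[as.integer(rownames(acc)), ] <- acc
    }
    list(dx)
  })
}

ag_slice_cols <- function(x, cols) {
  xv <- x$value
  ag_node(xv[, cols, drop = FALSE], list(x), function(g) {
    dx <- matrix(0, nrow(xv), ncol(xv))
    dx[, cols] <- g
    list(dx)
  })
}

ag_cbind <- function(lst) {
  vals <- lapply(lst, function(n) n$value)
  widths <- vapply(vals, ncol, integer(1L))
  ends <- cumsum(widths)
  starts <- ends - widths + 1L
  ag_node(do.call(cbind, vals), lst, function(g) {
    lapply(seq_along(lst), function(i) g[, starts[i]:ends[i], drop = FALSE])
  })
}

# Mean over blocks of n_per consecutive rows (global average pooling when the
# rows of one sample are contiguous).
ag_group_mean <- function(x, n_per) {
  xv <- x$value
  G <- nrow(xv) / n_per
  stopifnot(G == round(G))
  grp <- rep(seq_len(G), each = n_per)
  ag_node(rowsum(xv, grp) / n_per, list(x), function(g) {
    list(g[grp, , drop = FALSE] / n_per)
  })
}

# Add a per-token parameter P (m x d) to x ((B*m) x d), tiled over samples.
ag_add_posenc <- function(x, P) {
  xv <- x$value; Pv <- P$value
  m <- nrow(Pv)
  B <- nrow(xv) / m
  stopifnot(B == round(B))
  grp <- rep(seq_len(m), times = B)
  ag_node(xv + Pv[grp, , drop = FALSE], list(x, P), function(g) {
    list(g, rowsum(g, grp))
  })
}

# Reshape a column vector node (nr*nc x 1) into an (nr x nc) matrix
# (column-major, matching base R `matrix`).
ag_reshape <- function(x, nr, nc) {
  xv <- x$value
  stopifnot(length(xv) == nr * nc)
  ag_node(matrix(xv, nr, nc), list(x), function(g) {
    list(matrix(as.numeric(g), ncol = ncol(xv)))
  })
}

# Batched attention via the compiled kernel.  q: (G*nq) x d, k/v: (G*nk) x d.
# bias: optional node (nq x nk) shared across groups; mask: optional numeric
# (G*nq) x nk additive matrix (no gradient).
ag_attention <- function(q, k, v, nq, nk, scale, bias = NULL, mask = NULL) {
  if (anyNA(q$value) || any(!is.finite(q$value)) ||
      anyNA(k$value) || any(!is.finite(k$value)) ||
      anyNA(v$value) || any(!is.finite(v$value))) {
    stop("attention inputs contain NaN or Inf")
  }
  bmat <- if (is.null(bias)) matrix(numeric(0), 0L, 0L) else bias$value
  mmat <- if (is.null(mask)) matrix(numeric(0), 0L, 0L) else mask
  fw <- attn_forward_cpp(q$value, k$value, v$value, nq, nk, scale, bmat, mmat)
  parents <- list(q, k, v)
  if (!is.null(bias)) parents <- c(parents, list(bias))
  nd <- ag_node(fw$out, parents, NULL)
  nd$probs <- fw$probs
  qv <- q$value; kv <- k$value; vv <- v$value
  want_bias <- !is.null(bias)
  nd$backward <- function(g) {
    bw <- attn_backward_cpp(g, fw$probs, qv, kv, vv, nq, nk, scale, want_bias)
    out <- list(bw$dQ, bw$dK, bw$dV)
    if (want_bias) out <- c(out, list(bw$dBias))
    out
  }
  nd
}

# inverted dropout; identity unless training with rate > 0.  Mask draws come
# from the session RNG, so seeded training loops stay reproducible.
ag_dropout <- function(x, rate, training) {
  if (!training || rate <= 0) return(x)
  keep <- matrix(stats::runif(length(x$value)) >= rate,
                 nrow(x$value), ncol(x$value)) / (1 - rate)
  ag_node(x$value * keep, list(x), function(g) list(g * keep))
}

# Fused softmax + cross-entropy, mean over rows.  labels: integer vector in
# 1..K.  Probabilities are clamped at 1e-12 before the log.
ag_softmax_xent <- function(logits, labels) {
  lv <- logits$value
  n <- nrow(lv)
  stopifnot(length(labels) == n)
  m <- apply(lv, 1L, max)
  e <- exp(lv - m)
  p <- e / rowSums(e)
  idx <- cbind(seq_len(n), labels)
  loss <- -mean(log(pmax(p[idx], 1e-12)))
  nd <- ag_node(matrix(loss, 1L, 1L), list(logits), function(g) {
    d <- p
    d[idx] <- d[idx] - 1
    list(d * (g[1L, 1L] / n))
  })
  nd$probs <- p
  nd
}
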