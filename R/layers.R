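# Transformer building blocks: multi-head self-attention (MSA), windowed
# attention with relative position bias (W-MSA / SW-MSA), spatial-reduction
# attention (SRA), pre-norm residual blocks, and the supporting grid index
# arithmetic (window partition, cyclic shift, shifted-window masks).
#
# Token grids are stored row-major: the token at grid position (r, c) of an
# h x w grid is row (r-1)*w + c of the token matrix.  A batch of B samples
# stacks the B token blocks vertically.

# ---- parameter initialisation ---------------------------------------------

trunc_normal <- function(nr, nc, sd = 0.02) {
  x <- stats::rnorm(nr * nc, 0, sd)
  x <- pmin(pmax(x, -2 * sd), 2 * sd)
  matrix(x, nr, nc)
}

p_linear <- function(din, dout, bias = TRUE) {
  list(W = ag_param(trunc_normal(din, dout)),
       b = if (bias) ag_param(matrix(0, 1L, dout)) else NULL)
}

p_ln <- function(d) {
  list(gamma = ag_param(matrix(1, 1L, d)), beta = ag_param(matrix(0, 1L, d)))
}

lin_fwd <- function(x, p) ag_linear(x, p$W, p$b)
ln_fwd <- function(x, p) ag_layernorm(x, p$gamma, p$beta)

# ---- configuration ---------------------------------------------------------

#' Attention/block configuration
#'
#' Describes one self-attention family instance: channel width, head count,
#' window geometry for windowed attention, spatial-reduction factor for SRA,
#' and the MLP expansion ratio of the enclosing transformer block.
#'
#' @param dim channel width `c`; must be divisible by `n_heads`.
#' @param n_heads number of attention heads.
#' @param window side length of the (square) attention window for W-MSA.
#' @param shift cyclic shift offset for SW-MSA; must be `< window`.
#' @param sr_ratio spatial-reduction factor for SRA keys/values (1 = none).
#' @param mlp_ratio hidden-width expansion ratio `E` of the block MLP.
#' @param attn_scale `"inv_sqrt_d"` (default) scales attention scores by
#'   `1/sqrt(head_dim)`; `"inv_d"` uses the literal `1/head_dim`.
#' @param dropout residual dropout rate applied (during training only) to the
#'   attention and MLP branch outputs; 0 disables.
#' @return a list with class `"attention_config"`.
#' @export
attention_config <- function(dim, n_heads, window = 8L, shift = NULL,
                             sr_ratio = 1L, mlp_ratio = 4,
                             attn_scale = c("inv_sqrt_d", "inv_d"),
                             dropout = 0) {
  attn_scale <- match.arg(attn_scale)
  if (dim %% n_heads != 0L)
    stop("dim (", dim, ") must be divisible by n_heads (", n_heads, ")")
  if (is.null(shift)) shift <- window %/% 2L
  if (shift >= window) stop("shift must be smaller than window")
  structure(list(dim = as.integer(dim), n_heads = as.integer(n_heads),
                 head_dim = as.integer(dim %/% n_heads),
                 window = as.integer(window), shift = as.integer(shift),
                 sr_ratio = as.integer(sr_ratio), mlp_ratio = mlp_ratio,
                 attn_scale = attn_scale, dropout = dropout),
            class = "attention_config")
}

attn_scale_val <- function(cfg) {
  if (cfg$attn_scale == "inv_d") 1 / cfg$head_dim else 1 / sqrt(cfg$head_dim)
}

head_cols <- function(cfg, h) ((h - 1L) * cfg$head_dim + 1L):(h * cfg$head_dim)

# ---- grid index arithmetic -------------------------------------------------

grid_index <- function(h, w) matrix(seq_len(h * w), h, w, byrow = TRUE)

# window-major ordering of grid tokens: idx[j] = grid row of the j-th token
# in window order (windows row-major; tokens row-major within a window)
win_partition_idx <- function(h, w, win) {
  g <- grid_index(h, w)
  idx <- integer(h * w)
  k <- 0L
  for (wi in seq_len(h %/% win)) for (wj in seq_len(w %/% win)) {
    rows <- ((wi - 1L) * win + 1L):(wi * win)
    cols <- ((wj - 1L) * win + 1L):(wj * win)
    blk <- t(g[rows, cols, drop = FALSE])  # row-major within window
    idx[(k + 1L):(k + win * win)] <- as.vector(blk)
    k <- k + win * win
  }
  idx
}

# cyclic shift by s (toward the origin, as in shifted-window attention):
# output position (r, c) reads source ((r-1+s) %% h + 1, (c-1+s) %% w + 1)
roll_idx <- function(h, w, s) {
  r <- rep(seq_len(h), each = w)
  c <- rep(seq_len(w), times = h)
  sr <- (r - 1L + s) %% h + 1L
  sc <- (c - 1L + s) %% w + 1L
  (sr - 1L) * w + sc
}

inverse_perm <- function(idx) {
  inv <- integer(length(idx))
  inv[idx] <- seq_along(idx)
  inv
}

# relative-position-bias index map: (win^2 x win^2) of indices into the
# (2*win-1)^2 bias table, equal relative offsets sharing one entry
relpos_index <- function(win) {
  r <- rep(seq_len(win), each = win)
  c <- rep(seq_len(win), times = win)
  dr <- outer(r, r, "-") + win - 1L
  dc <- outer(c, c, "-") + win - 1L
  dr * (2L * win - 1L) + dc + 1L
}

# additive mask for shifted-window attention: wrapped token pairs are pushed
# to -1e9.  Returns (nwin*win^2) x win^2, window-major row order.
swin_mask <- function(h, w, win, s) {
  bounds <- function(n) list(c(1L, n - win), c(n - win + 1L, n - s), c(n - s + 1L, n))
  id <- matrix(0L, h, w)
  cnt <- 0L
  for (rb in bounds(h)) for (cb in bounds(w)) {
    if (rb[1L] > rb[2L] || cb[1L] > cb[2L]) next
    id[rb[1L]:rb[2L], cb[1L]:cb[2L]] <- cnt
    cnt <- cnt + 1L
  }
  ids <- as.vector(t(id))[win_partition_idx(h, w, win)]
  nwin <- (h %/% win) * (w %/% win)
  n2 <- win * win
  out <- matrix(0, nwin * n2, n2)
  for (g in seq_len(nwin)) {
    wid <- ids[((g - 1L) * n2 + 1L):(g * n2)]
    out[((g - 1L) * n2 + 1L):(g * n2), ] <- ifelse(outer(wid, wid, "!="), -1e9, 0)
  }
  out
}

# replicate a per-sample row index across a batch of B stacked samples
idx_batch <- function(idx, B, n) {
  if (B == 1L) return(idx)
  as.integer(outer(idx, (seq_len(B) - 1L) * n, "+"))
}

# ---- attention layer parameters -------------------------------------------

#' Create parameters for one attention layer
#'
#' @param cfg an [attention_config()].
#' @param type one of `"msa"`, `"wmsa"`, `"sra"`; `"wmsa"` adds a relative
#'   position bias table, `"sra"` (with `sr_ratio > 1`) adds the strided
#'   reduction projection for keys/values.
#' @param seed optional integer; when given, initialisation is done under this
#'   seed without disturbing the caller's RNG state.
#' @return list of parameter nodes.
#' @export
attn_layer <- function(cfg, type = c("msa", "wmsa", "sra"), seed = NULL) {
  type <- match.arg(type)
  make <- function() {
    p <- list(q = p_linear(cfg$dim, cfg$dim), k = p_linear(cfg$dim, cfg$dim),
              v = p_linear(cfg$dim, cfg$dim), o = p_linear(cfg$dim, cfg$dim))
    if (type == "wmsa") {
      p$relpos <- ag_param(trunc_normal((2L * cfg$window - 1L)^2, cfg$n_heads))
    }
    if (type == "sra" && cfg$sr_ratio > 1L) {
      p$red <- p_linear(cfg$sr_ratio^2 * cfg$dim, cfg$dim)
      p$red_ln <- p_ln(cfg$dim)
    }
    p
  }
  if (is.null(seed)) make() else with_seed(seed, make())
}

# ---- attention forwards (on nodes) ----------------------------------------

# plain multi-head self-attention; x: (B*n) x dim node
msa_node <- function(x, p, cfg, B, n) {
  q <- lin_fwd(x, p$q); k <- lin_fwd(x, p$k); v <- lin_fwd(x, p$v)
  sc <- attn_scale_val(cfg)
  heads <- lapply(seq_len(cfg$n_heads), function(hh) {
    cols <- head_cols(cfg, hh)
    ag_attention(ag_slice_cols(q, cols), ag_slice_cols(k, cols),
                 ag_slice_cols(v, cols), nq = n, nk = n, scale = sc)
  })
  lin_fwd(ag_cbind(heads), p$o)
}

# windowed multi-head self-attention (optionally shifted) with relative
# position bias; degenerates to unshifted when the window equals the grid
wmsa_node <- function(x, p, cfg, B, h, w, shifted = FALSE) {
  win <- cfg$window
  if (h %% win != 0L || w %% win != 0L)
    stop("window (", win, ") must divide the grid (", h, "x", w,
         "); pad the grid to a multiple of the window")
  s <- if (shifted && win < min(h, w)) cfg$shift else 0L
  n <- h * w
  q <- lin_fwd(x, p$q); k <- lin_fwd(x, p$k); v <- lin_fwd(x, p$v)
  part <- win_partition_idx(h, w, win)
  perm <- if (s > 0L) roll_idx(h, w, s)[part] else part
  bidx <- idx_batch(perm, B, n)
  qp <- ag_gather_rows(q, bidx)
  kp <- ag_gather_rows(k, bidx)
  vp <- ag_gather_rows(v, bidx)
  mask <- NULL
  if (s > 0L) {
    m1 <- swin_mask(h, w, win, s)
    mask <- do.call(rbind, rep(list(m1), B))
  }
  ridx <- relpos_index(win)
  rgath <- ag_gather_rows(p$relpos, as.vector(ridx))
  sc <- attn_scale_val(cfg)
  n2 <- win * win
  heads <- lapply(seq_len(cfg$n_heads), function(hh) {
    cols <- head_cols(cfg, hh)
    bias <- ag_reshape(ag_slice_cols(rgath, hh), n2, n2)
    ag_attention(ag_slice_cols(qp, cols), ag_slice_cols(kp, cols),
                 ag_slice_cols(vp, cols), nq = n2, nk = n2, scale = sc,
                 bias = bias, mask = mask)
  })
  merged <- ag_cbind(heads)
  out <- ag_gather_rows(merged, idx_batch(inverse_perm(perm), B, n))
  lin_fwd(out, p$o)
}

# spatial-reduction attention: queries at full resolution, keys/values from a
# strided sr x sr patch-merge projection of the grid (skipped when sr == 1)
sra_node <- function(x, p, cfg, B, h, w) {
  sr <- cfg$sr_ratio
  if (h %% sr != 0L || w %% sr != 0L)
    stop("sr_ratio (", sr, ") must divide the grid (", h, "x", w, ")")
  n <- h * w
  q <- lin_fwd(x, p$q)
  if (sr > 1L) {
    red <- unfold_node(x, h, w, sr, B)
    red <- lin_fwd(red, p$red)
    red <- ln_fwd(red, p$red_ln)
    nk <- (h %/% sr) * (w %/% sr)
    k <- lin_fwd(red, p$k); v <- lin_fwd(red, p$v)
  } else {
    nk <- n
    k <- lin_fwd(x, p$k); v <- lin_fwd(x, p$v)
  }
  sc <- attn_scale_val(cfg)
  heads <- lapply(seq_len(cfg$n_heads), function(hh) {
    cols <- head_cols(cfg, hh)
    ag_attention(ag_slice_cols(q, cols), ag_slice_cols(k, cols),
                 ag_slice_cols(v, cols), nq = n, nk = nk, scale = sc)
  })
  lin_fwd(ag_cbind(heads), p$o)
}

# non-overlapping sxs neighbourhood concatenation ("unfold"): (B*h*w) x c ->
# (B*(h/s)*(w/s)) x (s^2 c), neighbourhood scanned row-major
unfold_node <- function(x, h, w, s, B) {
  g <- grid_index(h, w)
  n <- h * w
  parts <- vector("list", s * s)
  k <- 0L
  for (dr in seq_len(s)) for (dc in seq_len(s)) {
    k <- k + 1L
    rows <- seq.int(dr, h, by = s)
    cols <- seq.int(dc, w, by = s)
    idx <- as.vector(t(g[rows, cols, drop = FALSE]))
    parts[[k]] <- ag_gather_rows(x, idx_batch(idx, B, n))
  }
  ag_cbind(parts)
}

# ---- block parameter sets and forwards ------------------------------------

p_mlp <- function(dim, ratio) {
  hidden <- as.integer(round(dim * ratio))
  list(fc1 = p_linear(dim, hidden), fc2 = p_linear(hidden, dim))
}

mlp_fwd <- function(x, p) lin_fwd(ag_gelu(lin_fwd(x, p$fc1)), p$fc2)

p_global_block <- function(cfg) {
  list(ln1 = p_ln(cfg$dim), att = attn_layer(cfg, "msa"),
       ln2 = p_ln(cfg$dim), mlp = p_mlp(cfg$dim, cfg$mlp_ratio))
}

# x -> x + MSA(LN(x)) -> + MLP(LN(.)); residual dropout during training
global_block_node <- function(x, p, cfg, B, n, training = FALSE) {
  drop <- function(nd) ag_dropout(nd, cfg$dropout, training)
  y <- ag_add(x, drop(msa_node(ln_fwd(x, p$ln1), p$att, cfg, B, n)))
  ag_add(y, drop(mlp_fwd(ln_fwd(y, p$ln2), p$mlp)))
}

p_local_block <- function(cfg) {
  list(ln1 = p_ln(cfg$dim), att1 = attn_layer(cfg, "wmsa"),
       ln2 = p_ln(cfg$dim), mlp1 = p_mlp(cfg$dim, cfg$mlp_ratio),
       ln3 = p_ln(cfg$dim), att2 = attn_layer(cfg, "wmsa"),
       ln4 = p_ln(cfg$dim), mlp2 = p_mlp(cfg$dim, cfg$mlp_ratio))
}

# two successive windowed blocks: W-MSA -> MLP -> SW-MSA -> MLP, pre-norm
local_block_node <- function(x, p, cfg, B, h, w) {
  y <- ag_add(x, wmsa_node(ln_fwd(x, p$ln1), p$att1, cfg, B, h, w, shifted = FALSE))
  y <- ag_add(y, mlp_fwd(ln_fwd(y, p$ln2), p$mlp1))
  z <- ag_add(y, wmsa_node(ln_fwd(y, p$ln3), p$att2, cfg, B, h, w, shifted = TRUE))
  ag_add(z, mlp_fwd(ln_fwd(z, p$ln4), p$mlp2))
}

# ---- exported numeric wrappers --------------------------------------------

#' Scaled dot-product attention
#'
#' Computes `softmax(Q K' * scale + R) V` for a single attention group.  The
#' attention probability matrix is attached as attribute `"probs"`.
#'
#' @param Q,K,V numeric matrices (`n x d`, `m x d`, `m x d`).
#' @param R optional additive bias matrix (`n x m`), e.g. a relative position
#'   bias; `NULL` means zero.
#' @param scale score scale; defaults to `1/sqrt(ncol(Q))`.
#' @return `n x d` output matrix with attribute `"probs"`.
#' @examples
#' Q <- matrix(0, 2, 1); K <- matrix(0, 2, 1); V <- matrix(c(1, 2), 2, 1)
#' scaled_attention(Q, K, V)  # uniform attention: both rows 1.5
#' @export
scaled_attention <- function(Q, K, V, R = NULL, scale = 1 / sqrt(ncol(Q))) {
  for (m in list(Q, K, V)) {
    if (anyNA(m) || any(!is.finite(m))) stop("attention inputs contain NaN or Inf")
  }
  stopifnot(ncol(Q) == ncol(K), nrow(K) == nrow(V))
  bias <- if (is.null(R)) matrix(numeric(0), 0L, 0L) else R
  fw <- attn_forward_cpp(Q, K, V, nrow(Q), nrow(K), scale, bias,
                         matrix(numeric(0), 0L, 0L))
  structure(fw$out, probs = fw$probs)
}

#' Single-sample attention block forward passes
#'
#' Numeric-in/numeric-out wrappers around the internal graph builders, for a
#' single token grid.  `x` is the `(h*w) x dim` token matrix; `params` comes
#' from [attn_layer()] (for `msa_forward`, `wmsa_forward`, `sra_forward`) or
#' from [block_layer()] (for the block forms).
#'
#' @param x numeric token matrix, rows in row-major grid order.
#' @param params parameter list.
#' @param cfg an [attention_config()].
#' @param h,w grid shape (`h*w == nrow(x)`).
#' @param shifted use the shifted-window variant (W-MSA vs SW-MSA).
#' @return numeric matrix of the same shape as `x`.
#' @name attention-forwards
NULL

#' @rdname attention-forwards
#' @export
msa_forward <- function(x, params, cfg) {
  msa_node(ag_const(x), params, cfg, 1L, nrow(x))$value
}

#' @rdname attention-forwards
#' @export
wmsa_forward <- function(x, params, cfg, h, w, shifted = FALSE) {
  wmsa_node(ag_const(x), params, cfg, 1L, h, w, shifted = shifted)$value
}

#' @rdname attention-forwards
#' @export
sra_forward <- function(x, params, cfg, h, w) {
  sra_node(ag_const(x), params, cfg, 1L, h, w)$value
}

#' Create parameters for a full transformer block
#'
#' @param cfg an [attention_config()].
#' @param type `"global"` (MSA block) or `"local"` (two successive windowed
#'   blocks with shifted windows).
#' @param seed optional initialisation seed.
#' @return parameter list for [global_block_forward()] / [local_block_forward()].
#' @export
block_layer <- function(cfg, type = c("global", "local"), seed = NULL) {
  type <- match.arg(type)
  make <- function() if (type == "global") p_global_block(cfg) else p_local_block(cfg)
  if (is.null(seed)) make() else with_seed(seed, make())
}

#' @rdname attention-forwards
#' @export
global_block_forward <- function(x, params, cfg) {
  global_block_node(ag_const(x), params, cfg, 1L, nrow(x))$value
}

#' @rdname attention-forwards
#' @export
local_block_forward <- function(x, params, cfg, h, w) {
  local_block_node(ag_const(x), params, cfg, 1L, h, w)$value
}

# ---- misc ------------------------------------------------------------------

# evaluate `expr` under `seed` without disturbing the caller's RNG stream
with_seed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# collect every ag_param node from a nested parameter list
collect_params <- function(p) {
  out <- list()
  rec <- function(x) {
    if (is_node(x)) {
      if (isTRUE(x$is_param)) out[[length(out) + 1L]] <<- x
    } else if (is.list(x)) {
      for (el in x) rec(el)
    }
  }
  rec(p)
  out
}
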