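# Cross-correlation attention module (CAM).
#
# Three same-shape scale features A (global branch), B (local branch) and
# C (aggregation branch) are stacked into G = [A, B, C].  A shared 1x1
# convolution produces spatial-level features f1; the per-position channel
# inner product between each scale slice of f1 and the (un-convolved)
# aggregation feature f2 = C, squashed by a sigmoid, yields one spatial
# attention map per scale.  Each scale's raw slice of G is re-weighted by its
# map, the three are concatenated channel-wise, and a 3x3 convolution fuses
# them back to c channels.
#
# Channel-major layout (c x hw, the printed convention) is used at the API
# surface; internally tokens are rows.

# zero-padded 3x3 neighbourhood indices for a row-major h x w grid; one index
# vector per kernel offset, offsets scanned row-major (-1,-1) .. (1,1);
# 0 marks an out-of-bounds (zero) neighbour
pad_conv_idx <- function(h, w) {
  r <- rep(seq_len(h), each = w)
  c <- rep(seq_len(w), times = h)
  out <- vector("list", 9L)
  k <- 0L
  for (dr in -1:1) for (dc in -1:1) {
    k <- k + 1L
    rr <- r + dr
    cc <- c + dc
    ok <- rr >= 1L & rr <= h & cc >= 1L & cc <= w
    idx <- integer(h * w)
    idx[ok] <- (rr[ok] - 1L) * w + cc[ok]
    out[[k]] <- idx
  }
  out
}

# batch-tile a padded index (0 stays 0)
idx_batch0 <- function(idx, B, n) {
  if (B == 1L) return(idx)
  unlist(lapply(seq_len(B) - 1L, function(b) ifelse(idx > 0L, idx + b * n, 0L)),
         use.names = FALSE)
}

#' Create CAM parameters
#'
#' The 1x1 convolution (`c -> c`) is shared across the three scale slices by
#' default; `share_conv1 = FALSE` gives each scale its own weights.  The 3x3
#' fusion convolution maps `3c -> c` with padding 1.  Its weight matrix is
#' stored as `(9*3c) x c`: rows are ordered kernel-offset-major (offsets
#' `(-1,-1), (-1,0), ..., (1,1)` row-major), and within one offset the `3c`
#' input channels are ordered `[A | B | C]`.
#'
#' @param channels channel width `c` of each scale feature.
#' @param seed optional initialisation seed.
#' @param share_conv1 share 1x1-convolution weights across scales (default).
#' @return parameter list of class `"cam_params"`.
#' @export
cam_layer <- function(channels, seed = NULL, share_conv1 = TRUE) {
  make <- function() {
    p <- list(channels = as.integer(channels), share_conv1 = share_conv1,
              conv3 = p_linear(9L * 3L * channels, channels))
    if (share_conv1) {
      p$conv1 <- p_linear(channels, channels)
    } else {
      p$conv1_a <- p_linear(channels, channels)
      p$conv1_b <- p_linear(channels, channels)
      p$conv1_c <- p_linear(channels, channels)
    }
    structure(p, class = "cam_params")
  }
  if (is.null(seed)) make() else with_seed(seed, make())
}

# graph version; A/B/C: ((Bz*h*w) x c) nodes in token layout
cam_node <- function(A, B, C, p, Bz, h, w) {
  c1 <- function(x, which) {
    if (p$share_conv1) lin_fwd(x, p$conv1)
    else lin_fwd(x, p[[paste0("conv1_", which)]])
  }
  f1a <- c1(A, "a"); f1b <- c1(B, "b"); f1c <- c1(C, "c")
  atta <- ag_sigmoid(ag_rowsum(ag_mul(f1a, C)))
  attb <- ag_sigmoid(ag_rowsum(ag_mul(f1b, C)))
  attc <- ag_sigmoid(ag_rowsum(ag_mul(f1c, C)))
  cat3 <- ag_cbind(list(ag_mul_bcast(A, atta),
                        ag_mul_bcast(B, attb),
                        ag_mul_bcast(C, attc)))
  n <- h * w
  nb <- pad_conv_idx(h, w)
  cols <- lapply(nb, function(idx) ag_gather_rows(cat3, idx_batch0(idx, Bz, n)))
  out <- lin_fwd(ag_cbind(cols), p$conv3)
  list(out = out, att = list(A = atta, B = attb, C = attc))
}

#' CAM forward pass
#'
#' @param A,B,C numeric `c x (h*w)` scale features (channel-major, positions
#'   scanned row-major over the `h x w` grid).
#' @param params a [cam_layer()] parameter set.
#' @param h,w grid shape.
#' @return fused feature `c x (h*w)`, with attribute `"att"`: the `3 x (h*w)`
#'   matrix of sigmoid attention maps (rows A, B, C), all entries in (0, 1).
#' @export
cam_forward <- function(A, B, C, params, h, w) {
  if (!all(dim(A) == dim(B)) || !all(dim(A) == dim(C)))
    stop("A, B and C must have identical shapes")
  if (ncol(A) != h * w)
    stop("expected ", h * w, " spatial positions, got ", ncol(A))
  res <- cam_node(ag_const(t(A)), ag_const(t(B)), ag_const(t(C)),
                  params, 1L, h, w)
  att <- rbind(A = res$att$A$value[, 1L], B = res$att$B$value[, 1L],
               C = res$att$C$value[, 1L])
  structure(t(res$out$value), att = att)
}

#' CAM reference oracle
#'
#' Identical contract to [cam_forward()], computed with explicit nested loops
#' over scales, channels and spatial positions (no batched linear algebra).
#' Serves as the independent equivalence oracle for the vectorised path.
#'
#' @inheritParams cam_forward
#' @return fused feature `c x (h*w)` with attribute `"att"` as in
#'   [cam_forward()].
#' @export
cam_oracle <- function(A, B, C, params, h, w) {
  if (!all(dim(A) == dim(B)) || !all(dim(A) == dim(C)))
    stop("A, B and C must have identical shapes")
  cc <- nrow(A)
  n <- h * w
  X <- list(A, B, C)
  W1 <- function(s) {
    if (params$share_conv1) params$conv1
    else params[[c("conv1_a", "conv1_b", "conv1_c")[s]]]
  }
  f1 <- lapply(1:3, function(s) {
    W <- W1(s)$W$value; b <- W1(s)$b$value[1L, ]
    out <- matrix(0, cc, n)
    for (ch in seq_len(cc)) for (t in seq_len(n)) {
      acc <- b[ch]
      for (i in seq_len(cc)) acc <- acc + W[i, ch] * X[[s]][i, t]
      out[ch, t] <- acc
    }
    out
  })
  att <- matrix(0, 3L, n)
  for (s in 1:3) for (t in seq_len(n)) {
    acc <- 0
    for (ch in seq_len(cc)) acc <- acc + f1[[s]][ch, t] * C[ch, t]
    att[s, t] <- 1 / (1 + exp(-acc))
  }
  ecat <- matrix(0, 3L * cc, n)
  for (s in 1:3) for (ch in seq_len(cc)) for (t in seq_len(n)) {
    ecat[(s - 1L) * cc + ch, t] <- att[s, t] * X[[s]][ch, t]
  }
  W3 <- params$conv3$W$value
  b3 <- params$conv3$b$value[1L, ]
  out <- matrix(0, cc, n)
  offs <- expand.grid(dc = -1:1, dr = -1:1)[, c("dr", "dc")]  # row-major order
  for (ch in seq_len(cc)) {
    for (r in seq_len(h)) for (cl in seq_len(w)) {
      t <- (r - 1L) * w + cl
      acc <- b3[ch]
      for (k in 1:9) {
        rr <- r + offs$dr[k]; cw <- cl + offs$dc[k]
        if (rr < 1L || rr > h || cw < 1L || cw > w) next
        tt <- (rr - 1L) * w + cw
        for (j in seq_len(3L * cc)) {
          acc <- acc + W3[(k - 1L) * 3L * cc + j, ch] * ecat[j, tt]
        }
      }
      out[ch, t] <- acc
    }
  }
  rownames(att) <- c("A", "B", "C")
  structure(out, att = att)
}
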