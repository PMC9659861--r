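# Self-attention families: scaled attention, MSA, W-MSA/SW-MSA, SRA, and the
# pre-norm block compositions.

test_that("scaled attention matches hand-computed cases", {
  # zero scores: uniform attention averages the values
  V <- matrix(c(1, 2, 3, 4, 5, 6), 3, 2)
  out <- scaled_attention(matrix(0, 3, 2), matrix(0, 3, 2), V)
  expect_equal(out, matrix(rep(colMeans(V), each = 3), 3, 2),
               ignore_attr = TRUE)

  # n=2, d=1 hand softmax
  out <- scaled_attention(matrix(c(1, 0), 2, 1), matrix(c(1, 0), 2, 1),
                          matrix(c(1, 2), 2, 1), scale = 1)
  expect_equal(out[1, 1], (exp(1) * 1 + exp(0) * 2) / (exp(1) + exp(0)),
               tolerance = 1e-6)
  expect_equal(out[2, 1], 1.5)

  # strong negative off-diagonal bias: attention collapses to self
  set.seed(1)
  V <- matrix(rnorm(8), 4, 2)
  R <- matrix(-1e9, 4, 4); diag(R) <- 0
  out <- scaled_attention(matrix(rnorm(8), 4, 2), matrix(rnorm(8), 4, 2), V, R)
  expect_equal(out, V, tolerance = 1e-6, ignore_attr = TRUE)
})

test_that("attention probabilities are rows of a stochastic matrix", {
  set.seed(7)
  for (i in 1:5) {
    out <- scaled_attention(matrix(rnorm(24), 6, 4), matrix(rnorm(24), 6, 4),
                            matrix(rnorm(24), 6, 4))
    expect_true(all(abs(rowSums(attr(out, "probs")) - 1) < 1e-6))
  }
})

test_that("non-finite attention inputs are rejected", {
  Q <- matrix(c(NA, 0), 1, 2)
  expect_error(scaled_attention(Q, matrix(0, 1, 2), matrix(0, 1, 2)),
               "NaN or Inf")
})

test_that("MSA preserves shape and known degenerate forms", {
  cfg <- attention_config(dim = 8, n_heads = 2)
  p <- attn_layer(cfg, "msa", seed = 2)
  set.seed(3)
  x <- matrix(rnorm(16 * 8), 16, 8)
  out <- msa_forward(x, p, cfg)
  expect_equal(dim(out), dim(x))

  # zero value projection: output is the output-projection bias everywhere
  p0 <- attn_layer(cfg, "msa", seed = 2)
  p0$v$W$value[] <- 0; p0$v$b$value[] <- 0
  p0$o$b$value[] <- seq_len(8)
  out0 <- msa_forward(x, p0, cfg)
  expect_equal(out0, matrix(rep(1:8, each = 16), 16, 8))

  # single token: attention is the identity weighting, out = proj(V)
  x1 <- matrix(rnorm(8), 1, 8)
  v <- x1 %*% p$v$W$value + p$v$b$value
  expect_equal(msa_forward(x1, p, cfg),
               v %*% p$o$W$value + p$o$b$value, tolerance = 1e-10)
})

test_that("MSA without positional information is permutation equivariant", {
  cfg <- attention_config(dim = 12, n_heads = 3)
  p <- attn_layer(cfg, "msa", seed = 4)
  set.seed(5)
  x <- matrix(rnorm(9 * 12), 9, 12)
  perm <- sample(9)
  y <- msa_forward(x, p, cfg)
  y_perm <- msa_forward(x[perm, ], p, cfg)
  expect_lt(max(abs(y[perm, ] - y_perm)), 1e-5)
})

test_that("W-MSA with full-grid window and zero bias equals MSA", {
  cfg <- attention_config(dim = 16, n_heads = 4, window = 4)
  p <- attn_layer(cfg, "wmsa", seed = 6)
  p$relpos$value[] <- 0
  set.seed(7)
  x <- matrix(rnorm(16 * 16), 16, 16)
  expect_lt(max(abs(wmsa_forward(x, p, cfg, 4, 4) - msa_forward(x, p, cfg))),
            1e-5)
})

test_that("windowed attention is local and shares bias across windows", {
  cfg <- attention_config(dim = 8, n_heads = 2, window = 2)
  p <- attn_layer(cfg, "wmsa", seed = 8)
  set.seed(9)
  x <- matrix(rnorm(16 * 8), 16, 8)      # 4x4 grid, 4 windows
  base <- wmsa_forward(x, p, cfg, 4, 4)

  # tokens constant within each window -> output constant within each window
  part <- ns$win_partition_idx(4L, 4L, 2L)
  xc <- x
  for (g in 1:4) xc[part[((g - 1) * 4 + 1):(g * 4)], ] <-
    matrix(rep(rnorm(8), each = 4), 4, 8)
  outc <- wmsa_forward(xc, p, cfg, 4, 4)
  for (g in 1:4) {
    rows <- part[((g - 1) * 4 + 1):(g * 4)]
    expect_lt(max(abs(sweep(outc[rows, ], 2, outc[rows[1], ]))), 1e-10)
  }

  # locality: zeroing one window leaves all other windows' outputs unchanged
  xz <- x
  xz[part[1:4], ] <- 0
  outz <- wmsa_forward(xz, p, cfg, 4, 4)
  expect_equal(outz[part[5:16], ], base[part[5:16], ], tolerance = 1e-12)

  # swapping two windows' contents swaps their outputs exactly
  xs <- x
  xs[part[1:4], ] <- x[part[5:8], ]
  xs[part[5:8], ] <- x[part[1:4], ]
  outs <- wmsa_forward(xs, p, cfg, 4, 4)
  expect_equal(outs[part[1:4], ], base[part[5:8], ], tolerance = 1e-12)
  expect_equal(outs[part[5:8], ], base[part[1:4], ], tolerance = 1e-12)
})

test_that("window size must divide the grid", {
  cfg <- attention_config(dim = 8, n_heads = 2, window = 3, shift = 1)
  p <- attn_layer(cfg, "wmsa", seed = 1)
  x <- matrix(rnorm(16 * 8), 16, 8)
  expect_error(wmsa_forward(x, p, cfg, 4, 4), "pad")
})

test_that("the shifted-window pass moves information across windows", {
  cfg <- attention_config(dim = 8, n_heads = 2, window = 2, mlp_ratio = 2)
  p <- block_layer(cfg, "local", seed = 11)
  set.seed(12)
  x <- matrix(rnorm(16 * 8), 16, 8)
  shifted <- local_block_forward(x, p, cfg, 4, 4)
  # same composition but with the second attention unshifted
  unshifted <- local({
    xn <- ns$ag_const(x)
    y <- ns$ag_add(xn, ns$wmsa_node(ns$ln_fwd(xn, p$ln1), p$att1, cfg, 1L, 4L, 4L,
                                    shifted = FALSE))
    y <- ns$ag_add(y, ns$mlp_fwd(ns$ln_fwd(y, p$ln2), p$mlp1))
    z <- ns$ag_add(y, ns$wmsa_node(ns$ln_fwd(y, p$ln3), p$att2, cfg, 1L, 4L, 4L,
                                   shifted = FALSE))
    ns$ag_add(z, ns$mlp_fwd(ns$ln_fwd(z, p$ln4), p$mlp2))$value
  })
  expect_gt(max(abs(shifted - unshifted)), 1e-4)
})

test_that("residual blocks with zeroed branch weights are identity maps", {
  cfg <- attention_config(dim = 8, n_heads = 2, window = 2, mlp_ratio = 2)
  zero_branch <- function(p) {
    for (q in ns$collect_params(p)) q$value[] <- 0
    p
  }
  set.seed(13)
  x <- matrix(rnorm(16 * 8), 16, 8)
  pg <- zero_branch(block_layer(cfg, "global", seed = 1))
  expect_equal(global_block_forward(x, pg, cfg), x)
  pl <- zero_branch(block_layer(cfg, "local", seed = 1))
  expect_equal(local_block_forward(x, pl, cfg, 4, 4), x)
})

test_that("SRA with ratio 1 equals MSA; reduction shrinks the key grid", {
  cfg <- attention_config(dim = 16, n_heads = 4, sr_ratio = 1)
  p <- attn_layer(cfg, "sra", seed = 14)
  set.seed(15)
  x <- matrix(rnorm(16 * 16), 16, 16)
  expect_lt(max(abs(sra_forward(x, p, cfg, 4, 4) - msa_forward(x, p, cfg))), 1e-5)

  # 32x32 grid at ratio 8 reduces keys/values to a 4x4 = 16-token grid
  red <- ns$unfold_node(ns$ag_const(matrix(rnorm(1024 * 4), 1024, 4)),
                        32L, 32L, 8L, 1L)
  expect_equal(nrow(red$value), 16L)

  cfg2 <- attention_config(dim = 16, n_heads = 4, sr_ratio = 2)
  p2 <- attn_layer(cfg2, "sra", seed = 16)
  out <- sra_forward(x, p2, cfg2, 4, 4)
  expect_equal(dim(out), dim(x))
  expect_error(sra_forward(x, p2, cfg2, 3, 3), "divide")
})

test_that("blocks stay finite for inputs in [-10, 10] at full-scale widths", {
  set.seed(17)
  for (dims in list(c(128L, 2L), c(256L, 4L), c(512L, 8L))) {
    cfg <- attention_config(dim = dims[1L], n_heads = dims[2L], window = 2,
                            mlp_ratio = 4)
    p <- block_layer(cfg, "global", seed = dims[1L])
    x <- matrix(stats::runif(16 * dims[1L], -10, 10), 16, dims[1L])
    expect_false(any(!is.finite(global_block_forward(x, p, cfg))))
  }
})

test_that("analytic gradients of a transformer block match finite differences", {
  cfg <- attention_config(dim = 8, n_heads = 2, mlp_ratio = 2)
  p <- block_layer(cfg, "global", seed = 3)
  set.seed(1)
  x <- matrix(rnorm(32), 4, 8)
  wmat <- matrix(rnorm(32), 4, 8)
  loss_of <- function() {
    sum(ns$global_block_node(ns$ag_const(x), p, cfg, 1L, 4L)$value * wmat)
  }
  plist <- ns$collect_params(p)
  ns$ag_zero_grads(plist)
  nd <- ns$global_block_node(ns$ag_const(x), p, cfg, 1L, 4L)
  loss <- ns$ag_node(matrix(sum(nd$value * wmat), 1, 1), list(nd),
                     function(g) list(g[1, 1] * wmat))
  ns$ag_backward(loss)
  for (pp in plist) {
    expect_false(is.null(pp$grad))
    for (k in sample(length(pp$value), min(3L, length(pp$value)))) {
      eps <- 1e-5
      v0 <- pp$value[k]
      pp$value[k] <- v0 + eps; lp <- loss_of()
      pp$value[k] <- v0 - eps; lm <- loss_of()
      pp$value[k] <- v0
      fd <- (lp - lm) / (2 * eps)
      expect_lt(abs(fd - pp$grad[k]) / max(1e-6, abs(fd), abs(pp$grad[k])),
                1e-4)
    }
  }
})

test_that("attention configuration invariants are enforced", {
  expect_error(attention_config(dim = 10, n_heads = 3), "divisible")
  expect_error(attention_config(dim = 8, n_heads = 2, window = 4, shift = 4),
               "shift")
  cfg <- attention_config(dim = 8, n_heads = 2, attn_scale = "inv_d")
  expect_equal(ns$attn_scale_val(cfg), 1 / 4)
})
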