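# CAST assembly: patch embedding, patch merging, branch wiring, ablations,
# classifier head and slide embedding.

test_that("patch embedding follows the stage-1 shape contracts", {
  # 256^2 x 3 with P=8 -> 32^2 tokens (weights at desk width to stay cheap)
  pe <- patch_embed_layer(8L, 16L, seed = 1)
  img <- array(stats::runif(256 * 256 * 3), c(256L, 256L, 3L))
  expect_equal(dim(patch_embed(img, 8L, pe)), c(1024L, 16L))

  pe2 <- patch_embed_layer(2L, 16L, seed = 2)
  img2 <- array(stats::runif(64 * 64 * 3), c(64L, 64L, 3L))
  expect_equal(dim(patch_embed(img2, 2L, pe2)), c(1024L, 16L))

  # P=1 with identity projection: tokens are the pixels
  ident <- list(W = diag(3), b = NULL)
  img3 <- array(stats::runif(4 * 4 * 3), c(4L, 4L, 3L))
  tokens <- patch_embed(img3, 1L, ident)
  expect_equal(tokens[2L, ], img3[1L, 2L, ])   # row-major token order
  expect_error(patch_embed(img3, 3L, ident), "divide")
})

test_that("patch merging halves the grid and projects channels", {
  set.seed(3)
  x <- matrix(rnorm(1024 * 8), 1024, 8)
  p <- list(W = ns$trunc_normal(32, 16), b = matrix(0, 1, 16))
  expect_equal(dim(stage_downsample(x, 32L, 32L, p)), c(256L, 16L))
  expect_equal(dim(stage_downsample(stage_downsample(x, 32L, 32L, p),
                                    16L, 16L,
                                    list(W = ns$trunc_normal(64, 24), b = NULL))),
               c(64L, 24L))
  # constant grid through an averaging projection stays constant
  xc <- matrix(rep(seq_len(8), each = 16), 16, 8)
  avg <- list(W = rbind(diag(8), diag(8), diag(8), diag(8)) / 4, b = NULL)
  expect_equal(stage_downsample(xc, 4L, 4L, avg), xc[1:4, ])
  expect_error(stage_downsample(x[1:9, ], 3L, 3L, p), "even")
})

test_that("the default configuration reproduces the hierarchical grid plan", {
  cfg <- cast_config()
  expect_equal(cfg$grid_sides, c(32L, 16L, 8L))
  expect_equal(cfg$stage_dims, c(128L, 256L, 512L))
  # tiny profile shares the structure at reduced width
  tcfg <- cast_config_tiny()
  expect_equal(tcfg$grid_sides, c(4L, 2L, 1L))
})

test_that("configuration contract violations are rejected", {
  expect_error(cast_config_tiny(use_fab = FALSE, use_cam = TRUE), "CAM")
  expect_error(cast_config_tiny(stage1_patch = c(ggb = 2L, fab = 2L, lgb = 8L)),
               "disagree")
  expect_error(cast_config_tiny(stage_heads = c(3L, 4L, 8L)), "divisible")
  expect_error(cast_config_tiny(embed_dim_out = 50L), "multiple of 3")
})

test_that("forward pass emits ten logits and the zero-filled embedding contract", {
  tri <- rand_triplet(32L, seed = 4)
  m <- cast_model(cast_config_tiny(), seed = 0)
  fw <- cast_forward(m, tri)
  expect_equal(ncol(fw$logits), 10L)
  expect_equal(dim(fw$embedding), c(1L, 48L))
  expect_equal(unname(rowSums(fw$probs)), 1, tolerance = 1e-6)

  # disabled LGB zero-fills its third of the embedding
  m2 <- cast_model(cast_config_tiny(use_lgb = FALSE, use_cam = FALSE), seed = 0)
  fw2 <- cast_forward(m2, tri)
  expect_equal(fw2$embedding[1L, 33:48], rep(0, 16))
  expect_gt(max(abs(fw2$embedding[1L, 1:32])), 0)

  # FAB-only single-branch variant keeps the output shape
  m3 <- cast_model(cast_config_tiny(use_ggb = FALSE, use_lgb = FALSE,
                                    use_cam = FALSE), seed = 0)
  fw3 <- cast_forward(m3, tri)
  expect_equal(dim(fw3$logits), c(1L, 10L))

  # mismatched image sizes are rejected
  expect_error(cast_forward(m, rand_triplet(16L)), "do not match")
})

test_that("predicted labels use argmax with lowest-index tie-break", {
  expect_equal(predict_label(c(0, 0, 0, 0, 1, 0, 0, 0, 0, 0) * 10), 4L)
  expect_equal(predict_label(rep(0, 10)), 0L)
  tri <- rand_triplet(32L, seed = 5)
  m <- cast_model(cast_config_tiny(), seed = 1)
  fw <- cast_forward(m, tri)
  expect_equal(unname(fw$predicted[1L]), which.max(fw$probs[1L, ]) - 1L)
  expect_error(predict_label(c(1, NA)), "finite")
})

test_that("repeated forward passes are deterministic", {
  tri <- rand_triplet(32L, seed = 6)
  m <- cast_model(cast_config_tiny(), seed = 2)
  expect_identical(cast_forward(m, tri)$logits, cast_forward(m, tri)$logits)
})

test_that("the classification loss reaches all three input stems", {
  m <- cast_model(cast_config_tiny(), seed = 3)
  tri <- rand_triplet(32L, seed = 7)
  plist <- ns$collect_params(m$params)
  ns$ag_zero_grads(plist)
  nd <- ns$cast_forward_node(m$params, m$config, list(tri))
  loss <- ns$ag_softmax_xent(nd$logits, 1L)
  ns$ag_backward(loss)
  for (b in c("ggb", "fab", "lgb")) {
    g <- m$params$stems[[b]]$W$grad
    expect_false(is.null(g))
    expect_gt(max(abs(g)), 0)
  }
})

test_that("batched and single forwards agree", {
  m <- cast_model(cast_config_tiny(), seed = 4)
  t1 <- rand_triplet(32L, seed = 8)
  t2 <- rand_triplet(32L, seed = 9)
  fw <- cast_forward(m, list(t1, t2))
  expect_equal(fw$logits[1L, ], cast_forward(m, t1)$logits[1L, ],
               tolerance = 1e-10)
  expect_equal(fw$logits[2L, ], cast_forward(m, t2)$logits[1L, ],
               tolerance = 1e-10)
})
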