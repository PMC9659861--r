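# Synthetic generator: determinism, multi-scale consistency, class mixture
# structure, and the designed scale split.

test_that("rendering is deterministic given label and seed", {
  cfg <- thw_config(size = 64L)
  a <- render_scene(3L, 7L, cfg)
  b <- render_scene(3L, 7L, cfg)
  expect_identical(a, b)
  expect_false(identical(render_scene(3L, 8L, cfg), a))
})

test_that("unknown labels are rejected with the valid range", {
  expect_error(render_scene(10L, 1L), "0\\.\\.9")
  expect_error(render_scene(-1L, 1L), "0\\.\\.9")
  expect_error(make_triplet(array(0.5, c(8, 8, 3)), 12L), "0\\.\\.9")
})

test_that("different seeds change pixels but not the class spectrum", {
  cfg <- thw_config(size = 64L)
  spec_mean <- function(seeds) {
    sp <- sapply(seeds, function(s) radial_power_spectrum(render_scene(0L, s, cfg)))
    rowMeans(sp)
  }
  m1 <- spec_mean(1:30)
  m2 <- spec_mean(101:130)
  expect_false(identical(render_scene(0L, 1L, cfg), render_scene(0L, 2L, cfg)))
  # class-mean radial spectra agree across seed sets (relative L2)
  expect_lt(sqrt(sum((m1 - m2)^2) / sum(m2^2)), 0.25)
})

test_that("a noiseless, jitter-free coarse scene equals its template", {
  cfg <- thw_config(size = 32L, noise_sd = 0, clutter_amp = 0, jitter = FALSE)
  for (cl in c(4L, 7L, 8L)) {
    expect_identical(render_scene(cl, 5L, cfg), scene_template(cl, 32L))
  }
})

test_that("triplets are exact area-average downsamplings", {
  # constants are preserved at every scale
  tri <- make_triplet(array(0.5, c(16L, 16L, 3L)), 0L)
  expect_equal(tri$img20, array(0.5, c(8, 8, 3)))
  expect_equal(tri$img10, array(0.5, c(4, 4, 3)))

  # a period-2 checkerboard averages to the two-colour mean at 20x
  S <- 16L
  cb <- outer(seq_len(S), seq_len(S), function(r, c) (r + c) %% 2)
  scene <- array(rep(0.2 + 0.6 * cb, 3L), c(S, S, 3L))
  tri <- make_triplet(scene, 1L)
  expect_equal(tri$img20, array(0.5, c(8, 8, 3)), tolerance = 1e-12)

  # full-scale shape contract: 64/128/256
  tri <- make_triplet(array(0.25, c(256L, 256L, 3L)), 2L)
  expect_equal(dim(tri$img10), c(64L, 64L, 3L))
  expect_equal(dim(tri$img20), c(128L, 128L, 3L))
  expect_equal(dim(tri$img40), c(256L, 256L, 3L))

  expect_error(make_triplet(array(0, c(10L, 10L, 3L)), 0L), "multiple of 4")
})

test_that("mean intensity is conserved across scales for rendered scenes", {
  cfg <- thw_config(size = 32L)
  for (cl in 0:9) {
    tri <- make_triplet(render_scene(cl, cl + 10L, cfg), cl)
    expect_lt(abs(mean(tri$img40) - mean(tri$img20)), 1e-6)
    expect_lt(abs(mean(tri$img40) - mean(tri$img10)), 1e-6)
  }
})

test_that("slide bags follow the configured composition", {
  # degenerate mixture: one-hot composition row forces a single class
  comp <- default_type_composition()
  comp[1L, ] <- c(0, 0, 0, 0, 0, 0, 1, 0, 0, 0)
  cfg <- thw_config(size = 8L, patches_per_wsi = 24L, type_composition = comp,
                    dirichlet_conc = 1e9)
  bag <- generate_wsi_bag(0L, cfg, seed = 3L)
  expect_true(all(vapply(bag$triplets, `[[`, integer(1L), "patho_label") == 6L))
  expect_equal(sum(bag$composition), 1, tolerance = 1e-9)

  # 10,000 draws from the type-A row: frequencies within 3 SE
  cfg2 <- thw_config(size = 8L, patches_per_wsi = 10000L, dirichlet_conc = 1e9)
  bag2 <- generate_wsi_bag(0L, cfg2, seed = 4L)
  labs <- vapply(bag2$triplets, `[[`, integer(1L), "patho_label")
  p <- default_type_composition()[1L, ]
  freq <- tabulate(labs + 1L, 10L) / 10000
  se <- sqrt(p * (1 - p) / 10000)
  expect_true(all(abs(freq - p) <= 3 * se + 1e-12))

  expect_error(generate_wsi_bag(8L, cfg), "0\\.\\.7")
})

test_that("identical configuration and seed reproduce the dataset exactly", {
  cfg <- thw_config(size = 16L, patches_per_wsi = 4L, n_wsis_per_type = 1L,
                    seed = 11L)
  d1 <- simulate_thw(cfg)
  d2 <- simulate_thw(cfg)
  expect_identical(d1$bags, d2$bags)
  expect_identical(d1$splits, d2$splits)
})

test_that("the coarse class pair is separable at 10x but degraded at 40x", {
  skip_if_not_installed("rpart")
  cfg <- thw_config(size = 64L)
  classes <- c(4L, 7L)
  gen <- function(n_per, seed0) {
    s <- make_patch_set(classes, n_per, seed0, size = 64L, cfg = cfg)
    list(i40 = lapply(s$triplets, `[[`, "img40"),
         i10 = lapply(s$triplets, `[[`, "img10"),
         y = factor(s$labels))
  }
  tr <- gen(80L, 100L)
  te <- gen(40L, 5000L)
  # fixed budget: the same 64 relative pixel locations at either scale
  set.seed(42)
  rel <- cbind(stats::runif(64), stats::runif(64))
  feats <- function(imgs) {
    t(vapply(imgs, function(im) {
      S <- dim(im)[1L]
      r <- pmin(S, pmax(1, ceiling(rel[, 1L] * S)))
      c <- pmin(S, pmax(1, ceiling(rel[, 2L] * S)))
      (im[cbind(r, c, 1)] + im[cbind(r, c, 2)] + im[cbind(r, c, 3)]) / 3
    }, numeric(64L)))
  }
  acc <- function(get) {
    fit <- rpart::rpart(y ~ ., data.frame(y = tr$y, feats(get(tr))))
    dte <- data.frame(y = te$y, feats(get(te)))
    mean(predict(fit, dte, type = "class") == dte$y)
  }
  a40 <- acc(function(d) d$i40)
  a10 <- acc(function(d) d$i10)
  expect_gt(a10, a40 + 0.15)   # the designed scale split
  expect_gt(a10, 0.95)
  expect_lt(a40, 0.95)         # below ceiling at 40x
})

test_that("configuration invariants are validated", {
  expect_error(thw_config(size = 30L), "multiple of 4")
  expect_error(thw_config(patches_per_wsi = 0L), ">= 1")
  bad <- default_type_composition()
  bad[1L, 1L] <- 0.9
  expect_error(thw_config(type_composition = bad), "sum to 1")
})
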