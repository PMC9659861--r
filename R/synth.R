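# Synthetic multi-scale thymoma histopathology data.
#
# The generator emulates the statistical structure the two-stage architecture
# assumes, without modelling real H&E appearance:
#   * co-registered patch triplets: one rendered 40x scene per patch, with the
#     20x and 10x views produced by exact 2x2 / 4x4 area-average downsampling
#     (same field of view at three resolutions);
#   * ten patch classes built from two signal families: coarse low-frequency
#     layout (bands for fibrous septa, rings for perivascular space, large
#     blobs for medullary areas) that survives downsampling, and fine texture
#     (nucleus size/density gradations for the four epithelial classes, small
#     specks for erythrocyte/lymphocyte, a dense irregular field for tumor)
#     that is attenuated by it;
#   * a high-frequency "clutter" field on the coarse classes whose 2x2 cells
#     average to zero exactly, so the coarse classes are clean at 10x/20x but
#     cluttered at 40x — one class pair is separable only through the coarse
#     family, one only through the fine family, making multi-branch fusion
#     genuinely informative;
#   * slide bags whose thymoma type fixes a Dirichlet-centred mixture over
#     patch classes, mixed types being exact averages of their components.

#' Synthetic dataset configuration
#'
#' @param n_wsis_per_type synthetic slides per thymoma type.
#' @param patches_per_wsi patch triplets per slide (default 3000, the
#'   full-scale slide division; desk-scale runs use 16-64).
#' @param size 40x scene side length in pixels (must be a multiple of 4; the
#'   10x/20x views are `size/4` and `size/2`).
#' @param noise_sd Gaussian pixel noise standard deviation (intensity units).
#' @param clutter_amp amplitude of the zero-mean high-frequency clutter
#'   applied to the coarse-layout classes.
#' @param jitter randomise coarse layout positions slightly per scene.
#' @param type_composition 8 x 10 row-stochastic matrix mapping thymoma types
#'   (rows: A, AB, B1, B1+B2, B2, B2+B3, B3, TC) to patch-class mixtures;
#'   defaults to [default_type_composition()].
#' @param dirichlet_conc concentration of the per-slide Dirichlet draw around
#'   the type's composition row (slide-to-slide variability).
#' @param train_frac fraction of slides per type assigned to the training
#'   split (slide-level, no patch leakage).
#' @param seed master seed; all randomness derives from it.
#' @return list of class `"thw_config"`.
#' @export
thw_config <- function(n_wsis_per_type = 2L, patches_per_wsi = 3000L,
                       size = 256L, noise_sd = 0.02, clutter_amp = 0.3,
                       jitter = TRUE, type_composition = default_type_composition(),
                       dirichlet_conc = 200, train_frac = 0.75, seed = 0L) {
  if (size %% 4L != 0L) stop("size must be a multiple of 4")
  if (patches_per_wsi < 1L) stop("patches_per_wsi must be >= 1")
  if (!all(abs(rowSums(type_composition) - 1) < 1e-9))
    stop("type_composition rows must sum to 1")
  if (nrow(type_composition) != 8L || ncol(type_composition) != 10L)
    stop("type_composition must be 8 x 10")
  structure(list(n_wsis_per_type = as.integer(n_wsis_per_type),
                 patches_per_wsi = as.integer(patches_per_wsi),
                 size = as.integer(size), noise_sd = noise_sd,
                 clutter_amp = clutter_amp, jitter = jitter,
                 type_composition = type_composition,
                 dirichlet_conc = dirichlet_conc, train_frac = train_frac,
                 seed = as.integer(seed)),
            class = "thw_config")
}

#' Default thymoma-type to patch-class composition
#'
#' Encodes the qualitative associations between slide types and patch-level
#' pathological information: type A concentrates on spindle epithelial cells
#' and tumor; B1 on B1 epithelial cells, lymphocytes and medullary areas; B2
#' adds perivascular spaces; B3 is epithelial-dominant with few lymphocytes;
#' TC is tumor-dominant; mixed types (AB, B1+B2, B2+B3) are exact averages of
#' their components.  Values are artifact-defined and editable.
#'
#' @return 8 x 10 row-stochastic matrix (rows: types, cols: patch classes).
#' @export
default_type_composition <- function() {
  a  <- c(.50, .02, .02, .02, .08, .06, .05, .05, .05, .15)
  b1 <- c(.02, .35, .03, .02, .06, .04, .25, .05, .15, .03)
  b2 <- c(.02, .03, .35, .03, .08, .04, .18, .15, .05, .07)
  b3 <- c(.02, .02, .04, .40, .06, .04, .06, .16, .02, .18)
  tc <- c(.03, .01, .01, .02, .10, .12, .05, .04, .02, .60)
  m <- rbind(A = a, AB = (a + b1) / 2, B1 = b1, `B1+B2` = (b1 + b2) / 2,
             B2 = b2, `B2+B3` = (b2 + b3) / 2, B3 = b3, TC = tc)
  colnames(m) <- patho_classes()
  m
}

# ---- scene rendering -------------------------------------------------------

.bg_tint <- c(0.92, 0.80, 0.88)       # eosin-like background
.fg_nucleus <- c(0.30, 0.15, 0.45)    # hematoxylin-like nuclei
.fg_eryth <- c(0.78, 0.18, 0.22)
.fg_lymph <- c(0.22, 0.16, 0.52)

coarse_classes <- function() c(4L, 7L, 8L)

# deterministic coarse luminance template (no jitter, no clutter, no noise)
coarse_delta <- function(label, S, off_r = 0L, off_c = 0L) {
  d <- matrix(0, S, S)
  if (label == 4L) {                       # fibrous septa: horizontal bands
    r <- (seq_len(S) - 1L + off_r) %% S
    dark <- (r %/% (S %/% 8L)) %% 2L == 0L
    d[dark, ] <- -0.35
  } else if (label == 7L) {                # perivascular space: ring
    cx <- S / 2 + off_c; cy <- S / 2 + off_r
    dist <- sqrt(outer((seq_len(S) - cy)^2, (seq_len(S) - cx)^2, "+"))
    d[dist >= 0.28 * S & dist <= 0.38 * S] <- -0.35
    d[dist < 0.10 * S] <- 0.08
  } else if (label == 8L) {                # medullary areas: two large blobs
    ctr <- rbind(c(0.30, 0.30), c(0.70, 0.65)) * S
    ctr[, 1L] <- ctr[, 1L] + off_r; ctr[, 2L] <- ctr[, 2L] + off_c
    for (i in 1:2) {
      d2 <- outer((seq_len(S) - ctr[i, 1L])^2, (seq_len(S) - ctr[i, 2L])^2, "+")
      d <- d - 0.40 * exp(-d2 / (2 * (0.15 * S)^2))
    }
  }
  d
}

#' Deterministic scene template
#'
#' The noiseless, jitter-free, clutter-free rendering of a class: background
#' tint plus the class's coarse layout (fine-texture classes have no
#' deterministic component beyond the tint).
#'
#' @param patho_label class index 0..9.
#' @param size scene side length.
#' @return `size x size x 3` array in `[0, 1]`.
#' @export
scene_template <- function(patho_label, size) {
  check_label(patho_label)
  img <- array(rep(.bg_tint, each = size * size), dim = c(size, size, 3L))
  d <- coarse_delta(patho_label, size)
  for (ch in 1:3) img[, , ch] <- pmin(pmax(img[, , ch] + d, 0), 1)
  round(img * 255) / 255
}

check_label <- function(patho_label) {
  if (length(patho_label) != 1L || is.na(patho_label) ||
      patho_label < 0L || patho_label > 9L || patho_label != round(patho_label))
    stop("unknown pathological class ", patho_label, "; valid labels are 0..9")
  invisible(as.integer(patho_label))
}

paint_discs <- function(st, centers, r) {
  S <- nrow(st)
  for (i in seq_len(nrow(centers))) {
    cy <- centers[i, 1L]; cx <- centers[i, 2L]
    ys <- max(1L, floor(cy - r)):min(S, ceiling(cy + r))
    xs <- max(1L, floor(cx - r)):min(S, ceiling(cx + r))
    mask <- outer((ys - cy)^2, (xs - cx)^2, "+") <= r^2
    blk <- st[ys, xs, drop = FALSE]
    blk[mask] <- 1
    st[ys, xs] <- blk
  }
  st
}

paint_spindles <- function(st, centers, len, wid, thetas) {
  S <- nrow(st)
  for (i in seq_len(nrow(centers))) {
    cy <- centers[i, 1L]; cx <- centers[i, 2L]; th <- thetas[i]
    ext <- ceiling(len)
    ys <- max(1L, floor(cy - ext)):min(S, ceiling(cy + ext))
    xs <- max(1L, floor(cx - ext)):min(S, ceiling(cx + ext))
    dy <- ys - cy; dx <- xs - cx
    u <- outer(dy * cos(th), dx * sin(th), "+")
    v <- outer(-dy * sin(th), dx * cos(th), "+")
    mask <- (u / len)^2 + (v / wid)^2 <= 1
    blk <- st[ys, xs, drop = FALSE]
    blk[mask] <- 1
    st[ys, xs] <- blk
  }
  st
}

# nucleus radius / count schedules (fractions of a 256 scene, scaled by size)
speck_spec <- function(label, S) {
  sc <- S / 256
  switch(as.character(label),
    "0" = list(kind = "spindle", n = round(140 * sc^2), len = max(2, 5 * sc),
               wid = max(1, 1.4 * sc), fg = .fg_nucleus),
    "1" = list(kind = "disc", n = round(120 * sc^2), r = max(1, 2 * sc),
               fg = .fg_nucleus),
    "2" = list(kind = "disc", n = round(230 * sc^2), r = max(1, 3 * sc),
               fg = .fg_nucleus),
    "3" = list(kind = "disc", n = round(130 * sc^2), r = max(1, 4 * sc),
               fg = .fg_nucleus),
    "5" = list(kind = "disc", n = round(900 * sc^2), r = max(1, 1.5 * sc),
               fg = .fg_eryth),
    "6" = list(kind = "disc", n = round(1800 * sc^2), r = max(1, 1.5 * sc),
               fg = .fg_lymph),
    NULL)
}

#' Render one synthetic 40x scene
#'
#' Deterministic given `(patho_label, seed, cfg)`.  Coarse-layout classes
#' (fibrous septa, perivascular space, medullary areas) are template + jitter
#' + zero-mean high-frequency clutter; fine-texture classes are nucleus /
#' speck fields; tumor is a dense irregular blocky field.
#'
#' @param patho_label class index 0..9.
#' @param seed integer rendering seed.
#' @param cfg a [thw_config()].
#' @return `size x size x 3` array in `[0, 1]`.
#' @export
render_scene <- function(patho_label, seed, cfg = thw_config()) {
  label <- check_label(patho_label)
  S <- cfg$size
  with_seed(seed, {
    img <- array(rep(.bg_tint, each = S * S), dim = c(S, S, 3L))
    if (label %in% coarse_classes()) {
      off_r <- off_c <- 0L
      if (cfg$jitter) {
        off_r <- sample.int(S %/% 8L, 1L) - S %/% 16L
        off_c <- sample.int(S %/% 8L, 1L) - S %/% 16L
      }
      d <- coarse_delta(label, S, off_r, off_c)
      if (cfg$clutter_amp > 0) {
        half <- S %/% 2L
        sgn <- matrix(sample(c(-1, 1), half * half, replace = TRUE), half, half)
        d <- d + kronecker(sgn, matrix(c(1, -1, -1, 1), 2L, 2L)) * cfg$clutter_amp
      }
      for (ch in 1:3) img[, , ch] <- img[, , ch] + d
    } else if (label == 9L) {              # tumor: dense irregular field
      blk <- max(2L, S %/% 32L)
      coarse <- matrix(stats::runif((S %/% blk)^2), S %/% blk, S %/% blk)
      field <- kronecker(coarse, matrix(1, blk, blk))
      st <- (field > stats::quantile(field, 0.45)) * 0.85
      st <- st * (0.7 + 0.3 * matrix(stats::runif(S * S), S, S))
      for (ch in 1:3) img[, , ch] <- img[, , ch] * (1 - st) + .fg_nucleus[ch] * st
    } else {                               # nucleus / speck fields
      sp <- speck_spec(label, S)
      st <- matrix(0, S, S)
      if (sp$n > 0L) {
        centers <- cbind(stats::runif(sp$n, 1, S), stats::runif(sp$n, 1, S))
        st <- if (sp$kind == "spindle") {
          paint_spindles(st, centers, sp$len, sp$wid,
                         stats::rnorm(sp$n, pi / 4, 0.15))
        } else {
          paint_discs(st, centers, sp$r)
        }
      }
      for (ch in 1:3) img[, , ch] <- img[, , ch] * (1 - st) + sp$fg[ch] * st
    }
    if (cfg$noise_sd > 0) {
      img <- img + array(stats::rnorm(length(img), 0, cfg$noise_sd), dim = dim(img))
    }
    # snap to the 8-bit intensity grid so PNG round trips are bit-exact
    round(pmin(pmax(img, 0), 1) * 255) / 255
  })
}

# ---- triplets --------------------------------------------------------------

# exact f x f area-average downsampling
area_downsample <- function(img, f) {
  d <- dim(img)
  stopifnot(d[1L] %% f == 0L, d[2L] %% f == 0L)
  out <- array(0, dim = c(d[1L] %/% f, d[2L] %/% f, d[3L]))
  for (ch in seq_len(d[3L])) {
    m <- img[, , ch]
    m <- rowsum(m, rep(seq_len(d[1L] %/% f), each = f))
    m <- t(rowsum(t(m), rep(seq_len(d[2L] %/% f), each = f)))
    out[, , ch] <- m / (f * f)
  }
  out
}

#' Assemble a co-registered patch triplet from a 40x scene
#'
#' The 20x and 10x views are exact 2x2 and 4x4 area averages of the scene
#' (same field of view), so mean intensity is conserved across scales.
#'
#' @param scene `S x S x 3` array (`S` a multiple of 4).
#' @param patho_label class index 0..9.
#' @param wsi_id slide identifier.
#' @param position integer `(row, col)` grid index within the slide.
#' @return list of class `"patch_triplet"` with `img10`, `img20`, `img40`,
#'   `patho_label`, `wsi_id`, `position`.
#' @export
make_triplet <- function(scene, patho_label, wsi_id = "wsi0", position = c(1L, 1L)) {
  d <- dim(scene)
  if (length(d) != 3L || d[3L] != 3L || d[1L] != d[2L] || d[1L] %% 4L != 0L)
    stop("scene must be an S x S x 3 array with S a multiple of 4; got ",
         paste(d, collapse = "x"))
  structure(list(img10 = area_downsample(scene, 4L),
                 img20 = area_downsample(scene, 2L),
                 img40 = scene,
                 patho_label = check_label(patho_label),
                 wsi_id = wsi_id, position = as.integer(position)),
            class = "patch_triplet")
}

# ---- slide bags and datasets ----------------------------------------------

rdirichlet1 <- function(alpha) {
  g <- stats::rgamma(length(alpha), shape = pmax(alpha, 1e-8))
  g / sum(g)
}

#' Generate one synthetic slide bag
#'
#' Draws a per-slide class composition from a Dirichlet centred on the type's
#' composition row, samples patch labels from it, and renders one triplet per
#' patch.
#'
#' @param thymoma_type type index 0..7 (A, AB, B1, B1+B2, B2, B2+B3, B3, TC).
#' @param cfg a [thw_config()].
#' @param seed slide seed.
#' @param wsi_id slide identifier.
#' @return list of class `"wsi_bag"` with `wsi_id`, `thymoma_type`,
#'   `composition` (length-10, sums to 1) and `triplets`.
#' @export
generate_wsi_bag <- function(thymoma_type, cfg = thw_config(), seed = 0L,
                             wsi_id = NULL) {
  if (length(thymoma_type) != 1L || is.na(thymoma_type) ||
      thymoma_type < 0L || thymoma_type > 7L)
    stop("thymoma_type must be in 0..7")
  if (is.null(wsi_id)) wsi_id <- sprintf("t%d_s%d", thymoma_type, seed)
  m <- cfg$patches_per_wsi
  drawn <- with_seed(seed, {
    comp <- rdirichlet1(cfg$dirichlet_conc *
                          cfg$type_composition[thymoma_type + 1L, ])
    labels <- sample(0:9, m, replace = TRUE, prob = comp)
    list(comp = comp, labels = labels,
         patch_seeds = sample.int(.Machine$integer.max - 1L, m))
  })
  side <- ceiling(sqrt(m))
  triplets <- vector("list", m)
  for (i in seq_len(m)) {
    scene <- render_scene(drawn$labels[i], drawn$patch_seeds[i], cfg)
    pos <- c((i - 1L) %/% side + 1L, (i - 1L) %% side + 1L)
    triplets[[i]] <- make_triplet(scene, drawn$labels[i], wsi_id, pos)
  }
  structure(list(wsi_id = wsi_id, thymoma_type = as.integer(thymoma_type),
                 composition = drawn$comp, triplets = triplets),
            class = "wsi_bag")
}

#' Simulate a full synthetic dataset
#'
#' Generates `n_wsis_per_type` slide bags for each of the eight thymoma types
#' and assigns a slide-level train/test split (no slide appears in both).
#'
#' @param cfg a [thw_config()].
#' @return list of class `"thw_dataset"` with `bags`, `splits` (named
#'   character vector, slide id -> "train"/"test") and `config`.
#' @export
simulate_thw <- function(cfg = thw_config()) {
  nw <- cfg$n_wsis_per_type
  seeds <- with_seed(cfg$seed,
                     matrix(sample.int(.Machine$integer.max - 1L, 8L * nw), 8L, nw))
  bags <- list()
  splits <- character(0L)
  n_test <- max(if (nw > 1L) 1L else 0L, round((1 - cfg$train_frac) * nw))
  for (t in 0:7) for (i in seq_len(nw)) {
    id <- sprintf("type%d_wsi%02d", t, i)
    bags[[id]] <- generate_wsi_bag(t, cfg, seed = seeds[t + 1L, i], wsi_id = id)
    splits[id] <- if (i > nw - n_test) "test" else "train"
  }
  structure(list(bags = bags, splits = splits, config = cfg),
            class = "thw_dataset")
}

#' Flatten a dataset into patch triplets and labels
#'
#' @param dataset a [simulate_thw()] result.
#' @param split optional `"train"` or `"test"` filter.
#' @return list with `triplets`, `labels` (0-based), `wsi_ids`.
#' @export
thw_patches <- function(dataset, split = NULL) {
  keep <- names(dataset$bags)
  if (!is.null(split)) keep <- keep[dataset$splits[keep] == split]
  triplets <- list(); labels <- integer(0L); ids <- character(0L)
  for (id in keep) {
    b <- dataset$bags[[id]]
    triplets <- c(triplets, b$triplets)
    labels <- c(labels, vapply(b$triplets, `[[`, integer(1L), "patho_label"))
    ids <- c(ids, rep(id, length(b$triplets)))
  }
  list(triplets = triplets, labels = labels, wsi_ids = ids)
}

#' Radial power spectrum of a scene
#'
#' Mean squared FFT magnitude of the luminance channel, binned by integer
#' radial spatial frequency.  Used to characterise the scale split of the
#' synthetic classes.
#'
#' @param img `S x S x 3` array (or `S x S` matrix).
#' @return numeric vector, one mean power value per radial frequency bin.
#' @export
radial_power_spectrum <- function(img) {
  g <- if (length(dim(img)) == 3L) (img[, , 1L] + img[, , 2L] + img[, , 3L]) / 3
       else img
  S <- nrow(g)
  P <- Mod(stats::fft(g - mean(g)))^2 / S^2
  f <- pmin(seq_len(S) - 1L, S - (seq_len(S) - 1L))
  rad <- round(sqrt(outer(f^2, f^2, "+")))
  as.numeric(tapply(as.numeric(P), as.integer(rad), mean))
}
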