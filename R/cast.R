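# CAST: the cross attentive scale-aware transformer.
#
# Three parallel branches process co-registered patch triplets: GGB (global
# branch, MSA blocks, 10x input), LGB (local branch, shifted-window blocks,
# 40x input) and FAB (aggregation branch, 20x input) whose CAS block fuses
# the three branches with CAM and updates the result with spatial-reduction
# attention.  All branches share one hierarchical grid schedule; after each
# of the first two stages a 2x2 patch-merge halves the grid and doubles the
# channels.  The classifier head global-average-pools the FAB grid; the
# slide-level embedding concatenates per-branch pooled projections.

#' CAST configuration
#'
#' Defaults follow the full-scale configuration: triplets of 64/128/256 pixel
#' images, stage widths 128/256/512, heads 2/4/8, MLP ratios 8/4/4, stage-1
#' patch sizes 2/4/8 (GGB/FAB/LGB) so that all branches share a 32x32 grid,
#' and 2x2 patch merging between stages.
#'
#' @param img_sizes named integer vector `c(img10=, img20=, img40=)`: side
#'   lengths of the three magnification inputs.
#' @param stage_dims channel widths of the three stages.
#' @param stage_heads attention heads per stage.
#' @param stage_mlp_ratios MLP expansion ratio per stage.
#' @param stage1_patch named vector `c(ggb=, fab=, lgb=)` of stage-1 patch
#'   sizes; each branch's image side divided by its patch size must agree.
#' @param merge_patch patch-merge factor between stages (2 = halve the grid).
#' @param blocks_per_stage transformer blocks per branch per stage.
#' @param n_classes number of pathological-information classes.
#' @param window window side for the local branch (clipped per stage to the
#'   grid side; the shift is `window/2`, or 0 when the window spans the grid).
#' @param sr_ratios spatial-reduction ratio of the FAB SRA per stage.
#' @param use_ggb,use_fab,use_lgb branch toggles (ablation variants).
#' @param use_cam use the cross-correlation attention module for fusion;
#'   requires all three branches.  With `use_cam = FALSE` fusion falls back
#'   to channel concatenation + linear projection (or identity when FAB is
#'   the only branch).
#' @param embed_dim_out width of the slide-level patch embedding (a multiple
#'   of 3; disabled branches contribute zeros).
#' @param attn_scale see [attention_config()].
#' @return a list of class `"cast_config"`.
#' @export
cast_config <- function(img_sizes = c(img10 = 64L, img20 = 128L, img40 = 256L),
                        stage_dims = c(128L, 256L, 512L),
                        stage_heads = c(2L, 4L, 8L),
                        stage_mlp_ratios = c(8, 4, 4),
                        stage1_patch = c(ggb = 2L, fab = 4L, lgb = 8L),
                        merge_patch = 2L,
                        blocks_per_stage = 2L,
                        n_classes = 10L,
                        window = 8L,
                        sr_ratios = c(8L, 4L, 2L),
                        use_ggb = TRUE, use_fab = TRUE, use_lgb = TRUE,
                        use_cam = TRUE,
                        embed_dim_out = 768L,
                        attn_scale = "inv_sqrt_d") {
  if (!any(use_ggb, use_fab, use_lgb)) stop("at least one branch must be enabled")
  if (use_cam && !(use_ggb && use_fab && use_lgb))
    stop("use_cam = TRUE requires all three branches ",
         "(CAM needs GGB, FAB and LGB inputs); disable CAM for ablations")
  if (embed_dim_out %% 3L != 0L) stop("embed_dim_out must be a multiple of 3")
  g <- c(ggb = img_sizes[["img10"]] / stage1_patch[["ggb"]],
         fab = img_sizes[["img20"]] / stage1_patch[["fab"]],
         lgb = img_sizes[["img40"]] / stage1_patch[["lgb"]])
  if (any(g != round(g))) stop("stage-1 patch sizes must divide the image sides")
  if (length(unique(g)) != 1L)
    stop("branch grids disagree after stage-1 patching: ",
         paste(names(g), g, sep = "=", collapse = ", "))
  sides <- integer(3L)
  sides[1L] <- as.integer(g[[1L]])
  for (i in 2:3) {
    if (sides[i - 1L] %% merge_patch != 0L)
      stop("merge_patch must divide the stage-", i - 1L, " grid side ", sides[i - 1L])
    sides[i] <- sides[i - 1L] %/% merge_patch
  }
  for (i in 1:3) {
    if (stage_dims[i] %% stage_heads[i] != 0L)
      stop("stage ", i, ": dim ", stage_dims[i],
           " not divisible by ", stage_heads[i], " heads")
    if (sides[i] %% min(sr_ratios[i], sides[i]) != 0L)
      stop("stage ", i, ": sr_ratio ", sr_ratios[i],
           " does not divide grid side ", sides[i])
  }
  structure(list(img_sizes = img_sizes, stage_dims = as.integer(stage_dims),
                 stage_heads = as.integer(stage_heads),
                 stage_mlp_ratios = stage_mlp_ratios,
                 stage1_patch = stage1_patch, merge_patch = as.integer(merge_patch),
                 blocks_per_stage = as.integer(blocks_per_stage),
                 n_classes = as.integer(n_classes), window = as.integer(window),
                 sr_ratios = as.integer(sr_ratios),
                 use_ggb = use_ggb, use_fab = use_fab, use_lgb = use_lgb,
                 use_cam = use_cam, embed_dim_out = as.integer(embed_dim_out),
                 attn_scale = attn_scale, grid_sides = sides),
            class = "cast_config")
}

#' Desk-scale CAST configuration
#'
#' A reduced configuration for experiments that run on a laptop CPU: 8/16/32
#' pixel triplets, stage widths 16/32/64, and a correspondingly small
#' embedding.  Architecture (branch structure, block types, fusion) is
#' unchanged.
#'
#' @param ... overrides passed on to [cast_config()].
#' @export
cast_config_tiny <- function(...) {
  args <- list(img_sizes = c(img10 = 8L, img20 = 16L, img40 = 32L),
               stage_dims = c(16L, 32L, 64L),
               stage_heads = c(2L, 4L, 8L),
               stage_mlp_ratios = c(4, 4, 4),
               stage1_patch = c(ggb = 2L, fab = 4L, lgb = 8L),
               window = 2L,
               sr_ratios = c(2L, 2L, 1L),
               n_classes = 10L,
               embed_dim_out = 48L)
  over <- list(...)
  args[names(over)] <- over
  do.call(cast_config, args)
}

# per-stage attention configs for the three block families
stage_attn_cfg <- function(cfg, i, family = c("msa", "wmsa", "sra")) {
  family <- match.arg(family)
  side <- cfg$grid_sides[i]
  win <- min(cfg$window, side)
  shift <- if (win < side) win %/% 2L else 0L
  attention_config(dim = cfg$stage_dims[i], n_heads = cfg$stage_heads[i],
                   window = win, shift = shift,
                   sr_ratio = min(cfg$sr_ratios[i], side),
                   mlp_ratio = cfg$stage_mlp_ratios[i],
                   attn_scale = cfg$attn_scale)
}

# ---- patch embedding and patch merging ------------------------------------

# image (H x W x 3 array) -> im2col matrix (n_tokens x 3*P^2); tokens scan the
# patch grid row-major, columns are (pixel row-major within patch) x channel
im2col_image <- function(img, P) {
  d <- dim(img)
  stopifnot(length(d) == 3L, d[3L] == 3L)
  if (d[1L] %% P != 0L || d[2L] %% P != 0L)
    stop("patch size ", P, " must divide the image sides ", d[1L], "x", d[2L])
  Hg <- d[1L] %/% P; Wg <- d[2L] %/% P
  cols <- vector("list", P * P)
  k <- 0L
  for (py in seq_len(P)) for (px in seq_len(P)) {
    k <- k + 1L
    sub <- img[seq.int(py, d[1L], by = P), seq.int(px, d[2L], by = P), ,
               drop = FALSE]
    cols[[k]] <- cbind(as.vector(t(sub[, , 1L])),
                       as.vector(t(sub[, , 2L])),
                       as.vector(t(sub[, , 3L])))
  }
  do.call(cbind, cols)
}

im2col_batch <- function(imgs, P) {
  do.call(rbind, lapply(imgs, im2col_image, P = P))
}

#' Patch splitting + linear embedding
#'
#' Splits an `H x W x 3` image into non-overlapping `P x P` patches, flattens
#' each patch and projects it to `C` channels, yielding an `(H/P * W/P) x C`
#' token grid (row-major).
#'
#' @param img numeric `H x W x 3` array.
#' @param P patch side; must divide both image sides.
#' @param params a [patch_embed_layer()] (or any list with `W` `(3*P^2) x C`
#'   and optional `b` parameter nodes).
#' @return numeric token matrix.
#' @export
patch_embed <- function(img, P, params) {
  x <- im2col_image(img, P)
  y <- x %*% ag_value(params$W)
  if (!is.null(params$b)) y <- sweep(y, 2L, ag_value(params$b)[1L, ], "+")
  y
}

#' @rdname patch_embed
#' @param C output channel count.
#' @param seed optional initialisation seed.
#' @export
patch_embed_layer <- function(P, C, seed = NULL) {
  make <- function() p_linear(3L * P^2, C)
  if (is.null(seed)) make() else with_seed(seed, make())
}

#' 2x2 patch-merge downsampling
#'
#' Reshapes a token grid to 2D, concatenates each non-overlapping 2x2 token
#' neighbourhood and projects it linearly, halving the grid and producing
#' `C_next` channels.
#'
#' @param x numeric `(h*w) x c` token matrix (row-major grid).
#' @param h,w grid shape; both must be even.
#' @param params list with `W` (`4c x C_next`) and optional `b`.
#' @return `(h/2 * w/2) x C_next` token matrix.
#' @export
stage_downsample <- function(x, h, w, params) {
  if (h %% 2L != 0L || w %% 2L != 0L)
    stop("grid sides must be even for 2x2 patch merging (got ", h, "x", w, ")")
  merged <- unfold_node(ag_const(x), h, w, 2L, 1L)$value
  y <- merged %*% ag_value(params$W)
  if (!is.null(params$b)) y <- sweep(y, 2L, ag_value(params$b)[1L, ], "+")
  y
}

# ---- model construction ----------------------------------------------------

branch_names <- function(cfg) {
  c(if (cfg$use_ggb) "ggb", if (cfg$use_fab) "fab", if (cfg$use_lgb) "lgb")
}

#' Construct an (untrained) CAST model
#'
#' @param cfg a [cast_config()].
#' @param seed initialisation seed.
#' @return object of class `"mcvit_cast"` with elements `config`, `params`
#'   and (after [fit_cast()]) `log`.
#' @export
cast_model <- function(cfg = cast_config(), seed = 0L) {
  with_seed(seed, {
    br <- branch_names(cfg)
    d1 <- cfg$stage_dims[1L]
    stems <- list()
    if (cfg$use_ggb) stems$ggb <- p_linear(3L * cfg$stage1_patch[["ggb"]]^2, d1)
    if (cfg$use_fab) stems$fab <- p_linear(3L * cfg$stage1_patch[["fab"]]^2, d1)
    if (cfg$use_lgb) stems$lgb <- p_linear(3L * cfg$stage1_patch[["lgb"]]^2, d1)
    stages <- vector("list", 3L)
    for (i in 1:3) {
      st <- list()
      if (cfg$use_ggb)
        st$ggb <- lapply(seq_len(cfg$blocks_per_stage), function(j)
          p_global_block(stage_attn_cfg(cfg, i, "msa")))
      if (cfg$use_lgb)
        st$lgb <- lapply(seq_len(cfg$blocks_per_stage), function(j)
          p_local_block(stage_attn_cfg(cfg, i, "wmsa")))
      if (cfg$use_fab) {
        dim_i <- cfg$stage_dims[i]
        n_in <- length(br)
        st$fab <- lapply(seq_len(cfg$blocks_per_stage), function(j) {
          p <- list(ln1 = p_ln(dim_i),
                    sra = attn_layer(stage_attn_cfg(cfg, i, "sra"), "sra"),
                    ln2 = p_ln(dim_i),
                    mlp = p_mlp(dim_i, cfg$stage_mlp_ratios[i]))
          if (cfg$use_cam) p$cam <- cam_layer(dim_i)
          else if (n_in > 1L) p$fuse <- p_linear(n_in * dim_i, dim_i)
          p
        })
      }
      stages[[i]] <- st
    }
    merges <- vector("list", 2L)
    for (i in 1:2) {
      merges[[i]] <- lapply(stats::setNames(br, br), function(b)
        p_linear(cfg$merge_patch^2 * cfg$stage_dims[i], cfg$stage_dims[i + 1L]))
    }
    d3 <- cfg$stage_dims[3L]
    head_in <- if (cfg$use_fab) d3 else length(br) * d3
    head <- p_linear(head_in, cfg$n_classes)
    per_branch <- cfg$embed_dim_out %/% 3L
    embed <- lapply(stats::setNames(br, br), function(b) p_linear(d3, per_branch))
    structure(list(config = cfg,
                   params = list(stems = stems, stages = stages, merges = merges,
                                 head = head, embed = embed),
                   seed = seed, log = NULL, version = "mcvit-checkpoint-1"),
              class = "mcvit_cast")
  })
}

# ---- forward ---------------------------------------------------------------

# CAS transformer block: fuse previous-block branch features (CAM or concat),
# then SRA and MLP with pre-norm residuals onto the FAB stream
cas_block_node <- function(A, Bt, C, p, cfg, acfg_sra, Bz, side) {
  if (!is.null(p$cam)) {
    fused <- cam_node(A, Bt, C, p$cam, Bz, side, side)$out
  } else if (!is.null(p$fuse)) {
    parts <- list()
    if (!is.null(A)) parts <- c(parts, list(A))
    if (!is.null(Bt)) parts <- c(parts, list(Bt))
    parts <- c(parts, list(C))
    fused <- lin_fwd(ag_cbind(parts), p$fuse)
  } else {
    fused <- C
  }
  ct <- ag_add(sra_node(ln_fwd(fused, p$ln1), p$sra, acfg_sra, Bz, side, side), C)
  ag_add(mlp_fwd(ln_fwd(ct, p$ln2), p$mlp), ct)
}

# full graph forward on a batch of triplets; returns nodes
cast_forward_node <- function(params, cfg, triplets) {
  Bz <- length(triplets)
  stems <- params$stems
  A <- Bt <- C <- NULL
  if (cfg$use_ggb)
    A <- lin_fwd(ag_const(im2col_batch(lapply(triplets, `[[`, "img10"),
                                       cfg$stage1_patch[["ggb"]])), stems$ggb)
  if (cfg$use_fab)
    C <- lin_fwd(ag_const(im2col_batch(lapply(triplets, `[[`, "img20"),
                                       cfg$stage1_patch[["fab"]])), stems$fab)
  if (cfg$use_lgb)
    Bt <- lin_fwd(ag_const(im2col_batch(lapply(triplets, `[[`, "img40"),
                                        cfg$stage1_patch[["lgb"]])), stems$lgb)
  grids <- list()
  for (i in 1:3) {
    side <- cfg$grid_sides[i]
    n <- side * side
    acfg_g <- if (cfg$use_ggb) stage_attn_cfg(cfg, i, "msa")
    acfg_l <- if (cfg$use_lgb) stage_attn_cfg(cfg, i, "wmsa")
    acfg_s <- if (cfg$use_fab) stage_attn_cfg(cfg, i, "sra")
    for (j in seq_len(cfg$blocks_per_stage)) {
      A_new <- if (cfg$use_ggb)
        global_block_node(A, params$stages[[i]]$ggb[[j]], acfg_g, Bz, n)
      B_new <- if (cfg$use_lgb)
        local_block_node(Bt, params$stages[[i]]$lgb[[j]], acfg_l, Bz, side, side)
      C_new <- if (cfg$use_fab)
        cas_block_node(A, Bt, C, params$stages[[i]]$fab[[j]], cfg, acfg_s, Bz, side)
      if (cfg$use_ggb) A <- A_new
      if (cfg$use_lgb) Bt <- B_new
      if (cfg$use_fab) C <- C_new
    }
    grids[[i]] <- list(ggb = A, fab = C, lgb = Bt)
    if (i < 3L) {
      if (cfg$use_ggb)
        A <- lin_fwd(unfold_node(A, side, side, cfg$merge_patch, Bz),
                     params$merges[[i]]$ggb)
      if (cfg$use_fab)
        C <- lin_fwd(unfold_node(C, side, side, cfg$merge_patch, Bz),
                     params$merges[[i]]$fab)
      if (cfg$use_lgb)
        Bt <- lin_fwd(unfold_node(Bt, side, side, cfg$merge_patch, Bz),
                      params$merges[[i]]$lgb)
    }
  }
  n3 <- cfg$grid_sides[3L]^2
  gaps <- list()
  if (cfg$use_ggb) gaps$ggb <- ag_group_mean(A, n3)
  if (cfg$use_fab) gaps$fab <- ag_group_mean(C, n3)
  if (cfg$use_lgb) gaps$lgb <- ag_group_mean(Bt, n3)
  head_in <- if (cfg$use_fab) gaps$fab else ag_cbind(gaps)
  logits <- lin_fwd(head_in, params$head)
  per_branch <- cfg$embed_dim_out %/% 3L
  emb_parts <- lapply(c("ggb", "fab", "lgb"), function(b) {
    if (!is.null(gaps[[b]])) lin_fwd(gaps[[b]], params$embed[[b]])
    else ag_const(matrix(0, Bz, per_branch))
  })
  embedding <- ag_cbind(emb_parts)
  list(logits = logits, embedding = embedding, grids = grids)
}

#' CAST forward pass
#'
#' @param model an [cast_model()] / [fit_cast()] object.
#' @param triplets a single patch triplet (list with `img10`, `img20`,
#'   `img40`) or a list of them.
#' @return list with `logits` (B x K), `probs`, `predicted` (0-based class
#'   indices), and `embedding` (B x embed_dim_out; disabled branches
#'   zero-filled).
#' @export
cast_forward <- function(model, triplets) {
  if (!is.null(triplets$img40)) triplets <- list(triplets)
  cfg <- model$config
  expect <- c(cfg$img_sizes[["img10"]], cfg$img_sizes[["img20"]],
              cfg$img_sizes[["img40"]])
  for (t in triplets) {
    got <- c(dim(t$img10)[1L], dim(t$img20)[1L], dim(t$img40)[1L])
    if (!all(got == expect))
      stop("triplet image sides ", paste(got, collapse = "/"),
           " do not match the configuration ", paste(expect, collapse = "/"))
  }
  nd <- cast_forward_node(model$params, cfg, triplets)
  logits <- nd$logits$value
  probs <- softmax_rows(logits)
  list(logits = logits, probs = probs,
       predicted = apply(logits, 1L, which.max) - 1L,
       embedding = nd$embedding$value)
}

softmax_rows <- function(x) {
  m <- apply(x, 1L, max)
  e <- exp(x - m)
  e / rowSums(e)
}

#' Predicted pathological class from logits
#'
#' Argmax with lowest-index tie-break; classes are 0-based.
#'
#' @param logits numeric vector (or 1-row matrix) of class logits.
#' @return integer class index (0-based).
#' @export
predict_label <- function(logits) {
  logits <- as.numeric(logits)
  if (anyNA(logits) || any(!is.finite(logits))) stop("logits must be finite")
  which.max(logits) - 1L
}
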