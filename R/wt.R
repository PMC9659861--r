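# WT: the slide-level WSI transformer.
#
# A slide is encoded as an m x (d+1) feature matrix: each of m randomly
# selected patches contributes its multi-scale CAST embedding (d values)
# concatenated with its pathological-information label as a normalised
# scalar (class / (K-1), in [0, 1]).  The default full-scale interface is
# 512 x 769 (768-d embedding + 1 label scalar).  A linear input projection
# maps the (d+1)-wide rows to the transformer width so the head count can
# divide the model dimension; three stages of two classical pre-norm MSA
# blocks follow, then token-wise global average pooling and a linear head
# over the eight thymoma types.

#' WT configuration
#'
#' @param n_tokens number of patch rows per slide matrix (`m`).
#' @param embed_dim width of the patch embedding part of each row; the
#'   feature-matrix width is `embed_dim + 1`.
#' @param model_dim transformer width after the input projection; must be
#'   divisible by `n_heads`.
#' @param stages,blocks_per_stage encoder depth (stages x blocks).
#' @param n_heads,mlp_ratio attention heads / MLP expansion of every block.
#' @param n_types number of slide-level classes (thymoma types).
#' @param use_abs_pos add learned absolute position encodings (default); with
#'   `FALSE` the network is invariant to row permutations of the matrix.
#' @param dropout residual dropout rate used during training (0 disables).
#' @param label_fourier number of fixed Fourier frequencies used to encode the
#'   label scalar before the linear input projection (`cos(pi k s)`,
#'   `sin(pi k s)`, `k = 1..label_fourier`, appended to the raw rows).  The
#'   ten discrete label values become linearly separable token features,
#'   which the per-token layers would otherwise have to synthesise from one
#'   scalar direction; 0 projects the literal scalar.
#' @param attn_scale see [attention_config()].
#' @return list of class `"wt_config"`.
#' @export
wt_config <- function(n_tokens = 512L, embed_dim = 768L, model_dim = 768L,
                      stages = 3L, blocks_per_stage = 2L, n_heads = 12L,
                      mlp_ratio = 4, n_types = 8L, use_abs_pos = TRUE,
                      attn_scale = "inv_sqrt_d", dropout = 0,
                      label_fourier = 8L) {
  if (model_dim %% n_heads != 0L)
    stop("model_dim (", model_dim, ") must be divisible by n_heads (", n_heads, ")")
  structure(list(n_tokens = as.integer(n_tokens), embed_dim = as.integer(embed_dim),
                 width = as.integer(embed_dim) + 1L,
                 width_in = as.integer(embed_dim) + 1L + 2L * as.integer(label_fourier),
                 label_fourier = as.integer(label_fourier),
                 model_dim = as.integer(model_dim), stages = as.integer(stages),
                 blocks_per_stage = as.integer(blocks_per_stage),
                 n_heads = as.integer(n_heads), mlp_ratio = mlp_ratio,
                 n_types = as.integer(n_types), use_abs_pos = use_abs_pos,
                 attn_scale = attn_scale, dropout = dropout),
            class = "wt_config")
}

#' Desk-scale WT configuration
#'
#' @param ... overrides passed on to [wt_config()].
#' @export
wt_config_tiny <- function(...) {
  args <- list(n_tokens = 32L, embed_dim = 48L, model_dim = 64L,
               n_heads = 4L, mlp_ratio = 2, dropout = 0.1)
  over <- list(...)
  args[names(over)] <- over
  do.call(wt_config, args)
}

#' Build a slide feature matrix
#'
#' Samples `m` patches uniformly (without replacement when possible, with
#' replacement when fewer than `m` patches are available) and stacks rows
#' `[embedding, label/(n_classes-1)]`.
#'
#' @param embeddings numeric matrix (`n_patches x d`) or list of d-vectors.
#' @param labels integer patch class labels, 0-based.
#' @param m number of rows to sample.
#' @param seed sampling seed (recorded in the result).
#' @param n_classes number of patch classes (normalisation denominator).
#' @param slide_id optional identifier stored on the result.
#' @return `m x (d+1)` matrix of class `"feature_matrix"` with attributes
#'   `slide_id`, `seed` and `source_idx` (the sampled patch indices).
#' @export
build_feature_matrix <- function(embeddings, labels, m, seed = 0L,
                                 n_classes = 10L, slide_id = NULL) {
  if (is.list(embeddings)) embeddings <- do.call(rbind, embeddings)
  n <- nrow(embeddings)
  if (n < 1L) stop("at least one patch embedding is required")
  if (length(labels) != n) stop("labels length must match embeddings rows")
  idx <- with_seed(seed, {
    if (n >= m) sample.int(n, m) else sample.int(n, m, replace = TRUE)
  })
  M <- cbind(embeddings[idx, , drop = FALSE], labels[idx] / (n_classes - 1L))
  structure(M, class = c("feature_matrix", class(M)), slide_id = slide_id,
            seed = seed, source_idx = idx)
}

#' Construct an (untrained) WT model
#'
#' @param cfg a [wt_config()].
#' @param seed initialisation seed.
#' @return object of class `"mcvit_wt"`.
#' @export
wt_model <- function(cfg = wt_config(), seed = 0L) {
  with_seed(seed, {
    acfg <- wt_block_cfg(cfg)
    blocks <- lapply(seq_len(cfg$stages * cfg$blocks_per_stage),
                     function(j) p_global_block(acfg))
    params <- list(inproj = p_linear(cfg$width_in, cfg$model_dim),
                   pos = if (cfg$use_abs_pos)
                     ag_param(trunc_normal(cfg$n_tokens, cfg$model_dim)),
                   blocks = blocks,
                   head = p_linear(cfg$model_dim, cfg$n_types))
    structure(list(config = cfg, params = params, seed = seed, log = NULL,
                   version = "mcvit-checkpoint-1"),
              class = "mcvit_wt")
  })
}

# fixed Fourier encoding of the label scalar (last column), appended to the
# raw rows; deterministic, applied before the linear input projection
wt_expand <- function(cfg, M) {
  K <- cfg$label_fourier
  if (K == 0L) return(unclass(M))
  s <- M[, ncol(M)]
  ks <- outer(s, pi * seq_len(K))
  cbind(unclass(M), cos(ks), sin(ks))
}

# apply the model's stored column standardisation (identity if absent)
wt_scale <- function(model, M) {
  s <- model$scaling
  if (is.null(s)) return(M)
  sweep(sweep(unclass(M), 2L, s$mu), 2L, s$sd, "/")
}

wt_block_cfg <- function(cfg) {
  attention_config(dim = cfg$model_dim, n_heads = cfg$n_heads,
                   mlp_ratio = cfg$mlp_ratio, attn_scale = cfg$attn_scale,
                   dropout = cfg$dropout)
}

# graph forward; mats: list of m x width matrices (one per slide)
wt_forward_node <- function(params, cfg, mats, training = FALSE) {
  Bz <- length(mats)
  m <- nrow(mats[[1L]])
  x <- lin_fwd(ag_const(do.call(rbind, mats)), params$inproj)
  if (cfg$use_abs_pos) {
    if (m != nrow(params$pos$value))
      stop("feature matrix has ", m, " rows but position encodings expect ",
           nrow(params$pos$value))
    x <- ag_add_posenc(x, params$pos)
  }
  acfg <- wt_block_cfg(cfg)
  for (p in params$blocks) x <- global_block_node(x, p, acfg, Bz, m, training)
  lin_fwd(ag_group_mean(x, m), params$head)
}

#' WT forward pass
#'
#' Applies the model's stored feature standardisation (when fitted with
#' `standardize = TRUE`) before the transformer.
#'
#' @param model an [wt_model()] / [fit_wt()] object.
#' @param M one feature matrix (`m x width`) or a list of them.
#' @return list with `logits` (B x n_types), `probs`, and `predicted`
#'   (0-based type indices, tie-break to the lowest index).
#' @export
wt_forward <- function(model, M) {
  if (is.matrix(M)) M <- list(M)
  cfg <- model$config
  for (mm in M) {
    if (ncol(mm) != cfg$width)
      stop("feature matrix width ", ncol(mm), " != expected ", cfg$width,
           " (embed_dim ", cfg$embed_dim, " + 1 label scalar)")
  }
  M <- lapply(M, function(mm) wt_scale(model, wt_expand(cfg, mm)))
  logits <- wt_forward_node(model$params, cfg, M)$value
  list(logits = logits, probs = softmax_rows(logits),
       predicted = apply(logits, 1L, which.max) - 1L)
}

#' Predicted thymoma type from logits
#'
#' Argmax with lowest-index tie-break; types are 0-based in the order
#' A, AB, B1, B1+B2, B2, B2+B3, B3, TC.
#'
#' @param logits numeric vector of type logits.
#' @return integer type index (0-based).
#' @export
predict_type <- function(logits) {
  logits <- as.numeric(logits)
  if (anyNA(logits) || any(!is.finite(logits))) stop("logits must be finite")
  which.max(logits) - 1L
}

#' Thymoma type names
#' @return character vector of the eight type labels in index order.
#' @export
thymoma_types <- function() c("A", "AB", "B1", "B1+B2", "B2", "B2+B3", "B3", "TC")

#' Pathological-information class names
#' @return character vector of the ten patch-level class labels in index order.
#' @export
patho_classes <- function() {
  c("spindle_epithelial", "b1_epithelial", "b2_epithelial", "b3_epithelial",
    "fibrous_septa", "erythrocyte", "lymphocyte", "perivascular_space",
    "medullary_areas", "tumor")
}
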