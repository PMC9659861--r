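# Dataset, manifest, prediction and feature-matrix IO.
#
# On-disk layout of a written dataset:
#   out_dir/
#     config.yaml                  generator configuration incl. master seed
#     manifest.csv                 one row per triplet (see columns below)
#     <wsi_id>/r<row>_c<col>_<scale>.png   patch images, scale in {10x,20x,40x}
#
# manifest.csv columns: wsi_id, row, col, path10, path20, path40, patho_label,
# thymoma_type, split.  Paths are relative to out_dir.  The first line is a
# comment carrying the master seed.

manifest_cols <- c("wsi_id", "row", "col", "path10", "path20", "path40",
                   "patho_label", "thymoma_type", "split")

#' Write a synthetic dataset to disk
#'
#' Patches are written as PNG files and indexed by a CSV manifest; the
#' generator configuration (including the seed) is stored alongside as YAML,
#' so the dataset is regenerable from the directory alone.
#'
#' @param dataset a `thw_dataset` (or plain list of `wsi_bag`s plus a
#'   `splits` named vector).
#' @param out_dir output directory.
#' @return the manifest path, invisibly.
#' @export
write_dataset <- function(dataset, out_dir) {
  bags <- if (inherits(dataset, "thw_dataset")) dataset$bags else dataset$bags
  splits <- dataset$splits
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) stop("cannot create output directory ", out_dir)
  rows <- vector("list", sum(vapply(bags, function(b) length(b$triplets),
                                    integer(1L))))
  k <- 0L
  for (b in bags) {
    wdir <- file.path(out_dir, b$wsi_id)
    dir.create(wdir, showWarnings = FALSE)
    for (t in b$triplets) {
      stem <- sprintf("r%d_c%d", t$position[1L], t$position[2L])
      rel <- file.path(b$wsi_id, paste0(stem, "_", c("10x", "20x", "40x"), ".png"))
      png::writePNG(t$img10, file.path(out_dir, rel[1L]))
      png::writePNG(t$img20, file.path(out_dir, rel[2L]))
      png::writePNG(t$img40, file.path(out_dir, rel[3L]))
      k <- k + 1L
      rows[[k]] <- data.frame(wsi_id = b$wsi_id, row = t$position[1L],
                              col = t$position[2L], path10 = rel[1L],
                              path20 = rel[2L], path40 = rel[3L],
                              patho_label = t$patho_label,
                              thymoma_type = b$thymoma_type,
                              split = unname(splits[b$wsi_id]))
    }
  }
  manifest <- do.call(rbind, rows)
  cfg <- if (inherits(dataset, "thw_dataset")) dataset$config else NULL
  mpath <- file.path(out_dir, "manifest.csv")
  con <- file(mpath, "w")
  writeLines(sprintf("# mcvit dataset manifest; seed=%s",
                     if (is.null(cfg)) "NA" else cfg$seed), con)
  utils::write.csv(manifest, con, row.names = FALSE)
  close(con)
  if (!is.null(cfg)) {
    ycfg <- unclass(cfg)
    ycfg$type_composition <- apply(cfg$type_composition, 1L, as.numeric,
                                   simplify = FALSE)
    yaml::write_yaml(ycfg, file.path(out_dir, "config.yaml"))
  }
  invisible(mpath)
}

#' Read a dataset manifest
#'
#' Validates the fixed column set and rejects manifests in which any slide
#' appears in more than one split (train/test leakage).
#'
#' @param path manifest CSV path.
#' @return data frame of manifest rows.
#' @export
read_manifest <- function(path) {
  if (!file.exists(path)) stop("manifest not found: ", path)
  m <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  missing <- setdiff(manifest_cols, names(m))
  if (length(missing))
    stop("manifest is missing required columns: ", paste(missing, collapse = ", "))
  per_wsi <- tapply(m$split, m$wsi_id, function(s) length(unique(s)))
  leaky <- names(per_wsi)[per_wsi > 1L]
  if (length(leaky))
    stop("slide(s) present in more than one split: ",
         paste(leaky, collapse = ", "))
  m
}

#' Load patch triplets referenced by manifest rows
#'
#' Scenes are rendered on the 8-bit intensity grid, so the stored 40x PNG is
#' bit-exact; by default the 10x/20x views are re-derived from it by area
#' averaging (preserving the exact co-registration invariant), while
#' `derive = FALSE` reads the stored, 8-bit-requantised views instead.
#'
#' @param manifest data frame from [read_manifest()].
#' @param base_dir dataset directory the paths are relative to.
#' @param derive recompute `img10`/`img20` from the 40x scene (default).
#' @return list with `triplets` and `labels` (0-based), as [thw_patches()].
#' @export
load_triplets <- function(manifest, base_dir, derive = TRUE) {
  triplets <- lapply(seq_len(nrow(manifest)), function(i) {
    r <- manifest[i, ]
    img40 <- png::readPNG(file.path(base_dir, r$path40))
    structure(list(img10 = if (derive) area_downsample(img40, 4L)
                           else png::readPNG(file.path(base_dir, r$path10)),
                   img20 = if (derive) area_downsample(img40, 2L)
                           else png::readPNG(file.path(base_dir, r$path20)),
                   img40 = img40,
                   patho_label = r$patho_label, wsi_id = r$wsi_id,
                   position = c(r$row, r$col)),
              class = "patch_triplet")
  })
  list(triplets = triplets, labels = manifest$patho_label,
       wsi_ids = manifest$wsi_id)
}

#' Write / read a predictions table
#'
#' Fixed CSV dialect (UTF-8, header, comma).  Columns: `id`, `true_label`,
#' `predicted_label`, then one probability column per class (`prob0` ...).
#' On read, probability rows not summing to 1 within 1e-4 trigger a warning.
#'
#' @param path CSV path.
#' @param ids item identifiers.
#' @param truth,pred 0-based labels.
#' @param probs `n x K` probability matrix.
#' @export
write_predictions <- function(path, ids, truth, pred, probs) {
  stopifnot(length(ids) == length(truth), length(truth) == length(pred),
            nrow(probs) == length(ids))
  df <- data.frame(id = ids, true_label = truth, predicted_label = pred)
  pr <- as.data.frame(probs)
  names(pr) <- paste0("prob", seq_len(ncol(probs)) - 1L)
  utils::write.csv(cbind(df, pr), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_predictions
#' @return data frame with attached `probs` matrix attribute.
#' @export
read_predictions <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("id", "true_label", "predicted_label")
  missing <- setdiff(need, names(df))
  if (length(missing))
    stop("predictions file missing columns: ", paste(missing, collapse = ", "))
  pcols <- grep("^prob[0-9]+$", names(df), value = TRUE)
  if (length(pcols)) {
    probs <- as.matrix(df[, pcols, drop = FALSE])
    bad <- abs(rowSums(probs) - 1) > 1e-4
    if (any(bad))
      warning(sum(bad), " probability row(s) do not sum to 1 within 1e-4")
    attr(df, "probs") <- probs
  }
  df
}

#' Write / read a slide feature matrix
#'
#' The matrix is stored as a little-endian double binary file with a JSON
#' sidecar (`<path>.json`) holding the dimensions, slide id, sampling seed
#' and source patch indices.
#'
#' @param M a [build_feature_matrix()] result.
#' @param path output path for the binary array.
#' @export
write_feature_matrix <- function(M, path) {
  con <- file(path, "wb")
  writeBin(as.numeric(M), con, size = 8L, endian = "little")
  close(con)
  jsonlite::write_json(list(nrow = nrow(M), ncol = ncol(M),
                            slide_id = attr(M, "slide_id"),
                            seed = attr(M, "seed"),
                            source_idx = attr(M, "source_idx")),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_feature_matrix
#' @return the restored feature matrix with attributes.
#' @export
read_feature_matrix <- function(path) {
  side <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  con <- file(path, "rb")
  x <- readBin(con, "numeric", n = side$nrow * side$ncol, size = 8L,
               endian = "little")
  close(con)
  structure(matrix(x, side$nrow, side$ncol),
            class = c("feature_matrix", "matrix", "array"),
            slide_id = side$slide_id, seed = side$seed,
            source_idx = side$source_idx)
}

# restore a thw_config from the YAML written by write_dataset
read_thw_config <- function(path) {
  y <- yaml::read_yaml(path)
  y$type_composition <- do.call(rbind, y$type_composition)
  do.call(thw_config, y[setdiff(names(y), character(0L))])
}
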