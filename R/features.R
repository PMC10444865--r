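#' Preprocessing configuration for nucleus images
#'
#' @param target_size Output size `c(height, width)` in pixels; fixed
#'   across a run because feature dimensionality of a flattened variant
#'   would depend on it.
#' @param background_fill Value assigned to out-of-mask pixels after
#'   normalization.
#' @return A `cspws_preproc`.
#' @export
preproc_config <- function(target_size = c(224, 224), background_fill = 0) {
  stopifnot(length(target_size) == 2, all(target_size >= 16))
  obj <- list(target_size = as.integer(target_size),
              background_fill = background_fill)
  class(obj) <- "cspws_preproc"
  obj
}

#' Preprocess a nucleus image for feature extraction
#'
#' Crops to the mask bounding box, min-max normalizes the in-mask values
#' to [0, 1] (a constant image maps to 0.5 by convention), fills the
#' background, and resizes to the target size with bilinear interpolation
#' (pixel-centre convention, no corner alignment).
#'
#' @param d_img A `cspws_d_image` or numeric matrix.
#' @param mask Logical matrix; defaults to the D image's own mask.
#' @param cfg A `cspws_preproc`.
#' @return Matrix `target_size[1] x target_size[2]` in [0, 1].
#' @export
preprocess_nucleus <- function(d_img, mask = NULL, cfg = preproc_config()) {
  vals <- if (inherits(d_img, "cspws_d_image")) d_img$d else d_img
  if (is.null(mask) && inherits(d_img, "cspws_d_image")) mask <- d_img$mask
  stopifnot(!is.null(mask))
  mask <- .as_mask(mask)
  if (!any(mask)) stop("empty mask")
  if (any(!is.finite(vals[mask]))) stop("non-finite in-mask values")
  idx <- which(mask, arr.ind = TRUE)
  rr <- range(idx[, 1])
  cc <- range(idx[, 2])
  sub <- vals[rr[1]:rr[2], cc[1]:cc[2], drop = FALSE]
  smask <- mask[rr[1]:rr[2], cc[1]:cc[2], drop = FALSE]
  mv <- sub[smask]
  lo <- min(mv)
  hi <- max(mv)
  out <- sub
  if (hi > lo) {
    out <- (sub - lo) / (hi - lo)
  } else {
    out[] <- 0.5
  }
  out[!smask] <- cfg$background_fill
  .bilinear_resize(out, cfg$target_size[1], cfg$target_size[2])
}

## Bilinear resize with pixel-centre sampling (align_corners = FALSE).
.bilinear_resize <- function(x, h_out, w_out) {
  h_in <- nrow(x)
  w_in <- ncol(x)
  sy <- (seq_len(h_out) - 0.5) * h_in / h_out - 0.5
  sx <- (seq_len(w_out) - 0.5) * w_in / w_out - 0.5
  y0 <- pmin(pmax(floor(sy), 0), h_in - 1)
  x0 <- pmin(pmax(floor(sx), 0), w_in - 1)
  y1 <- pmin(y0 + 1, h_in - 1)
  x1 <- pmin(x0 + 1, w_in - 1)
  fy <- pmin(pmax(sy - y0, 0), 1)
  fx <- pmin(pmax(sx - x0, 0), 1)
  a <- x[y0 + 1, x0 + 1, drop = FALSE]
  b <- x[y1 + 1, x0 + 1, drop = FALSE]
  cc <- x[y0 + 1, x1 + 1, drop = FALSE]
  d <- x[y1 + 1, x1 + 1, drop = FALSE]
  wy <- matrix(fy, h_out, w_out)
  wx <- matrix(fx, h_out, w_out, byrow = TRUE)
  a * (1 - wy) * (1 - wx) + b * wy * (1 - wx) + cc * (1 - wy) * wx +
    d * wy * wx
}

#' Aggregate cell features into one patient vector
#'
#' Multiple-instance aggregation: the elementwise mean and sample standard
#' deviation (n - 1) of the cell feature vectors are concatenated as
#' `[means, stds]`, giving a patient vector of length 2k. Invariant to the
#' order of cells; requires at least two cells.
#'
#' @param cell_features Matrix (cells x k) or list of length-k vectors.
#' @return Numeric vector of length 2k with an attribute `n_cells`.
#' @export
aggregate_patient <- function(cell_features) {
  if (is.list(cell_features)) cell_features <- do.call(rbind, cell_features)
  stopifnot(is.matrix(cell_features))
  n <- nrow(cell_features)
  if (n < 2) stop("at least 2 cells are required for the std block")
  mu <- colMeans(cell_features)
  sdv <- sqrt(pmax(colSums(sweep(cell_features, 2, mu)^2) / (n - 1), 0))
  out <- c(mu, sdv)
  names(out) <- c(paste0("f", seq_along(mu), "_mean"),
                  paste0("f", seq_along(sdv), "_sd"))
  attr(out, "n_cells") <- n
  out
}

#' Patient-level feature matrix for a cohort
#'
#' Streams over the cohort cell by cell: each cell's D image is read from
#' disk (when the manifest carries image paths) or rendered on the fly
#' from its recorded seed, preprocessed, passed through the backbone, and
#' aggregated per patient. No cohort-sized image store is ever
#' materialized.
#'
#' @param manifest A `cspws_manifest`.
#' @param backbone A `cspws_backbone`.
#' @param preproc A `cspws_preproc`.
#' @param qc Optional QC report (from [qc_report()]); cells with
#'   `keep == FALSE` are skipped.
#' @return A list with `features` (patients x 2k matrix), `labels`
#'   (factor, levels control/case), `patient_ids`, and `n_cells_used`.
#' @export
cohort_features <- function(manifest, backbone, preproc = preproc_config(),
                            qc = NULL) {
  if (!identical(backbone$pooling, "gap")) {
    stop("cohort_features() requires a pooling = \"gap\" backbone ",
         "(fixed feature dimensionality)")
  }
  cells <- manifest$cells
  if (!is.null(qc)) {
    keep_ids <- qc$cell_id[qc$keep]
    cells <- cells[cells$cell_id %in% keep_ids, , drop = FALSE]
  }
  pids <- manifest$patients$patient_id
  feat_rows <- vector("list", length(pids))
  used <- integer(length(pids))
  for (i in seq_along(pids)) {
    pc <- cells[cells$patient_id == pids[i], , drop = FALSE]
    if (nrow(pc) < 2) {
      stop("patient ", pids[i], " has fewer than 2 usable cells")
    }
    cf <- matrix(0, nrow(pc), backbone$k)
    for (j in seq_len(nrow(pc))) {
      if (!is.na(pc$image_path[j])) {
        dimg <- read_d_image(pc$image_path[j])
      } else {
        dimg <- render_d_image(pc$cell_mean_d[j], manifest$spec,
                               pc$render_seed[j])$d_image
      }
      img <- preprocess_nucleus(dimg, cfg = preproc)
      cf[j, ] <- extract_cell_features(img, backbone)
    }
    feat_rows[[i]] <- aggregate_patient(cf)
    used[i] <- nrow(pc)
  }
  features <- do.call(rbind, feat_rows)
  rownames(features) <- pids
  list(features = features,
       labels = factor(manifest$patients$group, levels = c("control", "case")),
       patient_ids = pids,
       n_cells_used = used)
}
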