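#' Segment nuclei in a D or brightfield image
#'
#' Automated stand-in for manual nucleus selection on synthetic images:
#' global Otsu threshold, connected-component labelling and hole filling,
#' returning one mask per component above the minimum area. `NaN` pixels
#' (the rendered background) are treated as background. A blank image
#' yields an empty list, not an error.
#'
#' @param img Numeric matrix; `NaN` allowed outside cells.
#' @param min_area_px Minimum component area in pixels.
#' @return List of logical masks, one per detected nucleus.
#' @export
segment_nuclei <- function(img, min_area_px = 100) {
  x <- img
  fin <- is.finite(x)
  if (!any(fin)) return(list())
  lo <- min(x[fin])
  hi <- max(x[fin])
  ## fill the (NaN) background well below the foreground range so the
  ## threshold separates background from cells, not structure within cells
  x[!fin] <- lo - max(hi - lo, 1e-6)
  if (hi == lo && all(fin)) return(list())  # constant image: nothing to segment
  rng <- range(x)
  xn <- (x - rng[1]) / (rng[2] - rng[1])
  thr <- EBImage::otsu(xn, range = c(0, 1))
  bw <- xn > thr
  bw <- EBImage::fillHull(EBImage::bwlabel(bw)) > 0
  lab <- EBImage::bwlabel(bw)
  n <- max(lab)
  if (n == 0) return(list())
  masks <- list()
  for (i in seq_len(n)) {
    m <- lab == i
    if (sum(m) >= min_area_px) masks[[length(masks) + 1]] <- m
  }
  masks
}

#' Quality-control configuration for segmented nuclei
#'
#' Thresholds standing in for the exclusion of outlier cells with deformed
#' shapes: area bounds, maximum eccentricity, minimum solidity, and a
#' border-contact rule. Defaults suit the generator's nucleus geometry at
#' 250 nm pixels.
#'
#' @param area_min_px,area_max_px Admissible mask area in pixels.
#' @param max_eccentricity Maximum moment-based eccentricity.
#' @param min_solidity Minimum ratio of mask area to convex-hull area.
#' @return A `cspws_qc_config`.
#' @export
qc_config <- function(area_min_px = 300, area_max_px = 4000,
                      max_eccentricity = 0.95, min_solidity = 0.90) {
  obj <- list(area_min_px = area_min_px, area_max_px = area_max_px,
              max_eccentricity = max_eccentricity,
              min_solidity = min_solidity)
  class(obj) <- "cspws_qc_config"
  obj
}

#' Quality-control verdict for one nucleus mask
#'
#' Pure function of the mask: computes area, moment eccentricity, solidity
#' (pixel count over convex-hull pixel count) and border contact, and
#' keeps the cell iff all thresholds are met.
#'
#' @param mask Logical matrix with at least one TRUE pixel.
#' @param config A `cspws_qc_config`.
#' @return A `cspws_cell_qc`: list with `area_px`, `eccentricity`,
#'   `solidity`, `touches_border`, `keep`, `reject_reason` (empty string
#'   iff kept).
#' @export
qc_filter <- function(mask, config = qc_config()) {
  mask <- .as_mask(mask)
  area <- sum(mask)
  if (area == 0) stop("empty mask")
  idx <- which(mask, arr.ind = TRUE)
  ecc <- .mask_eccentricity(idx)
  sol <- .mask_solidity(idx)
  touches <- any(idx[, 1] == 1 | idx[, 1] == nrow(mask) |
                 idx[, 2] == 1 | idx[, 2] == ncol(mask))
  reasons <- character()
  if (area < config$area_min_px) reasons <- c(reasons, "area_small")
  if (area > config$area_max_px) reasons <- c(reasons, "area_large")
  if (ecc > config$max_eccentricity) reasons <- c(reasons, "eccentricity")
  if (sol < config$min_solidity) reasons <- c(reasons, "solidity")
  if (touches) reasons <- c(reasons, "border")
  obj <- list(area_px = area, eccentricity = ecc, solidity = sol,
              touches_border = touches, keep = length(reasons) == 0,
              reject_reason = paste(reasons, collapse = ";"))
  class(obj) <- "cspws_cell_qc"
  obj
}

.mask_eccentricity <- function(idx) {
  y <- idx[, 1] - mean(idx[, 1])
  x <- idx[, 2] - mean(idx[, 2])
  ## central second moments with the pixel's own unit variance
  m <- matrix(c(mean(y * y) + 1 / 12, mean(x * y),
                mean(x * y), mean(x * x) + 1 / 12), 2, 2)
  ev <- eigen(m, symmetric = TRUE, only.values = TRUE)$values
  sqrt(max(0, 1 - ev[2] / ev[1]))
}

.mask_solidity <- function(idx) {
  if (nrow(idx) < 4) return(1)
  pts <- cbind(idx[, 2], idx[, 1])
  hull <- grDevices::chull(pts)
  hx <- pts[hull, 1]
  hy <- pts[hull, 2]
  rng_x <- range(pts[, 1])
  rng_y <- range(pts[, 2])
  gx <- rng_x[1]:rng_x[2]
  gy <- rng_y[1]:rng_y[2]
  gg <- expand.grid(x = gx, y = gy)
  inside <- .in_polygon(gg$x, gg$y, hx, hy)
  hull_px <- sum(inside)
  min(1, nrow(idx) / max(hull_px, 1))
}

## Even-odd point-in-polygon with on-edge tolerance.
.in_polygon <- function(px, py, vx, vy) {
  n <- length(vx)
  inside <- rep(FALSE, length(px))
  j <- n
  for (i in seq_len(n)) {
    crosses <- ((vy[i] > py) != (vy[j] > py)) &
      (px < (vx[j] - vx[i]) * (py - vy[i]) / (vy[j] - vy[i]) + vx[i] + 1e-9)
    inside <- xor(inside, crosses)
    j <- i
  }
  inside
}

#' Cohort-level QC report
#'
#' Applies [qc_filter()] to each cell's mask (from disk or rendered on the
#' fly) and returns one row per cell.
#'
#' @param manifest A `cspws_manifest`.
#' @param config A `cspws_qc_config`.
#' @return Data frame with cell_id, QC metrics, `keep` and
#'   `reject_reason`.
#' @export
qc_report <- function(manifest, config = qc_config()) {
  cells <- manifest$cells
  out <- vector("list", nrow(cells))
  for (j in seq_len(nrow(cells))) {
    mask <- if (!is.na(cells$mask_path[j])) {
      read_mask_png(cells$mask_path[j])
    } else {
      render_d_image(cells$cell_mean_d[j], manifest$spec,
                     cells$render_seed[j])$mask
    }
    q <- qc_filter(mask, config)
    out[[j]] <- data.frame(cell_id = cells$cell_id[j],
                           patient_id = cells$patient_id[j],
                           area_px = q$area_px, eccentricity = q$eccentricity,
                           solidity = q$solidity,
                           touches_border = q$touches_border,
                           keep = q$keep, reject_reason = q$reject_reason,
                           stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}
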