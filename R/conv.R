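## Minimal deterministic convolutional engine (VGG-style 3x3 conv stacks,
## ReLU, 2x2 max pooling) built on BLAS matrix products via im2col. Used
## for feature extraction only; no training.

## 3x3 same-padding convolution + ReLU. x: H x W x Cin array;
## wmat: (9 * Cin) x Cout, rows ordered offset-major then channel.
.conv3x3_relu <- function(x, wmat) {
  h <- dim(x)[1]
  w <- dim(x)[2]
  cin <- dim(x)[3]
  xp <- array(0, c(h + 2, w + 2, cin))
  xp[2:(h + 1), 2:(w + 1), ] <- x
  cols <- vector("list", 9)
  i <- 1
  for (dy in 0:2) {
    for (dx in 0:2) {
      blk <- xp[dy + seq_len(h), dx + seq_len(w), , drop = FALSE]
      dim(blk) <- c(h * w, cin)
      cols[[i]] <- blk
      i <- i + 1
    }
  }
  x2 <- do.call(cbind, cols)
  y <- x2 %*% wmat
  y[y < 0] <- 0
  dim(y) <- c(h, w, ncol(wmat))
  y
}

## 2x2 max pooling, stride 2, floor semantics on odd dimensions.
.maxpool2 <- function(x) {
  h <- dim(x)[1] %/% 2
  w <- dim(x)[2] %/% 2
  a <- x[seq_len(h) * 2 - 1, seq_len(w) * 2 - 1, , drop = FALSE]
  b <- x[seq_len(h) * 2, seq_len(w) * 2 - 1, , drop = FALSE]
  cc <- x[seq_len(h) * 2 - 1, seq_len(w) * 2, , drop = FALSE]
  d <- x[seq_len(h) * 2, seq_len(w) * 2, , drop = FALSE]
  pmax(a, b, cc, d)
}

#' Convolutional backbone specification
#'
#' A VGG16-layout feature extractor: five 3x3 convolution blocks (2, 2, 3,
#' 3, 3 layers) with 2x2 max pooling between blocks, and feature taps at
#' the final convolutional layer of blocks 2 through 5 followed by
#' per-channel global average pooling. With the full layer widths (64,
#' 128, 256, 512, 512) the concatenated feature length is k = 128 + 256 +
#' 512 + 512 = 1408.
#'
#' `weights_mode = "seeded_random"` draws fixed He-scaled Gaussian weights
#' from `seed` (zero biases), giving a deterministic random-projection
#' feature extractor that requires no external weight files; random conv
#' projections preserve the coarse intensity statistics that downstream
#' selection feeds on. `"pretrained"` is accepted as a declaration but
#' requires weights supplied via `weights`, since no pretrained weights
#' are bundled.
#'
#' @param width_mult Multiplier on the layer widths (e.g. 0.25 for a light
#'   profile with k = 352).
#' @param weights_mode `"seeded_random"` or `"pretrained"`.
#' @param seed Integer seed for `"seeded_random"` weights.
#' @param tap_blocks Blocks whose final conv layer is tapped (default 2:5).
#' @param pooling `"gap"` (per-channel global average pooling, fixed
#'   feature length `k`) or `"flatten"` (full activation maps; feature
#'   length then depends on the input size, and cohort-level helpers
#'   require `"gap"`).
#' @param weights Optional externally supplied weight list for
#'   `"pretrained"`.
#' @return A `cspws_backbone` with the realized weight matrices.
#' @export
backbone_spec <- function(width_mult = 1,
                          weights_mode = c("seeded_random", "pretrained"),
                          seed = 1, tap_blocks = 2:5,
                          pooling = c("gap", "flatten"), weights = NULL) {
  weights_mode <- match.arg(weights_mode)
  pooling <- match.arg(pooling)
  base_widths <- c(64, 128, 256, 512, 512)
  layers_per_block <- c(2, 2, 3, 3, 3)
  widths <- pmax(1L, as.integer(round(base_widths * width_mult)))
  stopifnot(all(tap_blocks %in% 1:5))
  if (weights_mode == "pretrained") {
    if (is.null(weights)) {
      stop("no pretrained weights are bundled; supply them via `weights` ",
           "or use weights_mode = \"seeded_random\"")
    }
    wts <- weights
  } else {
    set.seed(seed)
    wts <- list()
    cin <- 3
    for (b in 1:5) {
      for (l in seq_len(layers_per_block[b])) {
        cout <- widths[b]
        wts[[length(wts) + 1]] <-
          matrix(stats::rnorm(9 * cin * cout, sd = sqrt(2 / (9 * cin))),
                 9 * cin, cout)
        cin <- cout
      }
    }
  }
  obj <- list(widths = widths, layers_per_block = layers_per_block,
              tap_blocks = sort(tap_blocks), weights_mode = weights_mode,
              pooling = pooling, seed = seed, weights = wts,
              k = if (pooling == "gap") sum(widths[sort(tap_blocks)]) else NA_integer_)
  class(obj) <- "cspws_backbone"
  obj
}

#' @export
print.cspws_backbone <- function(x, ...) {
  cat(sprintf("conv backbone: widths %s, taps at blocks %s, k = %d, %s (seed %d)\n",
              paste(x$widths, collapse = "/"),
              paste(x$tap_blocks, collapse = ","), x$k, x$weights_mode,
              x$seed))
  invisible(x)
}

#' Extract convolutional features from one nucleus image
#'
#' Runs the preprocessed image through the backbone's conv stacks; at each
#' tap point the activation map is reduced by per-channel global average
#' pooling and the pooled vectors are concatenated in block order.
#' Deterministic given the backbone weights.
#'
#' @param image Matrix `H x W` (grayscale, replicated across the three
#'   input channels) or array `H x W x 3`.
#' @param backbone A `cspws_backbone`.
#' @return Numeric feature vector of length `backbone$k`.
#' @export
extract_cell_features <- function(image, backbone) {
  stopifnot(inherits(backbone, "cspws_backbone"))
  if (is.matrix(image)) {
    x <- array(image, c(dim(image), 3))
  } else {
    stopifnot(length(dim(image)) == 3, dim(image)[3] == 3)
    x <- image
  }
  if (any(!is.finite(x))) stop("image must be finite (preprocess first)")
  feats <- list()
  li <- 1
  for (b in 1:5) {
    for (l in seq_len(backbone$layers_per_block[b])) {
      x <- .conv3x3_relu(x, backbone$weights[[li]])
      li <- li + 1
    }
    if (b %in% backbone$tap_blocks) {
      if (identical(backbone$pooling, "flatten")) {
        feats[[length(feats) + 1]] <- as.numeric(x)
      } else {
        m <- x
        dim(m) <- c(dim(x)[1] * dim(x)[2], dim(x)[3])
        feats[[length(feats) + 1]] <- colMeans(m)
      }
    }
    if (b < 5) x <- .maxpool2(x)
  }
  unlist(feats, use.names = FALSE)
}
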