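#' Compact CNN architecture specification
#'
#' The compact ERP-classification network in two variants: `"eeg"` consumes
#' raw band-filtered epochs (22 channels x 250 samples) and `"pli"` consumes
#' 22 x 22 connectivity matrices. Both share the same layer plan -- bias-free
#' temporal convolution, batch normalization, max-norm-constrained depthwise
#' spatial convolution over all channels, batch normalization + ELU, average
#' pooling, dropout, separable convolution (depthwise temporal + pointwise),
#' batch normalization + ELU, average pooling to width 1, dropout, and a 1x1
#' classification convolution -- and differ only in input width, first pooling
#' width (halved for the pli variant so the narrower input survives) and the
#' separable kernel length.
#'
#' @param variant "pli" or "eeg".
#' @param n_channels Number of scalp channels (spatial height), default 22.
#' @param input_width Input width: 22 (pli) or 250 (eeg) by default.
#' @param temporal_filters F1, number of temporal filters (default 8).
#' @param depth_multiplier D, spatial filters learned per temporal filter
#'   (default 2).
#' @param separable_filters F2, pointwise output maps (default 16).
#' @param temporal_kernel Temporal kernel length (default 125, half a second
#'   at 250 Hz).
#' @param pool1_width First average-pooling width: 2 (pli) or 4 (eeg).
#' @param sep_kernel Depthwise kernel length of the separable block: 22 (pli)
#'   or 16 (eeg).
#' @param pool2_width Second average-pooling width: 12 (pli, collapses the
#'   remaining trace to width 1) or 8 (eeg, followed by a global mean).
#' @param dropout_rate Dropout probability (default 0.5).
#' @param n_classes Number of output classes (default 3).
#' @param max_norm Max-norm constraint on each depthwise spatial filter
#'   (default 1).
#' @return An `architecture_spec` list including the derived layer widths.
#' @export
architecture_spec <- function(variant = c("pli", "eeg"), n_channels = 22L,
                              input_width = NULL, temporal_filters = 8L,
                              depth_multiplier = 2L, separable_filters = 16L,
                              temporal_kernel = 125L, pool1_width = NULL,
                              sep_kernel = NULL, pool2_width = NULL,
                              dropout_rate = 0.5, n_classes = 3L,
                              max_norm = 1.0) {
  variant <- match.arg(variant)
  input_width <- input_width %||% if (variant == "pli") 22L else 250L
  pool1_width <- pool1_width %||% if (variant == "pli") 2L else 4L
  sep_kernel  <- sep_kernel  %||% if (variant == "pli") 22L else 16L
  w1 <- input_width %/% pool1_width
  w2 <- w1 + 1L - (sep_kernel %% 2L)   # "same" padding: even kernels gain 1
  pool2_width <- pool2_width %||% if (variant == "pli") w2 else 8L
  abort_if(w1 < 1, sprintf(
    "pool1_width %d does not divide input width %d into a nonzero trace",
    pool1_width, input_width))
  abort_if(w2 %/% pool2_width < 1, sprintf(
    "pool2_width %d exceeds the remaining trace width %d", pool2_width, w2))
  m2 <- temporal_filters * depth_multiplier
  structure(list(variant = variant, n_channels = as.integer(n_channels),
                 input_width = as.integer(input_width),
                 F1 = as.integer(temporal_filters),
                 D = as.integer(depth_multiplier),
                 F2 = as.integer(separable_filters),
                 M2 = as.integer(m2),
                 temporal_kernel = as.integer(temporal_kernel),
                 pool1_width = as.integer(pool1_width),
                 sep_kernel = as.integer(sep_kernel),
                 pool2_width = as.integer(pool2_width),
                 w_after_pool1 = as.integer(w1),
                 w_after_sep = as.integer(w2),
                 w_after_pool2 = as.integer(w2 %/% pool2_width),
                 dropout_rate = dropout_rate,
                 n_classes = as.integer(n_classes),
                 max_norm = max_norm),
            class = "architecture_spec")
}

# Index map of a 1-D "same"-padded convolution as a Win x Wout matrix:
# out[j] = sum_k K[k] * x[i], i = j + k - 1 - pad.
make_conv_index <- function(w_in, klen, pad = klen %/% 2L) {
  w_out <- w_in + 2L * pad - klen + 1L
  k <- rep(seq_len(klen), times = w_out)
  j <- rep(seq_len(w_out), each = klen)
  i <- j + k - 1L - pad
  ok <- i >= 1L & i <= w_in
  list(i = i[ok], j = j[ok], k = k[ok], w_in = w_in, w_out = w_out, klen = klen)
}

conv_index_matrix <- function(K, ci) {
  Tm <- matrix(0, ci$w_in, ci$w_out)
  Tm[cbind(ci$i, ci$j)] <- K[ci$k]
  Tm
}

conv_index_grad <- function(dT, ci) {
  g <- numeric(ci$klen)
  vals <- dT[cbind(ci$i, ci$j)]
  for (k in seq_len(ci$klen)) g[k] <- sum(vals[ci$k == k])
  g
}

#' Build (initialize) a compact CNN model
#'
#' Weights use scaled-normal initialization; batch-normalization scales start
#' at 1 and shifts at 0. Identical seeds give identical initial weights.
#'
#' @param spec An [architecture_spec()].
#' @param seed Integer seed for weight initialization.
#' @return A `cnn_model`: list with `spec`, `params`, batch-norm running
#'   statistics, and precomputed convolution index maps.
#' @export
build_model <- function(spec, seed = 1L) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(as.integer(seed))
  gi <- function(nr, nc) matrix(stats::rnorm(nr * nc, sd = sqrt(2 / (nr + nc))),
                                nr, nc)
  p <- list(
    conv1_K = gi(spec$temporal_kernel, spec$F1),
    bn1_gamma = rep(1, spec$F1), bn1_beta = rep(0, spec$F1),
    dw_W = gi(spec$n_channels, spec$M2),
    bn2_gamma = rep(1, spec$M2), bn2_beta = rep(0, spec$M2),
    sep_K = gi(spec$sep_kernel, spec$M2),
    pw_W = gi(spec$M2, spec$F2),
    bn3_gamma = rep(1, spec$F2), bn3_beta = rep(0, spec$F2),
    cls_W = gi(spec$F2, spec$n_classes),
    cls_b = rep(0, spec$n_classes)
  )
  bn_state <- list(
    bn1 = list(mean = rep(0, spec$F1), var = rep(1, spec$F1)),
    bn2 = list(mean = rep(0, spec$M2), var = rep(1, spec$M2)),
    bn3 = list(mean = rep(0, spec$F2), var = rep(1, spec$F2)))
  structure(list(spec = spec, params = p, bn = bn_state,
                 ci1 = make_conv_index(spec$input_width, spec$temporal_kernel),
                 ci_sep = make_conv_index(spec$w_after_pool1, spec$sep_kernel)),
            class = "cnn_model")
}

#' Per-layer trainable parameter counts
#'
#' One row per layer in forward order, mirroring the architecture table
#' (convolutions, batch normalizations, activation/pooling/dropout layers
#' with zero parameters, and the final classification convolution).
#'
#' @param model A `cnn_model`.
#' @return data.frame with columns layer, output_shape (for batch 32) and
#'   params; total in `attr(, "total")`.
#' @export
count_parameters <- function(model) {
  s <- model$spec
  shp <- function(maps, h, w) sprintf("[32, %d, %d, %d]", maps, h, w)
  rows <- list(
    c("conv_temporal",        shp(s$F1, s$n_channels, s$input_width),
      s$temporal_kernel * s$F1),
    c("batchnorm_1",          shp(s$F1, s$n_channels, s$input_width), 2 * s$F1),
    c("conv_spatial_depthwise_constrained", shp(s$M2, 1, s$input_width),
      s$n_channels * s$M2),
    c("batchnorm_2",          shp(s$M2, 1, s$input_width), 2 * s$M2),
    c("elu_1",                shp(s$M2, 1, s$input_width), 0),
    c("avgpool_1",            shp(s$M2, 1, s$w_after_pool1), 0),
    c("dropout_1",            shp(s$M2, 1, s$w_after_pool1), 0),
    c("conv_separable_depthwise", shp(s$M2, 1, s$w_after_sep),
      s$sep_kernel * s$M2),
    c("conv_separable_pointwise", shp(s$F2, 1, s$w_after_sep), s$M2 * s$F2),
    c("batchnorm_3",          shp(s$F2, 1, s$w_after_sep), 2 * s$F2),
    c("elu_2",                shp(s$F2, 1, s$w_after_sep), 0),
    c("avgpool_2",            shp(s$F2, 1, 1), 0),
    c("dropout_2",            shp(s$F2, 1, 1), 0),
    c("conv_classifier",      shp(s$n_classes, 1, 1),
      s$F2 * s$n_classes + s$n_classes),
    c("log_softmax",          shp(s$n_classes, 1, 1), 0))
  tbl <- data.frame(layer = vapply(rows, `[`, "", 1),
                    output_shape = vapply(rows, `[`, "", 2),
                    params = as.integer(vapply(rows, `[`, "", 3)),
                    stringsAsFactors = FALSE)
  attr(tbl, "total") <- sum(tbl$params)
  tbl
}

#' @export
print.cnn_model <- function(x, ...) {
  tbl <- count_parameters(x)
  cat(sprintf("compact CNN (%s variant): %d trainable parameters\n",
              x$spec$variant, attr(tbl, "total")))
  print(tbl, row.names = FALSE)
  invisible(x)
}
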