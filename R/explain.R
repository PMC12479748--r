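# Grad-CAM heatmaps and quantitative region-attention metrics.
#
# Grad-CAM: per-channel weights are the spatial mean of the gradient of the
# target-class score (pre-softmax logit) with respect to the chosen
# convolutional layer's activations; the map is the rectified weighted channel
# sum, bilinearly upsampled to the input grid and min-max normalized to
# [0, 1]. The two metrics mirror the evaluation of heatmap quality against
# expected diagnostic zones: Region Attention Accuracy (does the most
# activated region hit an expected zone?) and overlap of the activated area
# with the QRS zone.

#' Combine layer activations and gradients into a Grad-CAM heatmap
#'
#' @param activations array H x W x C (a spatial layer's output).
#' @param gradients array of the same shape: d(score)/d(activations).
#' @param out_shape integer c(H, W) of the input grid to upsample to
#'   (default: the activation grid itself).
#' @return matrix `out_shape` in \[0, 1\].
#' @export
grad_cam_map <- function(activations, gradients, out_shape = dim(activations)[1:2]) {
  if (!identical(dim(activations), dim(gradients))) {
    abort_field("gradients", "must match the activation shape")
  }
  if (length(dim(activations)) == 2) {
    activations <- array(activations, c(dim(activations), 1))
    gradients <- array(gradients, c(dim(gradients), 1))
  }
  if (length(dim(activations)) != 3) {
    abort_field("activations", "layer must have spatial extent (H x W x C)")
  }
  alpha <- apply(gradients, 3, mean)
  cam <- matrix(0, dim(activations)[1], dim(activations)[2])
  for (ch in seq_along(alpha)) cam <- cam + alpha[ch] * activations[, , ch]
  cam <- pmax(cam, 0)
  if (!identical(as.integer(out_shape), as.integer(dim(cam)))) {
    cam <- t(EBImage::imageData(EBImage::resize(EBImage::Image(t(cam)),
                                                w = out_shape[2], h = out_shape[1],
                                                filter = "bilinear")))
  }
  rng <- range(cam)
  if (diff(rng) < .Machine$double.eps) {
    warning("constant Grad-CAM map: returning all zeros")
    return(matrix(0, out_shape[1], out_shape[2]))
  }
  (cam - rng[1]) / diff(rng)
}

#' Grad-CAM heatmap for a trained spectrogram classifier
#'
#' @param model a `subsystem2_model`.
#' @param input a 224 x 224 (x3) spectrogram image.
#' @param target_class class name or index; defaults to the predicted class
#'   (the standard convention: explain the decision the model actually made).
#' @param layer `"conv3"` (default, the last convolutional layer), `"conv2"`,
#'   or `"conv1"`.
#' @return matrix `nrow(input) x ncol(input)` in \[0, 1\].
#' @export
grad_cam <- function(model, input, target_class = NULL,
                     layer = c("conv3", "conv2", "conv1")) {
  layer <- match.arg(layer)
  if (!inherits(model, "subsystem2_model")) {
    abort_field("model", "must be a subsystem2_model")
  }
  x28 <- s2_input(model, input)
  fw <- s2_forward(model$params, x28)
  k <- if (is.null(target_class)) which.max(fw$probs)
       else if (is.character(target_class)) match(target_class, model$levels)
       else as.integer(target_class)
  if (is.na(k)) abort_field("target_class", "unknown class")
  # d(logit_k)/d(layer activations) via the analytic backward pass
  dlogits <- rep(0, length(fw$probs)); dlogits[k] <- 1
  p <- model$params
  dgap <- drop(p$head$W %*% dlogits)
  n_pix <- prod(dim(fw$cache$a3)[1:2])
  dA3 <- array(rep(dgap / n_pix, each = n_pix), dim(fw$cache$a3))
  if (layer == "conv3") {
    A <- fw$cache$a3; G <- dA3
  } else {
    dC3 <- dA3 * (fw$cache$c3$out > 0)
    b3 <- conv_backward(dC3, fw$cache$c3, p$conv3$W)
    if (layer == "conv2") {
      A <- fw$cache$a2; G <- b3$dx
    } else {
      dC2 <- b3$dx * (fw$cache$c2$out > 0)
      b2 <- conv_backward(dC2, fw$cache$c2, p$conv2$W)
      dP1 <- pool2_backward(b2$dx, fw$cache$p1)
      A <- fw$cache$a1; G <- dP1
    }
  }
  grad_cam_map(A, G, out_shape = dim(input)[1:2])
}

#' Rasterize labeled zone boxes to a mask
#'
#' @param boxes list of zones, each `list(label, row_min, row_max, col_min,
#'   col_max)` in input (heatmap) coordinates.
#' @param shape integer c(H, W).
#' @return logical matrix (union of all boxes).
#' @export
zones_to_mask <- function(boxes, shape) {
  m <- matrix(FALSE, shape[1], shape[2])
  for (b in boxes) {
    if (is.null(b$label) || !nzchar(b$label)) abort_field("label", "must be non-empty")
    r <- max(1, b$row_min):min(shape[1], b$row_max)
    c <- max(1, b$col_min):min(shape[2], b$col_max)
    m[r, c] <- TRUE
  }
  m
}

#' Map ground-truth QRS windows into spectrogram-image zones
#'
#' Time-domain QRS sample windows are carried through the audio chain
#' (trace rate -> audio rate -> STFT frame = sample / hop_length) and then
#' scaled to image columns; the frequency extent spans all rows.
#'
#' @param qrs_windows two-column matrix of sample-index windows (at
#'   `trace_rate`).
#' @param trace_rate the trace's sampling rate (Hz).
#' @param cfg the [spectrogram_config()] used for the image.
#' @param n_frames pre-resize frame count (attribute of
#'   [spectrogram_image()]).
#' @param size image side length (default 224).
#' @return list of zone boxes (see [zones_to_mask()]).
#' @export
qrs_zones_to_image <- function(qrs_windows, trace_rate, cfg, n_frames,
                               size = 224L) {
  scale <- cfg$sampling_rate / trace_rate
  apply(qrs_windows, 1, function(wd) {
    f0 <- (wd[1] * scale) / cfg$hop_length
    f1 <- (wd[2] * scale) / cfg$hop_length
    list(label = "QRS",
         row_min = 1L, row_max = size,
         col_min = max(1L, floor(f0 / n_frames * size)),
         col_max = min(size, ceiling(f1 / n_frames * size)))
  })
}

# 8-connected region of the heatmap maximum among cells >= threshold.
peak_region <- function(heatmap, threshold) {
  mask <- heatmap >= threshold
  peak <- which.max(heatmap)
  if (!mask[peak]) mask[peak] <- TRUE   # the max always belongs to its region
  comp <- matrix(0L, nrow(heatmap), ncol(heatmap))
  comp[mask] <- 1L
  h <- nrow(comp)
  lab <- matrix(FALSE, nrow(comp), ncol(comp))
  queue <- peak; lab[peak] <- TRUE
  while (length(queue)) {
    cur <- queue; queue <- integer(0)
    r <- (cur - 1L) %% h + 1L; c <- (cur - 1L) %/% h + 1L
    for (dr in -1:1) for (dc in -1:1) {
      if (dr == 0 && dc == 0) next
      nr <- r + dr; nc <- c + dc
      ok <- nr >= 1 & nr <= h & nc >= 1 & nc <= ncol(comp)
      ni <- (nc[ok] - 1L) * h + nr[ok]
      ni <- ni[comp[ni] == 1L & !lab[ni]]
      if (length(ni)) { lab[ni] <- TRUE; queue <- c(queue, ni) }
    }
  }
  lab
}

#' Region Attention Accuracy
#'
#' A sample is a hit iff the connected region containing the heatmap's
#' maximum (cells at or above `activation_threshold`) intersects any expected
#' zone. Returns the hit percentage.
#'
#' @param heatmaps list of \[0, 1\] heatmap matrices.
#' @param annotations list (one per heatmap) of zone-box lists (see
#'   [zones_to_mask()]).
#' @param activation_threshold cells at or above this count as activated.
#' @return percentage in \[0, 100\].
#' @export
region_attention_accuracy <- function(heatmaps, annotations,
                                      activation_threshold = 0.5) {
  if (length(heatmaps) == 0) stop("empty sample set", call. = FALSE)
  if (length(heatmaps) != length(annotations)) {
    abort_field("annotations", "one annotation set per heatmap required")
  }
  hits <- vapply(seq_along(heatmaps), function(i) {
    region <- peak_region(heatmaps[[i]], activation_threshold)
    mask <- zones_to_mask(annotations[[i]], dim(heatmaps[[i]]))
    any(region & mask)
  }, logical(1))
  100 * mean(hits)
}

#' Overlap of the activated heatmap area with the QRS zone
#'
#' `100 * |activated ∩ QRS| / |activated|` where activated cells are those at
#' or above `activation_threshold`. Returns 0 with a warning when no cell
#' passes the threshold.
#'
#' @param heatmap \[0, 1\] matrix.
#' @param qrs_zone_mask logical matrix of the same shape.
#' @param activation_threshold activation cutoff.
#' @return percentage in \[0, 100\].
#' @export
qrs_overlap <- function(heatmap, qrs_zone_mask, activation_threshold = 0.5) {
  if (!identical(dim(heatmap), dim(qrs_zone_mask))) {
    abort_field("qrs_zone_mask", "shape must match the heatmap")
  }
  act <- heatmap >= activation_threshold
  if (!any(act)) {
    warning("no cell passes the activation threshold: overlap undefined, returning 0")
    return(0)
  }
  100 * sum(act & qrs_zone_mask) / sum(act)
}

#' Summarize per-sample region metrics as mean and sample sd
#'
#' @param records data.frame (or named list of numeric vectors) of per-sample
#'   metric values.
#' @return data.frame with `metric`, `mean`, `sd` (sd omitted with a warning
#'   when n < 2).
#' @export
summarize_region_metrics <- function(records) {
  records <- as.data.frame(records)
  n <- nrow(records)
  if (n < 2) {
    warning("fewer than 2 samples: sd omitted")
    return(data.frame(metric = names(records),
                      mean = vapply(records, mean, numeric(1)),
                      sd = NA_real_, row.names = NULL))
  }
  data.frame(metric = names(records),
             mean = vapply(records, mean, numeric(1)),
             sd = vapply(records, stats::sd, numeric(1)),
             row.names = NULL)
}

#' Sign-flip permutation test that mean overlap exceeds the zone area fraction
#'
#' For each sample the excess `overlap_i - 100 * area_fraction_i` is computed;
#' the one-sided p-value is estimated by randomly flipping the signs of the
#' excesses (the null of no systematic attention toward the zone).
#'
#' @param overlaps per-sample QRS-overlap percentages.
#' @param area_fractions per-sample QRS-zone area fractions (0..1).
#' @param n_perm permutation count.
#' @param seed integer seed.
#' @return list with `statistic` (mean excess), `p_value`.
#' @export
overlap_permutation_test <- function(overlaps, area_fractions, n_perm = 2000,
                                     seed = 1L) {
  excess <- overlaps - 100 * area_fractions
  stat <- mean(excess)
  set.seed(seed)
  null <- replicate(n_perm, mean(excess * sample(c(-1, 1), length(excess),
                                                 replace = TRUE)))
  list(statistic = stat,
       p_value = (1 + sum(null >= stat)) / (n_perm + 1))
}
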