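# ECG plot-image digitization: grayscale -> Gaussian blur -> adaptive
# threshold -> largest 8-connected component -> column-wise amplitude
# extraction. Coordinate convention (used everywhere): row 1 = image top,
# amplitude increases upward (amplitude = height - row in 0-based pixels),
# columns map to time left -> right.

#' Digitizer configuration
#'
#' @param blur_kernel odd Gaussian kernel size in pixels (>= 3).
#' @param blur_sigma Gaussian standard deviation in pixels.
#' @param adaptive_block_size odd local-mean block size in pixels (>= 3).
#' @param adaptive_offset intensity offset (0–255 scale): a pixel is
#'   foreground iff its polarity-adjusted intensity exceeds the local block
#'   mean by more than this.
#' @param trace_polarity `"dark_on_light"` (default) or `"light_on_dark"`.
#' @param column_reducer how to reduce a column's foreground rows to one row:
#'   `"mean_row"` (default, robust to trace thickness), `"median_row"`, or
#'   `"topmost_row"`.
#' @param gap_fill how to fill columns with no foreground:
#'   `"linear_interpolation"` (default) or `"hold_last"`.
#' @return A `digitizer_config` object.
#' @export
digitizer_config <- function(blur_kernel = 3, blur_sigma = 1,
                             adaptive_block_size = 31, adaptive_offset = 10,
                             trace_polarity = c("dark_on_light", "light_on_dark"),
                             column_reducer = c("mean_row", "median_row", "topmost_row"),
                             gap_fill = c("linear_interpolation", "hold_last")) {
  structure(list(blur_kernel = check_odd(blur_kernel, "blur_kernel"),
                 blur_sigma = check_number(blur_sigma, "blur_sigma", 1e-9),
                 adaptive_block_size = check_odd(adaptive_block_size, "adaptive_block_size"),
                 adaptive_offset = check_number(adaptive_offset, "adaptive_offset", 0),
                 trace_polarity = match.arg(trace_polarity),
                 column_reducer = match.arg(column_reducer),
                 gap_fill = match.arg(gap_fill)),
            class = "digitizer_config")
}

#' Convert an image to single-channel grayscale
#'
#' 3-channel inputs are reduced with the standard luminance weights
#' (0.299, 0.587, 0.114); grayscale inputs are returned unchanged.
#'
#' @param img numeric matrix (H x W) or array (H x W x 3), intensities 0–255.
#' @return numeric matrix H x W.
#' @export
to_grayscale <- function(img) {
  if (length(img) == 0) abort_field("img", "must be non-empty")
  if (is.matrix(img)) return(img)
  if (is.array(img) && length(dim(img)) == 3 && dim(img)[3] == 1) {
    return(img[, , 1, drop = TRUE])
  }
  if (is.array(img) && length(dim(img)) == 3 && dim(img)[3] == 3) {
    g <- 0.299 * img[, , 1] + 0.587 * img[, , 2] + 0.114 * img[, , 3]
    return(matrix(g, dim(img)[1], dim(img)[2]))
  }
  abort_field("img", "must be an H x W matrix or H x W x {1,3} array")
}

# Box-filter local mean with replicated borders, used by the adaptive
# threshold; block is odd.
local_mean <- function(m, block) {
  h <- nrow(m); w <- ncol(m); half <- block %/% 2
  # pad by edge replication
  ri <- pmin(pmax(seq(1 - half, h + half), 1L), h)
  ci <- pmin(pmax(seq(1 - half, w + half), 1L), w)
  p <- m[ri, ci]
  cs <- apply(p, 2, cumsum)
  rowsum <- cs[(half * 2 + 1):nrow(p), ] - rbind(0, cs[seq_len(nrow(p) - half * 2 - 1), ])
  cs2 <- t(apply(rowsum, 1, cumsum))
  total <- cs2[, (half * 2 + 1):ncol(p)] - cbind(0, cs2[, seq_len(ncol(p) - half * 2 - 1)])
  total / (block * block)
}

#' Binarize a grayscale ECG image
#'
#' Gaussian blur followed by a local-mean adaptive threshold. After polarity
#' adjustment (dark-on-light images are inverted so the trace is bright), a
#' pixel is foreground iff its blurred intensity exceeds its local block mean
#' by more than `adaptive_offset`.
#'
#' @param gray numeric matrix, intensities 0–255.
#' @param cfg a [digitizer_config()].
#' @return binary matrix in \{0, 1\}.
#' @export
binarize <- function(gray, cfg = digitizer_config()) {
  if (!is.matrix(gray)) abort_field("gray", "must be a single-channel matrix")
  if (cfg$adaptive_block_size > min(dim(gray))) {
    abort_field("adaptive_block_size", "larger than the image")
  }
  x <- if (cfg$trace_polarity == "dark_on_light") 255 - gray else gray
  bl <- EBImage::gblur(EBImage::Image(t(x) / 255), sigma = cfg$blur_sigma,
                       radius = cfg$blur_kernel, boundary = "replicate")
  x <- t(EBImage::imageData(bl)) * 255
  mask <- (x - local_mean(x, cfg$adaptive_block_size)) > cfg$adaptive_offset
  mode(mask) <- "integer"
  mask
}

#' Keep only the largest 8-connected foreground component
#'
#' "Largest" means greatest pixel count; ties are broken by the smallest
#' row-major (column-major scan of rows within columns is normalized to
#' row-major) top-left index.
#'
#' @param mask binary matrix in \{0, 1\}.
#' @return binary matrix containing only the winning component.
#' @export
largest_contour <- function(mask) {
  if (!all(mask %in% c(0L, 1L))) abort_field("mask", "must be binary")
  idx <- which(mask == 1L)
  if (length(idx) == 0) stop("no trace found: mask is empty", call. = FALSE)
  h <- nrow(mask); w <- ncol(mask)
  labels <- matrix(0L, h, w)
  nextlab <- 0L
  # BFS over foreground pixels, 8-neighborhood
  for (start in idx) {
    if (labels[start] != 0L) next
    nextlab <- nextlab + 1L
    queue <- start
    labels[start] <- nextlab
    while (length(queue) > 0) {
      cur <- queue
      queue <- integer(0)
      r <- (cur - 1L) %% h + 1L
      c <- (cur - 1L) %/% h + 1L
      for (dr in -1:1) for (dc in -1:1) {
        if (dr == 0 && dc == 0) next
        nr <- r + dr; nc <- c + dc
        ok <- nr >= 1L & nr <= h & nc >= 1L & nc <= w
        ni <- (nc[ok] - 1L) * h + nr[ok]
        ni <- ni[mask[ni] == 1L & labels[ni] == 0L]
        if (length(ni)) {
          labels[ni] <- nextlab
          queue <- c(queue, ni)
        }
      }
    }
  }
  sizes <- tabulate(labels[idx], nbins = nextlab)
  best <- which(sizes == max(sizes))
  if (length(best) > 1L) {
    # tie-break: smallest row-major index of the component's first pixel
    rowmajor <- function(lab) {
      pix <- which(labels == lab)
      r <- (pix - 1L) %% h; c <- (pix - 1L) %/% h
      min(r * w + c)
    }
    best <- best[which.min(vapply(best, rowmajor, numeric(1)))]
  }
  out <- matrix(0L, h, w)
  out[labels == best] <- 1L
  out
}

#' Extract a 1-D trace from a component mask
#'
#' One amplitude per image column: `amplitude = (height - 1) - reduced_row`
#' with rows 0-based from the top, so amplitude grows upward. Columns without
#' foreground are filled per `cfg$gap_fill`.
#'
#' @param component binary matrix (a single connected component).
#' @param cfg a [digitizer_config()].
#' @param columns_per_second optional time calibration; when `NULL` the trace
#'   gets `sampling_rate = 1` (one sample per column).
#' @return an [ecg_trace()] with `origin = "digitized"`.
#' @export
extract_trace <- function(component, cfg = digitizer_config(),
                          columns_per_second = NULL) {
  h <- nrow(component); w <- ncol(component)
  reduce <- switch(cfg$column_reducer,
                   mean_row = function(r) mean(r),
                   median_row = function(r) stats::median(r),
                   topmost_row = function(r) min(r))
  rows <- vapply(seq_len(w), function(j) {
    r <- which(component[, j] == 1L)
    if (length(r) == 0) NA_real_ else reduce(r)
  }, numeric(1))
  if (all(is.na(rows))) stop("no trace found: component empty in all columns", call. = FALSE)
  if (anyNA(rows)) {
    ok <- which(!is.na(rows))
    if (cfg$gap_fill == "linear_interpolation") {
      rows <- stats::approx(ok, rows[ok], xout = seq_len(w), rule = 2)$y
    } else {
      # hold last observed value; leading gaps take the first observation
      filled <- rows
      last <- rows[ok[1]]
      for (j in seq_len(w)) {
        if (is.na(filled[j])) filled[j] <- last else last <- filled[j]
      }
      rows <- filled
    }
  }
  amp <- (h - 1) - (rows - 1)   # rows are 1-based in R; contract is 0-based
  ecg_trace(amp, if (is.null(columns_per_second)) 1 else columns_per_second,
            origin = "digitized")
}

#' Digitize an ECG plot image into a 1-D trace
#'
#' Composition `extract_trace(largest_contour(binarize(to_grayscale(img))))`,
#' deterministic for a fixed configuration.
#'
#' @inheritParams to_grayscale
#' @inheritParams extract_trace
#' @param cfg a [digitizer_config()].
#' @return an [ecg_trace()].
#' @examples
#' rec <- generate_waveform(synthetic_ecg_spec(noise_sd = 0, duration = 4,
#'                                             heart_rate = 60))
#' img <- render_image(rec$trace)
#' tr <- digitize_image(img)
#' @export
digitize_image <- function(img, cfg = digitizer_config(), columns_per_second = NULL) {
  extract_trace(largest_contour(binarize(to_grayscale(img), cfg)), cfg,
                columns_per_second)
}

#' Digitization fidelity of a rendered trace
#'
#' Renders `trace`, digitizes the image, and reports the Pearson correlation
#' between the digitized amplitudes and the ground-truth trace, aligned on the
#' drawn column region (the render margin is excluded, and the truth is
#' resampled to one value per drawn column).
#'
#' @param trace an [ecg_trace()].
#' @param rs a [render_spec()]; by default the width follows the 160 px/s
#'   resolution convention of [make_ecg_dataset()].
#' @param cfg a [digitizer_config()].
#' @return Pearson correlation coefficient.
#' @export
digitization_fidelity <- function(trace, rs = NULL,
                                  cfg = digitizer_config()) {
  if (is.null(rs)) {
    dur <- length(trace$samples) / trace$sampling_rate
    rs <- render_spec(image_width = max(128, round(160 * dur)))
  }
  img <- render_image(trace, rs)
  dig <- digitize_image(img, cfg)
  usable <- rs$image_width - 2L * rs$margin
  drawn <- dig$samples[rs$margin + seq_len(usable)]
  truth <- stats::approx(seq_along(trace$samples), trace$samples, n = usable)$y
  stats::cor(truth, drawn)
}

#' Read an ECG plot image from PNG/JPEG
#'
#' @param path image file path.
#' @return numeric matrix/array with intensities on the 0–255 scale.
#' @export
read_ecg_image <- function(path) {
  im <- EBImage::readImage(path)
  d <- EBImage::imageData(im)
  if (length(dim(d)) == 2) t(d) * 255 else aperm(d, c(2, 1, 3)) * 255
}
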