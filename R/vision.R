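# Composite correlation-filter recognition of artifacts in grayscale frames.
#
# A filter is associated with each artifact: its template is the re-normalized
# average of the zero-mean, unit-energy reference images (an average-spectrum
# composite of normalized matched filters). Applying it to a frame yields a
# normalized cross-correlation surface whose global peak gives the artifact's
# similarity score and (x, y) location; thresholding the per-frame peak score
# over a frame series produces the artifact's binary presence signal.

#' Construct a grayscale frame
#'
#' @param pixels Numeric matrix of intensities (rows = y, columns = x,
#'   origin top-left).
#' @param t Capture time in seconds.
#' @return An object of class `vframe`.
#' @export
vframe <- function(pixels, t = 0) {
  pixels <- as.matrix(pixels)
  if (!all(is.finite(pixels))) stop("vframe: intensities must be finite")
  if (nrow(pixels) < 1L || ncol(pixels) < 1L) stop("vframe: empty frame")
  structure(list(pixels = pixels, t = t), class = "vframe")
}

#' Read a grayscale frame from PNG or plain PGM
#'
#' PNG requires the `png` package; color images are converted to luminance
#' (0.299 R + 0.587 G + 0.114 B). Plain (P2) PGM is parsed directly.
#'
#' @param path Image path.
#' @param t Capture time to attach (seconds).
#' @return A [vframe].
#' @export
read_frame <- function(path, t = 0) {
  if (grepl("\\.png$", path, ignore.case = TRUE)) {
    if (!requireNamespace("png", quietly = TRUE))
      stop("read_frame: the 'png' package is required for PNG input")
    px <- png::readPNG(path)
    if (length(dim(px)) == 3L)
      px <- 0.299 * px[, , 1] + 0.587 * px[, , 2] + 0.114 * px[, , 3]
    return(vframe(px, t))
  }
  if (grepl("\\.pgm$", path, ignore.case = TRUE)) {
    txt <- readLines(path, warn = FALSE)
    txt <- txt[!grepl("^#", txt)]
    tok <- scan(text = paste(txt, collapse = " "), what = character(),
                quiet = TRUE)
    if (tok[[1L]] != "P2") stop("read_frame: only plain (P2) PGM is supported")
    w <- as.integer(tok[[2L]]); h <- as.integer(tok[[3L]])
    maxv <- as.numeric(tok[[4L]])
    vals <- as.numeric(tok[-(1:4)])
    if (length(vals) != w * h) stop("read_frame: PGM pixel count mismatch")
    return(vframe(matrix(vals / maxv, nrow = h, ncol = w, byrow = TRUE), t))
  }
  stop("read_frame: unsupported format: ", path)
}

.as_pixels <- function(x) {
  if (inherits(x, "vframe")) x$pixels else as.matrix(x)
}

#' Build a composite correlation filter from reference images
#'
#' Each reference is made zero-mean and unit-energy; the composite template
#' is their re-normalized average (equivalently, the average of the
#' normalized matched-filter spectra in the frequency domain). With a single
#' reference the filter reduces to the normalized matched filter of that
#' image, so an exact copy planted in a frame scores 1.
#'
#' @param references List of [vframe]s or matrices, all of equal size.
#' @param artifact_id Artifact the filter recognizes.
#' @return An object of class `correlation_filter` with the spatial template,
#'   its spectrum and the template size.
#' @export
build_composite_filter <- function(references, artifact_id) {
  if (inherits(references, "vframe") || is.matrix(references))
    references <- list(references)
  mats <- lapply(references, .as_pixels)
  if (length(mats) < 1L) stop("build_composite_filter: need >= 1 reference")
  dims <- vapply(mats, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
    stop("build_composite_filter: reference sizes differ")
  norm1 <- lapply(mats, function(m) {
    m <- m - mean(m)
    e <- sqrt(sum(m^2))
    if (e < .Machine$double.eps)
      stop("build_composite_filter: constant reference image")
    m / e
  })
  comp <- Reduce(`+`, norm1) / length(norm1)
  comp <- comp - mean(comp)
  e <- sqrt(sum(comp^2))
  if (e < .Machine$double.eps)
    stop("build_composite_filter: references cancel out")
  comp <- comp / e
  structure(list(artifact_id = artifact_id, template = comp,
                 template_spectrum = stats::fft(comp),
                 template_size = dim(comp)),
            class = "correlation_filter")
}

# local sums of m over h x w windows via an integral image; returns the
# (nrow-h+1) x (ncol-w+1) valid-region matrix
.local_sums <- function(m, h, w) {
  ii <- matrix(0, nrow(m) + 1L, ncol(m) + 1L)
  ii[-1L, -1L] <- t(apply(apply(m, 2L, cumsum), 1L, cumsum))
  H <- nrow(m); W <- ncol(m)
  r <- seq_len(H - h + 1L); c <- seq_len(W - w + 1L)
  ii[r + h, c + w, drop = FALSE] - ii[r, c + w, drop = FALSE] -
    ii[r + h, c, drop = FALSE] + ii[r, c, drop = FALSE]
}

#' Correlate a filter with a frame
#'
#' Computes the normalized cross-correlation surface over all placements
#' where the template fully overlaps the frame (numerator via the frequency
#' domain, local energy via integral images) and returns its global maximum.
#' Scores are invariant to affine intensity rescaling of the frame; a score
#' of 1 is attained exactly where a verbatim copy of a single-reference
#' template occurs. Locally constant patches score 0.
#'
#' @param filter A [correlation_filter].
#' @param frame A [vframe] or matrix, at least template-sized.
#' @param return_surface Also return the full correlation surface.
#' @return An object of class `correlation_result`: `peak_value`, `peak_x`,
#'   `peak_y` (0-based column/row of the template's top-left corner, origin
#'   top-left), `t`, and optionally `surface`.
#' @export
correlate <- function(filter, frame, return_surface = FALSE) {
  stopifnot(inherits(filter, "correlation_filter"))
  t_at <- if (inherits(frame, "vframe")) frame$t else NA_real_
  f <- .as_pixels(frame)
  h <- filter$template_size[[1L]]; w <- filter$template_size[[2L]]
  H <- nrow(f); W <- ncol(f)
  if (H < h || W < w)
    stop("correlate: frame (", H, "x", W, ") smaller than template (",
         h, "x", w, ")")
  tpad <- matrix(0, H, W)
  tpad[seq_len(h), seq_len(w)] <- filter$template
  num <- Re(stats::fft(stats::fft(f) * Conj(stats::fft(tpad)),
                       inverse = TRUE)) / (H * W)
  num <- num[seq_len(H - h + 1L), seq_len(W - w + 1L), drop = FALSE]
  s1 <- .local_sums(f, h, w)
  s2 <- .local_sums(f * f, h, w)
  var_loc <- pmax(s2 - s1 * s1 / (h * w), 0)
  denom <- sqrt(var_loc)
  surf <- ifelse(denom > 1e-10 * max(denom, 1), num / denom, 0)
  surf <- pmin(pmax(surf, -1), 1)
  k <- which.max(surf)
  pr <- (k - 1L) %% nrow(surf) + 1L
  pc <- (k - 1L) %/% nrow(surf) + 1L
  res <- structure(list(peak_value = surf[[k]],
                        peak_x = pc - 1L, peak_y = pr - 1L, t = t_at),
                   class = "correlation_result")
  if (return_surface) res$surface <- surf
  res
}

#' Recognize an artifact across a frame series
#'
#' Applies [correlate()] to every frame, yielding one peak score per frame,
#' then thresholds the score series into the artifact's binary presence
#' signal via [discretize_scores()]; every transition keeps the frame time,
#' so downstream beats can be linked back to frame indexes.
#'
#' @param filter A [correlation_filter].
#' @param frames Time-ordered list of [vframe]s.
#' @param threshold Acceptance threshold on the peak score.
#' @return List with `scores` (data frame `t`, `score`, `x`, `y`), the vision
#'   [raw_stream] and the [binary_signal].
#' @export
recognize_series <- function(filter, frames, threshold) {
  if (inherits(frames, "vframe")) frames <- list(frames)
  ts <- vapply(frames, function(fr) fr$t, numeric(1))
  if (length(ts) > 1L && any(diff(ts) <= 0))
    stop("recognize_series: frames must be strictly time-ordered")
  res <- lapply(frames, function(fr) correlate(filter, fr))
  scores <- data.frame(t = ts,
                       score = vapply(res, `[[`, numeric(1), "peak_value"),
                       x = vapply(res, `[[`, integer(1), "peak_x"),
                       y = vapply(res, `[[`, integer(1), "peak_y"))
  stream <- raw_stream(filter$artifact_id, "vision", scores$t, scores$score)
  list(scores = scores, stream = stream,
       signal = discretize_scores(stream, threshold))
}

#' Generate a synthetic frame with a planted template
#'
#' Test/fixture helper: a `height` x `width` background (constant plus
#' optional Gaussian noise) with `template` copied verbatim at 0-based
#' top-left position (`x`, `y`); `x = NA` plants nothing.
#'
#' @param template Numeric matrix to plant.
#' @param width,height Frame size in pixels.
#' @param x,y 0-based column/row of the template's top-left corner.
#' @param noise_sd Standard deviation of additive Gaussian noise.
#' @param background Background intensity.
#' @param t Frame time (seconds).
#' @return A [vframe].
#' @export
plant_template <- function(template, width = 320, height = 240, x = NA, y = NA,
                           noise_sd = 0, background = 0, t = 0) {
  f <- matrix(background, height, width)
  if (noise_sd > 0) f <- f + matrix(stats::rnorm(height * width, 0, noise_sd),
                                    height, width)
  if (!is.na(x)) {
    template <- as.matrix(template)
    h <- nrow(template); w <- ncol(template)
    if (y + h > height || x + w > width)
      stop("plant_template: template does not fit at (", x, ", ", y, ")")
    f[y + seq_len(h), x + seq_len(w)] <- template
  }
  vframe(f, t)
}
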