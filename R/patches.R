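#' Ternary patch state
#'
#' A 2x2 image patch, variance-normalised, is mapped pixel-wise to one of
#' three levels and encoded as four 2-bit pairs: level "low" (below -0.5)
#' is `(0,1)`, "mid" (within +/-0.5) is `(0,0)`, "high" (above 0.5) is
#' `(1,0)`.  There are `3^4 = 81` such states; `index` is the 0-based
#' ternary rank and `bits` the concatenated 8-bit code used for Hamming
#' distortion.
#'
#' @param index integer in `0..80`.
#' @return A list of class `patch_state` with `index`, `ternary` (four
#'   digits in 0..2: 0 = low, 1 = mid, 2 = high) and `bits` (8 zeros/ones).
#' @export
patch_state <- function(index) {
  stopifnot(length(index) == 1L, index >= 0, index <= 80)
  digits <- (index %/% 3^(0:3)) %% 3
  pair <- function(t) switch(t + 1L, c(0L, 1L), c(0L, 0L), c(1L, 0L))
  structure(list(index = as.integer(index),
                 ternary = as.integer(digits),
                 bits = as.integer(unlist(lapply(digits, pair)))),
            class = "patch_state")
}

#' @export
print.patch_state <- function(x, ...) {
  cat(sprintf("Patch state %d: ternary (%s), bits %s\n", x$index,
              paste(x$ternary, collapse = ","),
              paste(x$bits, collapse = "")))
  invisible(x)
}

#' Ternarize a 2x2 patch
#'
#' Centres the four pixel values, scales them to unit variance, and maps
#' each to a ternary level with threshold 0.5 (see [patch_state()]).  A
#' constant patch (zero variance) maps to the all-mid state by convention.
#'
#' @param patch numeric 2x2 matrix (or length-4 vector) of pixel values.
#' @return A [patch_state()].
#' @export
ternarize_patch <- function(patch) {
  v <- as.numeric(patch)
  stopifnot(length(v) == 4L, all(is.finite(v)))
  s <- stats::sd(v)
  digits <- if (s == 0) rep(1L, 4L) else {
    z <- (v - mean(v)) / s
    ifelse(z < -0.5, 0L, ifelse(z > 0.5, 2L, 1L))
  }
  patch_state(sum(digits * 3^(0:3)))
}

# 81 x 8 matrix of bit codes, rows in index order 0..80
patch_bits_matrix <- function() {
  t(vapply(0:80, function(i) patch_state(i)$bits, integer(8)))
}

#' Hamming distortion between all ternary patch states
#'
#' @return An 81 x 81 symmetric integer matrix of Hamming distances
#'   between the 8-bit codes of the states (zero diagonal, max `<= 8`).
#' @export
patch_hamming_matrix <- function() {
  B <- patch_bits_matrix()
  as.matrix(stats::dist(B, method = "manhattan"))
}

#' Rate-distortion problem of ternarized image patches
#'
#' Slides a `2x2` window over each image with the given stride,
#' ternarizes every patch ([ternarize_patch()]), and forms the empirical
#' distribution over the 81 states (a pseudo-count keeps unobserved
#' states strictly positive, as the source distribution requires).  The
#' distortion is the Hamming distance between the states' 8-bit codes.
#'
#' @param images a list of numeric matrices (grayscale images), or a
#'   single matrix.
#' @param patch_stride window stride in pixels (default 2:
#'   non-overlapping patches).
#' @param pseudo_count mass added to every state before normalisation.
#' @return An [rd_problem()] on 81 states, with the raw `counts` attached
#'   as an attribute.
#' @export
patch_rd_problem <- function(images, patch_stride = 2, pseudo_count = 1) {
  if (is.matrix(images)) images <- list(images)
  stopifnot(length(images) >= 1, patch_stride >= 1, pseudo_count > 0)
  counts <- numeric(81)
  for (img in images) {
    stopifnot(is.matrix(img), nrow(img) >= 2, ncol(img) >= 2)
    ri <- seq(1, nrow(img) - 1, by = patch_stride)
    ci <- seq(1, ncol(img) - 1, by = patch_stride)
    for (r in ri) for (cc in ci) {
      st <- ternarize_patch(img[r:(r + 1), cc:(cc + 1)])
      counts[st$index + 1L] <- counts[st$index + 1L] + 1
    }
  }
  q <- counts + pseudo_count
  pr <- rd_problem(q / sum(q), patch_hamming_matrix())
  attr(pr, "counts") <- counts
  pr
}

#' Synthetic 1/f-noise grayscale images
#'
#' Generates images with a 1/f amplitude spectrum and random Fourier
#' phases — the hallmark second-order statistic of natural scenes —
#' rescaled to `[0, 1]`.  Deterministic per seed; a built-in stand-in for
#' a natural-image database so the patch-coding pipeline runs
#' self-contained.
#'
#' @param seed integer seed.
#' @param width,height image dimensions in pixels.
#' @param count number of images.
#' @return A list of `height x width` numeric matrices with values in
#'   `[0, 1]`.
#' @export
synthetic_image_generator <- function(seed = 1, width = 128, height = 128,
                                      count = 4) {
  stopifnot(width > 1, height > 1, count >= 1)
  set.seed(seed)
  fx <- c(0:(floor(width / 2)), -(ceiling(width / 2) - 1):-1) / width
  fy <- c(0:(floor(height / 2)), -(ceiling(height / 2) - 1):-1) / height
  f <- sqrt(outer(fy^2, fx^2, "+"))
  amp <- ifelse(f > 0, 1 / f, 0)
  lapply(seq_len(count), function(k) {
    white <- matrix(stats::rnorm(width * height), height, width)
    img <- Re(stats::fft(stats::fft(white) * amp, inverse = TRUE))
    rng <- range(img)
    (img - rng[1]) / (rng[2] - rng[1])
  })
}
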