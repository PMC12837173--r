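#' Parameters for local adaptive binarization
#'
#' Bundles the thresholding method and its coefficients. Supported methods:
#' \describe{
#'   \item{niblack}{`T = m + k * s` with local mean `m` and local (population)
#'     standard deviation `s` over a `window_px` square window. With bright
#'     vessels on a dark background, `k >= 0` is the usual convention (the
#'     mirrored sign, `T = m - k * s`, applies under `polarity =
#'     "dark_vessels"`; see Details).}
#'   \item{phansalkar}{`T = m * (1 + p_coef * exp(-q_coef * m) + k * (s / r - 1))`,
#'     designed for low-contrast bright objects; intensities are normalized to
#'     [0, 1] first so the exponential term behaves as published.}
#'   \item{otsu_global}{single Otsu threshold maximizing between-class
#'     variance on the 256-bin histogram of the whole image.}
#'   \item{otsu_local}{Otsu threshold recomputed on each pixel's window
#'     histogram (slow; intended for small images and validation).}
#' }
#'
#' A pixel is classified as vessel iff its intensity is strictly greater than
#' its threshold (`bright_vessels`). Under `dark_vessels` the image is
#' intensity-inverted (`1 - I`) before thresholding, which for Niblack is
#' algebraically the mirrored rule `I < m - k * s`.
#'
#' Borders are handled by symmetric (edge-mirroring) padding of half the
#' window on each side, which avoids the artificially low local means a
#' zero-padded rim would produce.
#'
#' Defaults follow the established local-thresholding literature; none of
#' these coefficients is standardized for OCTA, so all are exposed and echoed
#' into pipeline metadata.
#'
#' @param method one of `"phansalkar"`, `"niblack"`, `"otsu_global"`, `"otsu_local"`.
#' @param window_px odd window side in pixels (local methods).
#' @param k sensitivity coefficient.
#' @param r dynamic-range normalizer (phansalkar).
#' @param p_coef,q_coef coefficients of the phansalkar exponential term.
#' @param polarity `"bright_vessels"` (default) or `"dark_vessels"`.
#' @return An object of class `threshold_params`.
#' @export
threshold_params <- function(method = c("phansalkar", "niblack", "otsu_global", "otsu_local"),
                             window_px = 15L,
                             k = if (match.arg(method) == "phansalkar") 0.25 else 0.2,
                             r = 0.5, p_coef = 2, q_coef = 10,
                             polarity = c("bright_vessels", "dark_vessels")) {
  method <- match.arg(method)
  polarity <- match.arg(polarity)
  window_px <- as.integer(window_px)
  if (method != "otsu_global") {
    if (window_px < 3L || window_px %% 2L == 0L)
      stop_octa("invalid-params", "window_px must be odd and >= 3")
  }
  if (method == "phansalkar" && (!is.finite(r) || r <= 0))
    stop_octa("invalid-params", "phansalkar requires r > 0")
  structure(list(method = method, window_px = window_px, k = k, r = r,
                 p_coef = p_coef, q_coef = q_coef, polarity = polarity),
            class = "threshold_params")
}

#' Default threshold parameters for a scan site
#'
#' The pipeline routes macula scans to Phansalkar and ONH scans to Niblack
#' thresholding by default.
#'
#' @param center_type `"macula"` or `"onh"`.
#' @return A [threshold_params()] object.
#' @export
default_threshold_params <- function(center_type = c("macula", "onh")) {
  center_type <- match.arg(center_type)
  if (center_type == "macula") threshold_params("phansalkar")
  else threshold_params("niblack")
}

## Symmetric (half-sample, edge-repeating) padding by `r` pixels.
pad_reflect <- function(m, r) {
  nr <- nrow(m); nc <- ncol(m)
  if (r >= nr || r >= nc)
    stop_octa("invalid-params", "window does not fit inside the padded image")
  ri <- c(r:1, 1:nr, nr:(nr - r + 1))
  ci <- c(r:1, 1:nc, nc:(nc - r + 1))
  m[ri, ci, drop = FALSE]
}

## Windowed sums over w x w windows of the padded matrix, evaluated at every
## original pixel, via separable cumulative sums.
box_sums <- function(padded, w, nr, nc) {
  cs <- apply(padded, 2, cumsum)
  cs <- rbind(0, cs)
  vert <- cs[(1:nr) + w, , drop = FALSE] - cs[1:nr, , drop = FALSE]
  cs2 <- t(apply(vert, 1, cumsum))
  cs2 <- cbind(0, cs2)
  cs2[, (1:nc) + w, drop = FALSE] - cs2[, 1:nc, drop = FALSE]
}

## Local mean and population SD over centered w x w windows with symmetric
## padding.
local_stats <- function(img, w) {
  r <- (w - 1L) %/% 2L
  nr <- nrow(img); nc <- ncol(img)
  p <- pad_reflect(img, r)
  n <- as.numeric(w)^2
  s1 <- box_sums(p, w, nr, nc)
  s2 <- box_sums(p * p, w, nr, nc)
  m <- s1 / n
  v <- pmax(0, s2 / n - m * m)
  list(mean = m, sd = sqrt(v))
}

## Otsu threshold on a 256-bin histogram of values in [0,1]. Returns the
## threshold as a bin-boundary value, or NA when no valid split exists
## (constant input). Foreground is defined as intensity > threshold.
otsu_threshold01 <- function(x) {
  bins <- pmin(255L, pmax(0L, as.integer(floor(x * 256))))
  h <- tabulate(bins + 1L, nbins = 256L)
  n <- sum(h)
  omega <- cumsum(h) / n
  mu <- cumsum(h * (0:255)) / n
  mu_t <- mu[256]
  denom <- omega * (1 - omega)
  sigma_b <- ifelse(denom > 0, (mu_t * omega - mu)^2 / denom, NA_real_)
  sigma_b <- sigma_b[1:255]
  if (all(is.na(sigma_b))) return(NA_real_)
  k <- which.max(sigma_b)        # first maximum; bins <= k-1 are background
  (k - 0.5) / 255                # boundary value between bin k-1 and bin k
}

#' Binarize an en-face angiogram into a vessel mask
#'
#' Applies the local adaptive threshold described by `params` (see
#' [threshold_params()]) after rescaling intensities to [0, 1]. A pixel is a
#' vessel iff its normalized intensity is strictly greater than its local
#' threshold, so a perfectly constant image always yields an empty mask.
#'
#' @param img an [enface_angiogram()] or a numeric matrix already on [0, 1].
#' @param params a [threshold_params()] object.
#' @return An object of class `binary_vessel_map`: a list with the logical
#'   `mask`, the source `spec` (if available) and `params`.
#' @examples
#' spec <- image_spec(32, 32, 3, "macula", "OD")
#' img <- matrix(0L, 32, 32); img[10:14, 8:26] <- 200L
#' bm <- binarize(enface_angiogram(img, spec), threshold_params("niblack"))
#' sum(bm$mask)
#' @export
binarize <- function(img, params = threshold_params()) {
  stopifnot(inherits(params, "threshold_params"))
  spec <- NULL
  xint <- NULL   # 8-bit source: windowed sums run on exact integer cumsums
  if (inherits(img, "enface_angiogram")) {
    spec <- img$spec
    xint <- img$pixels
    if (params$polarity == "dark_vessels") xint <- 255L - xint
    x <- xint / 255
  } else {
    stopifnot(is.matrix(img), is.numeric(img))
    x <- img
    if (min(x) < 0 || max(x) > 1)
      x <- (x - min(x)) / max(max(x) - min(x), .Machine$double.eps)
    if (params$polarity == "dark_vessels") x <- 1 - x
  }
  lstats <- function(w) {
    if (is.null(xint)) return(local_stats(x, w))
    ## doubles hold these integer sums exactly (well below 2^53)
    ls <- local_stats(matrix(as.numeric(xint), nrow(xint)), w)
    list(mean = ls$mean / 255, sd = ls$sd / 255)
  }

  w <- params$window_px
  mask <- switch(params$method,
    niblack = {
      ls <- lstats(w)
      x > ls$mean + params$k * ls$sd
    },
    phansalkar = {
      ls <- lstats(w)
      thr <- ls$mean * (1 + params$p_coef * exp(-params$q_coef * ls$mean) +
                          params$k * (ls$sd / params$r - 1))
      x > thr
    },
    otsu_global = {
      t0 <- otsu_threshold01(as.vector(x))
      if (is.na(t0)) {
        warning("constant image: no valid Otsu threshold, returning all-background")
        matrix(FALSE, nrow(x), ncol(x))
      } else x > t0
    },
    otsu_local = {
      r <- (w - 1L) %/% 2L
      p <- pad_reflect(x, r)
      nr <- nrow(x); nc <- ncol(x)
      out <- matrix(FALSE, nr, nc)
      any_na <- FALSE
      for (j in seq_len(nc)) for (i in seq_len(nr)) {
        win <- p[i:(i + w - 1L), j:(j + w - 1L)]
        t0 <- otsu_threshold01(as.vector(win))
        if (is.na(t0)) any_na <- TRUE else out[i, j] <- x[i, j] > t0
      }
      if (any_na)
        warning("constant window(s): no valid Otsu threshold there, kept background")
      out
    })
  structure(list(mask = mask, spec = spec, params = params),
            class = "binary_vessel_map")
}

#' @export
print.binary_vessel_map <- function(x, ...) {
  cat(sprintf("<binary_vessel_map> %dx%d, %s, vessel fraction %.4f\n",
              nrow(x$mask), ncol(x$mask), x$params$method, mean(x$mask)))
  invisible(x)
}
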