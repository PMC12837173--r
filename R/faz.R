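#' A traced foveal avascular zone outline
#'
#' An ordered, implicitly closed polygon of `(x, y)` vertices in pixel
#' coordinates (raster convention, y down), together with the scan's
#' [image_spec()] so metrics can be reported in millimetres. The polygon must
#' be simple (non-self-intersecting) and have at least 3 vertices.
#'
#' @param vertices two-column numeric matrix or data.frame of `(x, y)` pixel
#'   coordinates, one vertex per row.
#' @param spec an [image_spec()].
#' @param check if `TRUE` (default) verify simplicity (O(n^2) segment test).
#' @return An object of class `faz_outline`.
#' @export
faz_outline <- function(vertices, spec, check = TRUE) {
  stopifnot(inherits(spec, "image_spec"))
  v <- as.matrix(vertices)[, 1:2, drop = FALSE]
  storage.mode(v) <- "double"
  ## drop a duplicated closing vertex
  n <- nrow(v)
  if (n >= 2 && isTRUE(all(v[1, ] == v[n, ]))) v <- v[-n, , drop = FALSE]
  if (nrow(v) < 3)
    stop_octa("invalid-outline", "an outline needs at least 3 distinct vertices")
  if (check && polygon_self_intersects(v))
    stop_octa("invalid-outline", "outline polygon is self-intersecting")
  structure(list(vertices = v, spec = spec), class = "faz_outline")
}

## Proper-crossing test between all non-adjacent edge pairs.
polygon_self_intersects <- function(v) {
  n <- nrow(v)
  a <- v
  b <- v[c(2:n, 1), , drop = FALSE]
  cross <- function(ox, oy, px, py, qx, qy) (px - ox) * (qy - oy) - (py - oy) * (qx - ox)
  for (i in seq_len(n - 2L)) {
    js <- (i + 2L):n
    if (i == 1L) js <- js[js != n]           # edge n is adjacent to edge 1
    if (!length(js)) next
    d1 <- cross(a[i, 1], a[i, 2], b[i, 1], b[i, 2], a[js, 1], a[js, 2])
    d2 <- cross(a[i, 1], a[i, 2], b[i, 1], b[i, 2], b[js, 1], b[js, 2])
    d3 <- cross(a[js, 1], a[js, 2], b[js, 1], b[js, 2], a[i, 1], a[i, 2])
    d4 <- cross(a[js, 1], a[js, 2], b[js, 1], b[js, 2], b[i, 1], b[i, 2])
    if (any(d1 * d2 < 0 & d3 * d4 < 0)) return(TRUE)
  }
  FALSE
}

#' FAZ area, perimeter and acircularity index
#'
#' Area by the shoelace formula (absolute value), perimeter by summed
#' vertex-to-vertex Euclidean distances, both converted to physical units via
#' the outline's scan calibration. The acircularity index is the ratio of the
#' FAZ perimeter to the perimeter of the circle with the same area,
#' `P / (2 * sqrt(pi * A))`: 1 for a perfect circle and larger for lobed or
#' elongated zones (isoperimetric inequality), up to digitization error.
#'
#' @param outline a [faz_outline()].
#' @return An object of class `faz_metrics`: list with `area_mm2`,
#'   `perimeter_mm`, `acircularity`.
#' @examples
#' spec <- image_spec(512, 512, 3, "macula", "OD")
#' th <- seq(0, 2 * pi, length.out = 361)[-361]
#' circ <- cbind(256 + 50 * cos(th), 256 + 50 * sin(th))
#' faz_metrics(faz_outline(circ, spec))$acircularity  # ~1
#' @export
faz_metrics <- function(outline) {
  stopifnot(inherits(outline, "faz_outline"))
  v <- outline$vertices
  n <- nrow(v)
  nxt <- c(2:n, 1)
  area_px2 <- abs(sum(v[, 1] * v[nxt, 2] - v[nxt, 1] * v[, 2])) / 2
  per_px <- sum(sqrt((v[nxt, 1] - v[, 1])^2 + (v[nxt, 2] - v[, 2])^2))
  if (area_px2 <= 0) stop_octa("invalid-outline", "outline encloses zero area")
  s <- mm_per_px(outline$spec)
  area <- area_px2 * s^2
  per <- per_px * s
  structure(list(area_mm2 = area, perimeter_mm = per,
                 acircularity = per / (2 * sqrt(pi * area))),
            class = "faz_metrics")
}

#' @export
print.faz_metrics <- function(x, ...) {
  cat(sprintf("<faz_metrics> area %.4f mm^2, perimeter %.4f mm, acircularity %.4f\n",
              x$area_mm2, x$perimeter_mm, x$acircularity))
  invisible(x)
}

#' Automatically trace the FAZ outline on a vessel mask
#'
#' Flood-fills the avascular (non-vessel) 4-connected component containing
#' the grid center and traces its outer boundary as a closed polygon of pixel
#' centers (Moore neighbor tracing). This replaces, for synthetic data, the
#' manual freehand tracing a human grader performs.
#'
#' @param mask a `binary_vessel_map` or logical vessel matrix (TRUE = vessel).
#' @param spec the scan's [image_spec()] (must be macula-centered).
#' @param center_px optional `(x, y)` seed; defaults to the image center.
#' @return A [faz_outline()].
#'   Errors: `"no-faz-at-center"` if the seed pixel is a vessel;
#'   `"unbounded-faz"` if the avascular region touches the image border
#'   (no FAZ could be determined).
#' @export
auto_faz_outline <- function(mask, spec, center_px = NULL) {
  if (inherits(mask, "binary_vessel_map")) mask <- mask$mask
  stopifnot(inherits(spec, "image_spec"), is.matrix(mask), is.logical(mask))
  if (spec$center_type != "macula")
    stop_octa("invalid-spec", "FAZ extraction applies to macula-centered scans")
  if (is.null(center_px)) center_px <- c(spec$width_px / 2, spec$height_px / 2)
  ci <- pmin(pmax(1L, as.integer(ceiling(center_px[2]))), nrow(mask))
  cj <- pmin(pmax(1L, as.integer(ceiling(center_px[1]))), ncol(mask))
  if (mask[ci, cj]) stop_octa("no-faz-at-center", "center pixel lies on a vessel")
  lab <- label_components(!mask, connectivity = 4L)
  comp <- lab == lab[ci, cj]
  if (any(comp[1, ]) || any(comp[nrow(comp), ]) ||
      any(comp[, 1]) || any(comp[, ncol(comp)]))
    stop_octa("unbounded-faz", "avascular region reaches the image border; no FAZ could be determined")
  poly <- trace_boundary(comp)
  faz_outline(poly, spec, check = FALSE)
}

## Moore-neighbor boundary tracing with Jacob's stopping criterion.
## Returns pixel-center (x, y) coordinates of the outer boundary, clockwise
## in raster orientation. Input must be a single nonempty component.
trace_boundary <- function(comp) {
  nr <- nrow(comp); nc <- ncol(comp)
  idx <- which(comp)
  ## start at the topmost, then leftmost pixel
  rows <- ((idx - 1L) %% nr) + 1L
  cols <- ((idx - 1L) %/% nr) + 1L
  o <- order(rows, cols)
  sr <- rows[o[1L]]; sc <- cols[o[1L]]
  if (sum(comp) == 1L) {
    ## degenerate single-pixel region: tiny square around the pixel center
    x <- sc - 0.5; y <- sr - 0.5
    return(cbind(x = x + c(-0.4, 0.4, 0.4, -0.4), y = y + c(-0.4, -0.4, 0.4, 0.4)))
  }
  ## Moore neighborhood, clockwise on screen (y down), starting at west:
  drs <- c(0L, -1L, -1L, -1L, 0L, 1L, 1L, 1L)
  dcs <- c(-1L, -1L, 0L, 1L, 1L, 1L, 0L, -1L)
  dir_of <- function(dr, dc) which(drs == dr & dcs == dc) - 1L
  fg <- function(r, c) r >= 1L && r <= nr && c >= 1L && c <= nc && comp[r, c]

  path_r <- integer(0); path_c <- integer(0)
  r <- sr; c <- sc
  bd <- 0L                      # backtrack direction: entered scanning from W
  seen <- logical(nr * nc * 8L) # (pixel, backtrack) states already visited
  repeat {
    state <- ((c - 1L) * nr + (r - 1L)) * 8L + bd + 1L
    if (seen[state]) break
    seen[state] <- TRUE
    path_r <- c(path_r, r); path_c <- c(path_c, c)
    found <- FALSE
    prev <- bd
    for (k in 1:8) {
      d <- (bd + k) %% 8L
      rr <- r + drs[d + 1L]; cc <- c + dcs[d + 1L]
      if (fg(rr, cc)) {
        ## new backtrack = last background neighbor scanned, re-expressed
        ## relative to the new current pixel
        br <- r + drs[prev + 1L]; bc <- c + dcs[prev + 1L]
        bd <- dir_of(br - rr, bc - cc)
        r <- rr; c <- cc
        found <- TRUE
        break
      }
      prev <- d
    }
    if (!found) break  # isolated pixel (handled above), safety net
  }
  cbind(x = path_c - 0.5, y = path_r - 0.5)
}

#' Read or write a FAZ outline as a CSV vertex list
#'
#' Plain CSV with `x`, `y` headers, one vertex per row, pixel units.
#'
#' @param outline a [faz_outline()].
#' @param path file path.
#' @param spec an [image_spec()] for reading.
#' @export
write_faz_outline <- function(outline, path) {
  utils::write.csv(data.frame(x = outline$vertices[, 1], y = outline$vertices[, 2]),
                   path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_faz_outline
#' @export
read_faz_outline <- function(path, spec) {
  df <- utils::read.csv(path)
  faz_outline(as.matrix(df[, c("x", "y")]), spec)
}
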