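#' Construct an ETDRS grid
#'
#' The ETDRS overlay used for regional analysis: concentric circles of 1, 3
#' and 6 mm diameter (radii 0.5 / 1.5 / 3.0 mm) about a center point, with
#' the annuli split into superior / nasal / inferior / temporal quadrants by
#' the +-45 degree diagonals. The central disc (r <= 0.5 mm) belongs to no
#' region. Nasal/temporal labels mirror with laterality: by default the
#' temporal quadrant is on the image left for OD (right eye) scans and on the
#' image right for OS, a mapping that can be overridden via `temporal_side`.
#'
#' @param spec an [image_spec()]; supplies scale, laterality and default center.
#' @param center_px optional `(x, y)` sub-pixel grid center in pixel units;
#'   defaults to the geometric image center.
#' @param radii_mm radii of the central disc, inner ring and outer ring, mm.
#' @param temporal_side named character vector mapping laterality to the image
#'   side ("left"/"right") holding the temporal quadrant.
#' @return An object of class `etdrs_grid`.
#' @export
etdrs_grid <- function(spec, center_px = NULL,
                       radii_mm = c(r_center = 0.5, r_inner = 1.5, r_outer = 3.0),
                       temporal_side = c(OD = "left", OS = "right")) {
  stopifnot(inherits(spec, "image_spec"))
  if (!(radii_mm[1] > 0 && radii_mm[1] < radii_mm[2] && radii_mm[2] < radii_mm[3]))
    stop_octa("invalid-grid", "grid radii must satisfy 0 < r_center < r_inner < r_outer")
  if (is.null(center_px))
    center_px <- c(spec$width_px / 2, spec$height_px / 2)
  if (center_px[1] < 0 || center_px[1] > spec$width_px ||
      center_px[2] < 0 || center_px[2] > spec$height_px)
    stop_octa("center-out-of-bounds", "grid center lies outside the image")
  structure(list(center_px = as.numeric(center_px),
                 mm_per_px = mm_per_px(spec),
                 radii_mm = radii_mm,
                 laterality = spec$laterality,
                 temporal_side = temporal_side,
                 spec = spec),
            class = "etdrs_grid")
}

#' Translate an ETDRS grid from the image center
#'
#' Emulates the manual "translate" centering step: the grid starts at the
#' geometric image center and is shifted by `offset_px`; the offset is kept on
#' the returned grid for audit.
#'
#' @param img an [enface_angiogram()] (or an [image_spec()]).
#' @param offset_px numeric `(dx, dy)` translation in pixels.
#' @param ... passed to [etdrs_grid()].
#' @return An `etdrs_grid` centered at image center + offset.
#' @export
center_grid <- function(img, offset_px = c(0, 0), ...) {
  spec <- if (inherits(img, "enface_angiogram")) img$spec else img
  stopifnot(inherits(spec, "image_spec"))
  ctr <- c(spec$width_px / 2 + offset_px[1], spec$height_px / 2 + offset_px[2])
  g <- etdrs_grid(spec, center_px = ctr, ...)
  g$offset_px <- as.numeric(offset_px)
  g
}

#' ETDRS region labels for a site
#' @param center_type `"macula"` (4 inner regions) or `"onh"` (8 regions).
#' @return data.frame with columns `region`, `quadrant`, `ring`.
#' @export
etdrs_regions <- function(center_type = c("macula", "onh")) {
  center_type <- match.arg(center_type)
  quad <- c("superior", "nasal", "inferior", "temporal")
  if (center_type == "macula")
    data.frame(region = paste0("inner_", quad), quadrant = quad,
               ring = "inner", stringsAsFactors = FALSE)
  else
    data.frame(region = c(paste0("inner_", quad), paste0("outer_", quad)),
               quadrant = rep(quad, 2),
               ring = rep(c("inner", "outer"), each = 4),
               stringsAsFactors = FALSE)
}

#' Rasterize ETDRS region masks
#'
#' Assigns every pixel by the polar coordinates of its center about the grid
#' center: ring by radius (half-open annuli `(r_center, r_inner]` and
#' `(r_inner, r_outer]`) and quadrant by angle with half-open boundaries on
#' the diagonals, so the masks are pairwise disjoint and partition the
#' annulus. For a 3 mm macula field only the inner ring fits and 4 masks are
#' returned; for a 6 mm ONH field all 8.
#'
#' @param spec an [image_spec()].
#' @param grid an [etdrs_grid()]; defaults to a grid at the image center.
#' @return Named list of logical masks, one per region (see [etdrs_regions()]).
#'   If part of the outer ring falls outside the image a `"grid-clipped"`
#'   warning reports the clipped fraction.
#' @export
build_region_masks <- function(spec, grid = etdrs_grid(spec)) {
  stopifnot(inherits(spec, "image_spec"), inherits(grid, "etdrs_grid"))
  pc <- pixel_centers(spec)
  dx_mm <- (pc$x - grid$center_px[1]) * grid$mm_per_px
  dy_up_mm <- (grid$center_px[2] - pc$y) * grid$mm_per_px   # y axis up
  r <- sqrt(dx_mm^2 + dy_up_mm^2)
  theta <- atan2(dy_up_mm, dx_mm) * 180 / pi                # (-180, 180]

  rc <- grid$radii_mm[[1]]; ri <- grid$radii_mm[[2]]; ro <- grid$radii_mm[[3]]
  macula <- spec$center_type == "macula"
  max_r_mm <- spec$field_mm / 2
  if (macula && ri > max_r_mm + 1e-9)
    stop_octa("invalid-grid", "inner ring does not fit in the scan field")

  ## angular quadrants, half-open at the diagonals
  q_sup <- theta >= 45 & theta < 135
  q_inf <- theta >= -135 & theta < -45
  q_right <- theta >= -45 & theta < 45
  q_left <- !(q_sup | q_inf | q_right)
  side <- grid$temporal_side[[grid$laterality]]
  q_temp <- if (identical(side, "left")) q_left else q_right
  q_nas <- if (identical(side, "left")) q_right else q_left
  quads <- list(superior = q_sup, nasal = q_nas, inferior = q_inf, temporal = q_temp)

  inner <- r > rc & r <= ri
  regions <- etdrs_regions(spec$center_type)
  out <- vector("list", nrow(regions))
  names(out) <- regions$region
  if (!macula) {
    outer <- r > ri & r <= ro
    ## warn if the outer circle is clipped by the image border
    margin <- min(grid$center_px[1], spec$width_px - grid$center_px[1],
                  grid$center_px[2], spec$height_px - grid$center_px[2]) *
      grid$mm_per_px
    if (ro > margin + 1e-9) {
      full_area <- pi * (ro^2 - rc^2)
      raster_area <- (sum(inner) + sum(outer)) * grid$mm_per_px^2
      warning(sprintf("grid-clipped: ~%.1f%% of the ETDRS annulus falls outside the image",
                      100 * max(0, 1 - raster_area / full_area)))
    }
  }
  for (i in seq_len(nrow(regions))) {
    ringmask <- if (regions$ring[i] == "inner") inner else outer
    out[[i]] <- ringmask & quads[[regions$quadrant[i]]]
  }
  out
}

#' Extract regional skeletonized vessel densities
#'
#' Computes [skeleton_density()] in every ETDRS region of the grid, plus the
#' unweighted across-region mean as a site-level summary row (`region =
#' "mean"`). Inner and outer sectors have different areas, so an
#' area-weighted alternative is available via `weighted = TRUE`.
#'
#' @param skel a `skeleton_map` or logical matrix.
#' @param grid an [etdrs_grid()].
#' @param meta optional named list / one-row data.frame of covariates
#'   (subject, eye, diagnosis, ...) replicated onto each record.
#' @param weighted if `TRUE` the summary row is the pixel-area-weighted mean.
#' @return data.frame with columns `region`, `quadrant`, `ring`, `density`,
#'   `n_px`, plus any `meta` columns.
#' @export
extract_region_densities <- function(skel, grid, meta = NULL, weighted = FALSE) {
  if (inherits(skel, "skeleton_map")) skel <- skel$skeleton
  spec <- grid$spec
  masks <- build_region_masks(spec, grid)
  regions <- etdrs_regions(spec$center_type)
  dens <- vapply(masks, function(m) skeleton_density(skel, m), numeric(1))
  npx <- vapply(masks, sum, numeric(1))
  df <- data.frame(region = regions$region, quadrant = regions$quadrant,
                   ring = regions$ring, density = as.numeric(dens),
                   n_px = as.numeric(npx), stringsAsFactors = FALSE)
  avg <- if (weighted) sum(dens * npx) / sum(npx) else mean(dens)
  df <- rbind(df, data.frame(region = "mean", quadrant = NA_character_,
                             ring = NA_character_, density = avg,
                             n_px = sum(npx), stringsAsFactors = FALSE))
  if (!is.null(meta)) {
    meta <- as.data.frame(meta, stringsAsFactors = FALSE)
    df <- cbind(meta[rep(1L, nrow(df)), , drop = FALSE], df, row.names = NULL)
  }
  df
}
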