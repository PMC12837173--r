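## Neighbor bookkeeping for 3x3 topology tests. Neighbors are indexed
## P2..P9 clockwise from north: N, NE, E, SE, S, SW, W, NW, on a matrix
## with origin top-left (north = row - 1).

## Offsets into a padded matrix with `nrp` rows, in P2..P9 order.
nb_offsets <- function(nrp) {
  c(-1L,                 # N
    -1L + nrp,           # NE
    nrp,                 # E
    1L + nrp,            # SE
    1L,                  # S
    1L - nrp,            # SW
    -nrp,                # W
    -1L - nrp)           # NW
}

## Number of 0 -> 1 transitions in the cyclic sequence P2,P3,...,P9,P2.
transitions8 <- function(nb) {
  s <- c(nb, nb[1L])
  sum(!s[-9L] & s[-1L])
}

#' Thin a binary vessel mask to one-pixel-wide centerlines
#'
#' Iterative morphological thinning in the Zhang-Suen family: two directional
#' sub-iterations repeatedly delete border pixels whose removal keeps the
#' local topology intact (exactly one foreground run around the pixel, 2-6
#' foreground neighbors, and the directional north/south-east/west gating
#' conditions). Deletions within each sub-iteration are applied sequentially
#' in raster order, re-checking the conditions against the current mask; this
#' sequential application is what guarantees that the number of 8-connected
#' components is preserved (a fully parallel sweep can erase an isolated 2x2
#' block outright).
#'
#' The result is a subset of the input, reduces every structure to (at most)
#' unit width away from junctions, and is a fixed point: re-applying the
#' operator returns the skeleton unchanged. Endpoints are never deleted, so
#' spurs are retained (no pruning).
#'
#' @param mask a logical matrix or a `binary_vessel_map`.
#' @return An object of class `skeleton_map` with the logical `skeleton`
#'   matrix and the source mask.
#' @examples
#' m <- matrix(FALSE, 9, 40); m[3:7, 2:39] <- TRUE
#' sk <- skeletonize(m)
#' sum(sk$skeleton)  # a single thin line
#' @export
skeletonize <- function(mask) {
  src <- mask
  if (inherits(mask, "binary_vessel_map")) mask <- mask$mask
  stopifnot(is.matrix(mask), is.logical(mask))
  nr <- nrow(mask); nc <- ncol(mask)
  ## pad with a FALSE ring so neighbor indexing never leaves the matrix
  M <- matrix(FALSE, nr + 2L, nc + 2L)
  M[2:(nr + 1L), 2:(nc + 1L)] <- mask
  nrp <- nr + 2L
  off <- nb_offsets(nrp)
  inner <- which(M)

  repeat {
    changed <- FALSE
    for (phase in 1:2) {
      cand <- thin_candidates(M, phase)
      if (length(cand)) {
        ## sequential confirm-and-delete in raster order
        for (idx in cand) {
          nb <- M[idx + off]
          b <- sum(nb)
          if (b < 2L || b > 6L) next
          if (transitions8(nb) != 1L) next
          if (phase == 1L) {
            if ((nb[1L] && nb[3L] && nb[5L]) || (nb[3L] && nb[5L] && nb[7L])) next
          } else {
            if ((nb[1L] && nb[3L] && nb[7L]) || (nb[1L] && nb[5L] && nb[7L])) next
          }
          M[idx] <- FALSE
          changed <- TRUE
        }
      }
    }
    if (!changed) break
  }
  skeleton <- M[2:(nr + 1L), 2:(nc + 1L), drop = FALSE]
  structure(list(skeleton = skeleton, source = src), class = "skeleton_map")
}

## Vectorized pre-screen: foreground pixels that satisfy the deletion
## conditions against the mask as it stood at the start of the sub-iteration.
## Survivors are re-checked sequentially before deletion.
thin_candidates <- function(M, phase) {
  nr <- nrow(M); nc <- ncol(M)
  core <- M[2:(nr - 1L), 2:(nc - 1L), drop = FALSE]
  sh <- function(dr, dc) M[(2:(nr - 1L)) + dr, (2:(nc - 1L)) + dc, drop = FALSE]
  n <- sh(-1L, 0L); ne <- sh(-1L, 1L); e <- sh(0L, 1L); se <- sh(1L, 1L)
  s <- sh(1L, 0L); sw <- sh(1L, -1L); w <- sh(0L, -1L); nw <- sh(-1L, -1L)
  b <- n + ne + e + se + s + sw + w + nw
  a <- (!n & ne) + (!ne & e) + (!e & se) + (!se & s) +
       (!s & sw) + (!sw & w) + (!w & nw) + (!nw & n)
  ok <- core & b >= 2L & b <= 6L & a == 1L
  if (phase == 1L) ok <- ok & !(n & e & s) & !(e & s & w)
  else ok <- ok & !(n & e & w) & !(n & s & w)
  ## convert core indices back to padded-matrix indices
  idx <- which(ok)
  if (!length(idx)) return(integer(0))
  r0 <- ((idx - 1L) %% (nr - 2L)) + 2L
  c0 <- ((idx - 1L) %/% (nr - 2L)) + 2L
  sort((c0 - 1L) * nr + r0)
}

#' @export
print.skeleton_map <- function(x, ...) {
  cat(sprintf("<skeleton_map> %dx%d, %d skeleton px\n",
              nrow(x$skeleton), ncol(x$skeleton), sum(x$skeleton)))
  invisible(x)
}

#' Skeletonized vessel density within a region
#'
#' The fraction of region pixels occupied by skeleton centerline pixels —
#' the per-region quantity the ETDRS analysis feeds into the cohort models.
#'
#' @param skel a `skeleton_map` or logical matrix.
#' @param region_mask logical matrix of the same dimensions selecting the
#'   region (must contain at least one pixel).
#' @return Fraction in [0, 1].
#' @export
skeleton_density <- function(skel, region_mask) {
  if (inherits(skel, "skeleton_map")) skel <- skel$skeleton
  stopifnot(is.matrix(skel), is.logical(skel),
            is.matrix(region_mask), is.logical(region_mask),
            all(dim(skel) == dim(region_mask)))
  npx <- sum(region_mask)
  if (npx == 0L) stop_octa("empty-region", "region mask selects no pixels")
  sum(skel & region_mask) / npx
}

#' Label connected components of a binary image
#'
#' Stack-based flood fill; 8- or 4-connectivity.
#'
#' @param mask logical matrix.
#' @param connectivity 8 (default) or 4.
#' @return Integer matrix of component labels (0 = background).
#' @export
label_components <- function(mask, connectivity = 8L) {
  stopifnot(is.matrix(mask), is.logical(mask), connectivity %in% c(4L, 8L))
  nr <- nrow(mask); nc <- ncol(mask)
  M <- matrix(FALSE, nr + 2L, nc + 2L)
  M[2:(nr + 1L), 2:(nc + 1L)] <- mask
  nrp <- nr + 2L
  off <- if (connectivity == 8L) nb_offsets(nrp) else c(-1L, 1L, nrp, -nrp)
  lab <- matrix(0L, nrp, nc + 2L)
  cur <- 0L
  todo <- which(M)
  for (start in todo) {
    if (lab[start] != 0L) next
    cur <- cur + 1L
    stack <- start
    lab[start] <- cur
    while (length(stack)) {
      p <- stack[[length(stack)]]
      stack <- stack[-length(stack)]
      nbs <- p + off
      nbs <- nbs[M[nbs] & lab[nbs] == 0L]
      if (length(nbs)) {
        lab[nbs] <- cur
        stack <- c(stack, nbs)
      }
    }
  }
  lab[2:(nr + 1L), 2:(nc + 1L), drop = FALSE]
}
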