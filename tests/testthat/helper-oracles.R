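## Independent brute-force oracles used across the suite. These deliberately
## avoid the package's vectorized code paths: statistics are recomputed by
## direct summation / enumeration.

## Symmetric (edge-mirroring) padded window extraction by index arithmetic.
oracle_window <- function(x, i, j, w) {
  r <- (w - 1L) %/% 2L
  nr <- nrow(x); nc <- ncol(x)
  reflect <- function(idx, n) {
    idx <- ifelse(idx < 1L, 1L - idx, idx)
    ifelse(idx > n, 2L * n + 1L - idx, idx)
  }
  vals <- numeric(w * w)
  k <- 0L
  for (dj in -r:r) for (di in -r:r) {
    k <- k + 1L
    vals[k] <- x[reflect(i + di, nr), reflect(j + dj, nc)]
  }
  vals
}

## Per-pixel local threshold masks recomputed window by window.
oracle_local_mask <- function(x, w, method, k = 0.2, r = 0.5, p = 2, q = 10) {
  nr <- nrow(x); nc <- ncol(x)
  out <- matrix(FALSE, nr, nc)
  for (j in seq_len(nc)) for (i in seq_len(nr)) {
    win <- oracle_window(x, i, j, w)
    m <- sum(win) / length(win)
    s <- sqrt(sum((win - m)^2) / length(win))
    thr <- switch(method,
      niblack = m + k * s,
      phansalkar = m * (1 + p * exp(-q * m) + k * (s / r - 1)),
      otsu = oracle_otsu(win))
    if (!is.na(thr)) out[i, j] <- x[i, j] > thr
  }
  out
}

## Otsu by exhaustive split search over the 256-bin histogram convention
## (values in [0,1], bin = floor(v * 256) clamped to 255, threshold at the
## boundary below the maximizing split, first maximum on ties).
oracle_otsu <- function(v) {
  bins <- pmin(255, pmax(0, floor(v * 256)))
  best <- -Inf; best_k <- NA_integer_
  n <- length(v)
  for (kk in 0:254) {
    n0 <- sum(bins <= kk)
    n1 <- n - n0
    if (n0 == 0 || n1 == 0) next
    mu0 <- mean(bins[bins <= kk]); mu1 <- mean(bins[bins > kk])
    bc <- n0 / n * n1 / n * (mu0 - mu1)^2
    if (bc > best + 1e-12) { best <- bc; best_k <- kk }
  }
  if (is.na(best_k)) return(NA_real_)
  (best_k + 0.5) / 255
}

## Benjamini-Hochberg step-up from the definition.
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  adj <- numeric(m)
  for (i in seq_len(m)) adj[i] <- min(1, min(ps[i:m] * m / (i:m)))
  out <- numeric(m)
  out[o] <- adj
  out
}

## Pearson chi-square by direct O/E summation.
oracle_chisq <- function(tab) {
  e <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  sum((tab - e)^2 / e)
}

## 8-connected component count by union-find (independent of the package's
## flood-fill labeller).
oracle_n_components <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  idx <- which(mask)
  if (!length(idx)) return(0L)
  parent <- seq_along(idx)
  pos <- match(seq_len(nr * nc), idx)
  find <- function(a) { while (parent[a] != a) { parent[a] <<- parent[parent[a]]; a <- parent[a] }; a }
  for (t in seq_along(idx)) {
    p <- idx[t]
    i <- ((p - 1L) %% nr) + 1L; j <- ((p - 1L) %/% nr) + 1L
    for (d in list(c(-1L, -1L), c(0L, -1L), c(1L, -1L), c(-1L, 0L))) {
      ii <- i + d[1L]; jj <- j + d[2L]
      if (ii < 1L || ii > nr || jj < 1L || jj > nc) next
      q <- (jj - 1L) * nr + ii
      if (!mask[q]) next
      ra <- find(t); rb <- find(pos[q])
      if (ra != rb) parent[ra] <- rb
    }
  }
  length(unique(vapply(seq_along(idx), find, integer(1))))
}

## Random blob masks for skeleton-contract tests: a few random discs and
## thick line segments on a small canvas.
random_blob_mask <- function(n = 48L) {
  m <- matrix(FALSE, n, n)
  for (b in seq_len(sample(2:5, 1))) {
    if (runif(1) < 0.5) {
      cx <- runif(1, 5, n - 5); cy <- runif(1, 5, n - 5); rr <- runif(1, 2, 6)
      m <- m | outer(1:n, 1:n, function(i, j) (i - cy)^2 + (j - cx)^2 <= rr^2)
    } else {
      x0 <- runif(1, 3, n - 3); y0 <- runif(1, 3, n - 3)
      ang <- runif(1, 0, 2 * pi); len <- runif(1, 8, n)
      tseq <- seq(0, 1, length.out = 2 * len)
      xs <- pmin(n, pmax(1, round(x0 + tseq * len * cos(ang))))
      ys <- pmin(n, pmax(1, round(y0 + tseq * len * sin(ang))))
      wd <- sample(1:3, 1)
      for (t in seq_along(xs)) {
        ii <- max(1, ys[t] - wd):min(n, ys[t] + wd)
        jj <- max(1, xs[t] - wd):min(n, xs[t] + wd)
        m[ii, jj] <- TRUE
      }
    }
  }
  m
}

## Shared tiny specs.
spec_mac <- function(px = 256L) image_spec(px, px, 3, "macula", "OD")
spec_onh <- function(px = 256L) image_spec(px, px, 6, "onh", "OD")
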