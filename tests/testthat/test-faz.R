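test_that("closed-form shapes give the expected acircularity", {
  spec <- spec_mac(512)
  ## 360-gon circle: acircularity 1 within 1e-4
  th <- seq(0, 2 * pi, length.out = 361)[-361]
  circ <- cbind(256 + 80 * cos(th), 256 + 80 * sin(th))
  m <- faz_metrics(faz_outline(circ, spec))
  expect_equal(m$acircularity, 1, tolerance = 1e-4)
  expect_equal(m$area_mm2, pi * (80 * mm_per_px(spec))^2, tolerance = 1e-3)

  ## square of side s: A = s^2, P = 4 s, acircularity = 2 / sqrt(pi)
  sq <- cbind(c(100, 200, 200, 100), c(100, 100, 200, 200))
  ms <- faz_metrics(faz_outline(sq, spec))
  px <- mm_per_px(spec)
  expect_equal(ms$area_mm2, (100 * px)^2, tolerance = 1e-12)
  expect_equal(ms$perimeter_mm, 400 * px, tolerance = 1e-12)
  expect_equal(ms$acircularity, 2 / sqrt(pi), tolerance = 1e-12)
})

test_that("scale, rotation and translation behave as geometry dictates", {
  spec <- spec_mac(512)
  set.seed(5)
  th <- sort(runif(24, 0, 2 * pi))
  rad <- runif(24, 30, 60)
  poly <- cbind(250 + rad * cos(th), 250 + rad * sin(th))
  m0 <- faz_metrics(faz_outline(poly, spec))

  c0 <- colMeans(poly)
  m2 <- faz_metrics(faz_outline(sweep(sweep(poly, 2, c0), 2, c0, `+`) , spec))
  sc <- sweep(sweep(poly, 2, c0) * 1.7, 2, c0, `+`)
  msc <- faz_metrics(faz_outline(sc, spec))
  expect_equal(msc$area_mm2, 1.7^2 * m0$area_mm2, tolerance = 1e-12)
  expect_equal(msc$perimeter_mm, 1.7 * m0$perimeter_mm, tolerance = 1e-12)
  expect_equal(msc$acircularity, m0$acircularity, tolerance = 1e-12)

  ang <- 0.73
  R <- matrix(c(cos(ang), sin(ang), -sin(ang), cos(ang)), 2)
  rot <- sweep(sweep(poly, 2, c0) %*% R, 2, c0 + c(5, -8), `+`)
  mr <- faz_metrics(faz_outline(rot, spec))
  expect_equal(mr$area_mm2, m0$area_mm2, tolerance = 1e-9)
  expect_equal(mr$perimeter_mm, m0$perimeter_mm, tolerance = 1e-9)
  expect_equal(mr$acircularity, m0$acircularity, tolerance = 1e-9)
})

test_that("every valid outline satisfies the isoperimetric bound", {
  spec <- spec_mac(256)
  set.seed(8)
  for (rep in 1:50) {
    th <- sort(runif(sample(8:30, 1), 0, 2 * pi))
    rad <- runif(length(th), 10, 50)
    poly <- cbind(128 + rad * cos(th), 128 + rad * sin(th))
    m <- faz_metrics(faz_outline(poly, spec))
    expect_gte(m$acircularity, 1 - 0.01)
  }
})

test_that("polygon metrics agree with a rasterization oracle", {
  spec <- spec_mac(256)
  set.seed(14)
  for (rep in 1:5) {
    th <- sort(runif(40, 0, 2 * pi))
    rad <- runif(40, 30, 60)
    poly <- cbind(120 + rad * cos(th), 120 + rad * sin(th))
    m <- faz_metrics(faz_outline(poly, spec))
    ## oracle: count pixel centers inside the polygon (even-odd ray casting,
    ## an entirely different area computation than the shoelace formula)
    g <- expand.grid(x = (1:256) - 0.5, y = (1:256) - 0.5)
    crossings <- integer(nrow(g))
    n <- nrow(poly)
    for (e in 1:n) {
      x1 <- poly[e, 1]; y1 <- poly[e, 2]
      x2 <- poly[e %% n + 1, 1]; y2 <- poly[e %% n + 1, 2]
      hit <- ((y1 > g$y) != (y2 > g$y)) &
        (g$x < x1 + (g$y - y1) / (y2 - y1) * (x2 - x1))
      crossings <- crossings + hit
    }
    inside <- sum(crossings %% 2L == 1L)
    expect_equal(m$area_mm2, inside * mm_per_px(spec)^2, tolerance = 0.02)
  }
})

test_that("self-intersecting or degenerate outlines are rejected", {
  spec <- spec_mac(128)
  bow <- cbind(c(10, 50, 50, 10), c(10, 50, 10, 50))
  expect_error(faz_outline(bow, spec), class = "invalid-outline")
  expect_error(faz_outline(cbind(c(1, 2), c(1, 2)), spec), class = "invalid-outline")
})

test_that("automatic FAZ extraction recovers the planted zone", {
  spec <- spec_mac(256)
  out <- generate_angiogram(spec, vessel_sim_config(n_seeds = 30, seed = 9,
                                                    noise_sd = 0, faz_area_mm2 = 0.25))
  bm <- binarize(out$image, default_threshold_params("macula"))
  m <- faz_metrics(auto_faz_outline(bm$mask, spec))
  expect_lt(abs(m$area_mm2 - 0.25) / 0.25, 0.10)

  ## planted polygon area itself is within 15% of the target (circular case)
  v <- out$truth$faz_polygon
  nxt <- c(2:nrow(v), 1)
  a <- abs(sum(v[, 1] * v[nxt, 2] - v[nxt, 1] * v[, 2])) / 2 * mm_per_px(spec)^2
  expect_lt(abs(a - 0.25) / 0.25, 0.15)

  ## no vessel pixel strictly inside the planted polygon
  r0 <- sqrt(0.25 / pi) / mm_per_px(spec)
  ctr <- expand.grid(i = 1:256, j = 1:256)
  rr <- matrix(sqrt((ctr$j - 0.5 - 128)^2 + (ctr$i - 0.5 - 128)^2), 256)
  expect_identical(sum(out$truth$vessel_mask & rr < r0 - 1), 0L)
})

test_that("planted outline irregularity raises recovered acircularity", {
  spec <- spec_mac(256)
  f <- function(irr) {
    out <- generate_angiogram(spec, vessel_sim_config(n_seeds = 30, seed = 5,
                                                      noise_sd = 0,
                                                      faz_irregularity = irr))
    bm <- binarize(out$image, default_threshold_params("macula"))
    faz_metrics(auto_faz_outline(bm$mask, spec))$acircularity
  }
  expect_gt(f(0.6), f(0))
})

test_that("FAZ error paths signal the documented conditions", {
  spec <- spec_mac(64)
  allv <- matrix(TRUE, 64, 64)
  expect_error(auto_faz_outline(allv, spec), class = "no-faz-at-center")
  ## avascular everywhere: region reaches the border
  expect_error(auto_faz_outline(matrix(FALSE, 64, 64), spec), class = "unbounded-faz")
})

test_that("outlines round-trip through CSV", {
  spec <- spec_mac(128)
  th <- seq(0, 2 * pi, length.out = 13)[-13]
  poly <- cbind(64 + 20 * cos(th), 64 + 20 * sin(th))
  o <- faz_outline(poly, spec)
  f <- tempfile(fileext = ".csv")
  write_faz_outline(o, f)
  o2 <- read_faz_outline(f, spec)
  expect_equal(o2$vertices, o$vertices, tolerance = 1e-12, ignore_attr = TRUE)
  unlink(f)
})
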