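test_that("the 8 ONH masks partition the annulus and match analytic sector areas", {
  spec <- image_spec(512, 512, 6, "onh", "OD")
  masks <- build_region_masks(spec)
  expect_length(masks, 8L)

  ## partition: union equals the annulus pixel set, pairwise disjoint
  pc <- expand.grid(i = 1:512, j = 1:512)
  r_mm <- matrix(sqrt((pc$j - 0.5 - 256)^2 + (pc$i - 0.5 - 256)^2), 512) * mm_per_px(spec)
  annulus <- r_mm > 0.5 & r_mm <= 3.0
  stack <- Reduce(`+`, lapply(masks, function(m) m * 1L))
  expect_true(all(stack <= 1L))
  expect_identical(stack == 1L, annulus)

  ## rasterized areas within 1% of the analytic sector areas
  s2 <- mm_per_px(spec)^2
  a_inner <- pi * (1.5^2 - 0.5^2) / 4
  a_outer <- pi * (3.0^2 - 1.5^2) / 4
  for (nm in names(masks)) {
    want <- if (grepl("^inner", nm)) a_inner else a_outer
    expect_lt(abs(sum(masks[[nm]]) * s2 - want) / want, 0.01)
  }
})

test_that("a 3 mm macula grid yields exactly the 4 inner-ring regions", {
  spec <- image_spec(512, 512, 3, "macula", "OS")
  masks <- build_region_masks(spec)
  expect_length(masks, 4L)
  expect_true(all(grepl("^inner", names(masks))))
  regions <- etdrs_regions("macula")
  expect_true(all(regions$ring == "inner"))
})

test_that("nasal/temporal assignment mirrors with laterality", {
  ## a marker on the image-left side of the inner annulus
  left_marker <- matrix(FALSE, 256, 256)
  left_marker[126:130, 30:70] <- TRUE
  for (lat in c("OD", "OS")) {
    spec <- image_spec(256, 256, 3, "macula", lat)
    masks <- build_region_masks(spec)
    dens <- vapply(masks, function(m) sum(left_marker & m), numeric(1))
    hit <- names(which.max(dens))
    expect_identical(hit, if (lat == "OD") "inner_temporal" else "inner_nasal")
  }
})

test_that("rotating the image by 90 degrees permutes quadrant densities", {
  out <- generate_angiogram(spec_mac(192),
                            vessel_sim_config(n_seeds = 25, seed = 13, noise_sd = 0))
  sk <- skeletonize(out$truth$vessel_mask)$skeleton
  spec <- spec_mac(192)
  d0 <- extract_region_densities(sk, etdrs_grid(spec))
  ## rotate 90 degrees counterclockwise on screen: superior -> left side
  skr <- t(sk)[ncol(sk):1, ]
  dr <- extract_region_densities(skr, etdrs_grid(spec))
  g <- function(df, q) df$density[df$quadrant == q & !is.na(df$quadrant)]
  ## OD: left = temporal; ccw rotation sends superior->temporal(left),
  ## temporal(left)->inferior, inferior->nasal(right), nasal->superior
  expect_equal(g(dr, "temporal"), g(d0, "superior"), tolerance = 1e-12)
  expect_equal(g(dr, "inferior"), g(d0, "temporal"), tolerance = 1e-12)
  expect_equal(g(dr, "nasal"), g(d0, "inferior"), tolerance = 1e-12)
  expect_equal(g(dr, "superior"), g(d0, "nasal"), tolerance = 1e-12)
})

test_that("grid centering offsets compose and invert", {
  spec <- spec_mac(256)
  g0 <- center_grid(spec, c(0, 0))
  expect_identical(g0$center_px, c(128, 128))
  g1 <- center_grid(spec, c(10, 0))
  g2 <- center_grid(spec, c(-10, 0))
  expect_identical((g1$center_px + g2$center_px) / 2, g0$center_px)
  expect_error(center_grid(spec, c(1e4, 0)), class = "center-out-of-bounds")
})

test_that("small centering jitter perturbs regional densities by under 5%", {
  out <- generate_angiogram(spec_mac(512),
                            vessel_sim_config(n_seeds = 40, seed = 17, noise_sd = 0))
  sk <- skeletonize(out$truth$vessel_mask)$skeleton
  spec <- spec_mac(512)
  d0 <- extract_region_densities(sk, etdrs_grid(spec))
  set.seed(1)
  for (rep in 1:5) {
    off <- runif(2, -2, 2)
    dj <- extract_region_densities(sk, center_grid(spec, off))
    rel <- abs(dj$density - d0$density) / d0$density
    expect_lt(max(rel), 0.05)
  }
})

test_that("regional density records include an exact across-region mean", {
  out <- generate_angiogram(spec_onh(192),
                            vessel_sim_config(n_seeds = 30, seed = 19, noise_sd = 0))
  sk <- skeletonize(out$truth$vessel_mask)$skeleton
  df <- extract_region_densities(sk, etdrs_grid(spec_onh(192)),
                                 meta = list(subject = "S1", eye = "OD"))
  expect_identical(nrow(df), 9L)
  expect_equal(df$density[df$region == "mean"],
               mean(df$density[df$region != "mean"]), tolerance = 1e-15)
  expect_true(all(c("subject", "eye") %in% names(df)))
})

test_that("measured regional densities track planted ground truth", {
  ## across regions and images, skeleton density is proportional to the
  ## planted mask density (skeletonization rescales, correlation remains)
  planted <- measured <- numeric(0)
  for (s in c(31, 32, 33, 34)) {
    mult <- c(temporal = 0.3, nasal = 0.6, inferior = 1, superior = 1)
    out <- generate_angiogram(spec_mac(256),
                              vessel_sim_config(n_seeds = 40, branch_prob = 0.08,
                                                seed = s, noise_sd = 0,
                                                regional_multipliers = mult))
    sk <- skeletonize(binarize(out$image, default_threshold_params("macula")))$skeleton
    df <- extract_region_densities(sk, etdrs_grid(spec_mac(256)))
    df <- df[df$region != "mean", ]
    planted <- c(planted, out$truth$region_true_density[df$region])
    measured <- c(measured, df$density)
  }
  expect_gte(stats::cor(planted, measured), 0.95)
})

test_that("planted temporal thinning halves the measured temporal density", {
  mult <- c(temporal = 0.5)
  out <- generate_angiogram(spec_mac(256),
                            vessel_sim_config(n_seeds = 30, seed = 23, noise_sd = 0,
                                              regional_multipliers = mult))
  sk <- skeletonize(binarize(out$image, default_threshold_params("macula")))$skeleton
  df <- extract_region_densities(sk, etdrs_grid(spec_mac(256)))
  tmp <- df$density[df$quadrant == "temporal" & !is.na(df$quadrant)]
  oth <- mean(df$density[!is.na(df$quadrant) & df$quadrant != "temporal"])
  expect_lt(tmp / oth, 0.75)
  expect_gt(tmp / oth, 0.3)
})
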