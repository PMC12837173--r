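#' Configuration for the synthetic vessel-network generator
#'
#' The generator draws a branching vascular network as a biased random walk:
#' root walkers start on the image border (macula scans, growing inward) or
#' on the optic-disc margin (ONH scans, growing outward), take fixed-length
#' steps with angular jitter, and spawn binary branches. Segments are stamped
#' with a small disc brush 1-3 px wide. Growth stops once the network's
#' unmodulated coverage reaches `base_density`. Regional multipliers gate
#' drawing per walker: each walker carries one uniform draw and stamps pixels
#' inside an ETDRS region only when that draw falls below the region's
#' multiplier, so a multiplier of 0.5 removes about half the vessels crossing
#' the region at full caliber — both mask density and skeleton length scale
#' with the multiplier — without touching any other region. Trajectories and
#' random-number consumption are identical across multiplier settings at a
#' fixed seed, which makes regional density monotone in the multiplier.
#'
#' For macula scans an avascular zone with target area `faz_area_mm2` is
#' carved at the center; its outline radius is modulated by random low-order
#' harmonics scaled by `faz_irregularity` (0 = circle). For ONH scans a
#' bright 1.5 mm diameter disc with no vessels inside marks the nerve head.
#'
#' The background is multiplicative speckle: Gaussian noise of standard
#' deviation `noise_sd` on log-intensity (approximately the coefficient of
#' variation), clipped to [0, 1] — OCTA decorrelation noise is speckle-like.
#'
#' @param n_seeds number of root walkers.
#' @param branch_prob branching probability per growth step.
#' @param step_px growth step length in pixels.
#' @param max_steps maximum steps per walker.
#' @param base_density target unmodulated vessel-pixel fraction (0-1).
#' @param regional_multipliers named numeric vector, ETDRS region label (or
#'   quadrant name, applied to both rings) to multiplicative density factor.
#' @param faz_area_mm2 target FAZ area (macula only).
#' @param faz_irregularity 0 = circular FAZ outline; larger = more lobed.
#' @param noise_sd log-intensity speckle standard deviation.
#' @param vessel_intensity,background_intensity mean levels on [0, 1].
#' @param seed integer RNG seed.
#' @return An object of class `vessel_sim_config`.
#' @export
vessel_sim_config <- function(n_seeds = 40L, branch_prob = 0.05, step_px = 2,
                              max_steps = 1500L, base_density = 0.12,
                              regional_multipliers = numeric(0),
                              faz_area_mm2 = 0.3, faz_irregularity = 0,
                              noise_sd = 0.3,
                              vessel_intensity = 0.85, background_intensity = 0.15,
                              seed = 1L) {
  if (base_density < 0 || base_density > 1)
    stop_octa("invalid-config", "base_density must lie in [0, 1]")
  if (length(regional_multipliers) && any(regional_multipliers < 0))
    stop_octa("invalid-config", "regional multipliers must be >= 0")
  if (faz_area_mm2 < 0) stop_octa("invalid-config", "faz_area_mm2 must be >= 0")
  structure(list(n_seeds = as.integer(n_seeds), branch_prob = branch_prob,
                 step_px = step_px, max_steps = as.integer(max_steps),
                 base_density = base_density,
                 regional_multipliers = regional_multipliers,
                 faz_area_mm2 = faz_area_mm2, faz_irregularity = faz_irregularity,
                 noise_sd = noise_sd, vessel_intensity = vessel_intensity,
                 background_intensity = background_intensity,
                 seed = as.integer(seed)),
            class = "vessel_sim_config")
}

## Star-shaped FAZ radial function r(theta) in mm; vertices and raster tests
## share it exactly, so the polygon and the carved region agree.
faz_radius_fun <- function(cfg) {
  r0 <- sqrt(cfg$faz_area_mm2 / pi)
  if (cfg$faz_irregularity <= 0 || cfg$faz_area_mm2 <= 0) {
    function(theta) rep(r0, length(theta))
  } else {
    amp <- stats::rnorm(3) * cfg$faz_irregularity / c(2, 3, 4)
    phase <- stats::runif(3, 0, 2 * pi)
    function(theta) {
      mod <- 1 + amp[1] * cos(2 * theta + phase[1]) +
        amp[2] * cos(3 * theta + phase[2]) + amp[3] * cos(4 * theta + phase[3])
      pmax(0.1 * r0, r0 * mod)
    }
  }
}

## Disc-brush pixel offsets (row, col) for a stroke width in px.
brush_offsets <- function(width) {
  r <- (width - 1) / 2
  span <- seq(-ceiling(r), ceiling(r))
  g <- expand.grid(dr = span, dc = span)
  g <- g[g$dr^2 + g$dc^2 <= r^2 + 0.26, , drop = FALSE]
  as.matrix(g)
}

#' Generate a synthetic en-face angiogram with ground truth
#'
#' See [vessel_sim_config()] for the generative model. Determinism: the same
#' `spec`, `cfg` and seed yield bit-identical output.
#'
#' @param spec an [image_spec()].
#' @param cfg a [vessel_sim_config()].
#' @return A list with `image` (an [enface_angiogram()]) and `truth`, a list
#'   holding the boolean `vessel_mask`, the per-region planted density
#'   `region_true_density`, and `faz_polygon` (macula) / `disc_mask` (ONH).
#'   Signals `"undersaturated"` if `base_density` cannot be reached with the
#'   configured walker budget.
#' @examples
#' spec <- image_spec(128, 128, 3, "macula", "OD")
#' out <- generate_angiogram(spec, vessel_sim_config(n_seeds = 12, seed = 7))
#' mean(out$truth$vessel_mask)
#' @export
generate_angiogram <- function(spec, cfg) {
  stopifnot(inherits(spec, "image_spec"), inherits(cfg, "vessel_sim_config"))
  with_seed(cfg$seed, generate_angiogram_impl(spec, cfg))
}

generate_angiogram_impl <- function(spec, cfg) {
  nr <- spec$height_px; nc <- spec$width_px
  npx <- nr * nc
  scale <- mm_per_px(spec)
  cx <- nc / 2; cy <- nr / 2
  macula <- spec$center_type == "macula"

  ## --- forbidden region: FAZ (macula) or optic disc (ONH) ---
  pc <- pixel_centers(spec)
  faz_polygon <- NULL
  disc_mask <- NULL
  forbid <- matrix(FALSE, nr, nc)
  if (macula && cfg$faz_area_mm2 > 0) {
    rfun <- faz_radius_fun(cfg)
    dx <- (pc$x - cx) * scale; dy <- (cy - pc$y) * scale
    rr <- sqrt(dx^2 + dy^2); th <- atan2(dy, dx)
    forbid <- rr < rfun(th)
    vth <- seq(0, 2 * pi, length.out = 73)[-73]
    vr <- rfun(vth) / scale
    faz_polygon <- cbind(x = cx + vr * cos(vth), y = cy - vr * sin(vth))
  } else if (!macula) {
    rfun <- NULL
    disc_r_mm <- 0.75
    dx <- (pc$x - cx) * scale; dy <- (cy - pc$y) * scale
    disc_mask <- sqrt(dx^2 + dy^2) <= disc_r_mm
    forbid <- disc_mask
  }

  ## --- region multiplier lookup image ---
  masks <- build_region_masks(spec, etdrs_grid(spec))
  mult_img <- matrix(1, nr, nc)
  rm <- cfg$regional_multipliers
  if (length(rm)) {
    regions <- etdrs_regions(spec$center_type)
    for (nm in names(rm)) {
      hit <- if (nm %in% regions$region) nm
             else regions$region[regions$quadrant == nm]
      for (h in hit) mult_img[masks[[h]]] <- rm[[nm]]
    }
  }

  potential <- matrix(FALSE, nr, nc)   # coverage if all multipliers were 1
  drawn <- matrix(FALSE, nr, nc)       # actually drawn vessel pixels
  target_px <- cfg$base_density * npx
  ## Perifoveal capillary ring: a closed vessel loop hugging the FAZ
  ## boundary (as in real maculae), so the avascular zone is a bounded
  ## component and automatic outline extraction is well defined.
  if (macula && cfg$faz_area_mm2 > 0) {
    rmax_px <- max(rfun(seq(0, 2 * pi, length.out = 181))) / scale
    thr <- seq(0, 2 * pi, length.out = max(64L, ceiling(4 * pi * rmax_px)))
    rr_px <- rfun(thr) / scale + 1.2
    bo <- brush_offsets(2)
    ring_i <- rep(ceiling(cy - rr_px * sin(thr)), each = nrow(bo)) + bo[, 1]
    ring_j <- rep(ceiling(cx + rr_px * cos(thr)), each = nrow(bo)) + bo[, 2]
    keep <- ring_i >= 1 & ring_i <= nr & ring_j >= 1 & ring_j <= nc
    ring_lin <- unique((ring_j[keep] - 1L) * nr + ring_i[keep])
    ring_lin <- ring_lin[!forbid[ring_lin]]
    potential[ring_lin] <- TRUE
    drawn[ring_lin] <- TRUE
  }

  ## Per-walker acceptance draw: walker w draws inside region R iff
  ## u_w < multiplier[R], so a vessel either grows through a region at full
  ## caliber or skips it entirely — regional mask density and skeleton
  ## length then both scale like the multiplier. A single uniform per walker
  ## (consumed regardless of the multipliers) keeps trajectories and RNG
  ## state identical across multiplier settings, making regional density
  ## monotone in the multiplier and leaving other regions untouched at a
  ## fixed seed.

  if (cfg$n_seeds > 0L && cfg$base_density > 0) {
    ## root walkers
    walkers <- vector("list", cfg$n_seeds)
    for (i in seq_len(cfg$n_seeds)) {
      if (macula) {
        side <- sample.int(4L, 1L)
        pos <- switch(side,
          c(stats::runif(1, 0, nc), 0),            # top
          c(stats::runif(1, 0, nc), nr),           # bottom
          c(0, stats::runif(1, 0, nr)),            # left
          c(nc, stats::runif(1, 0, nr)))           # right
        ang <- atan2(cy - pos[2], cx - pos[1]) + stats::rnorm(1, 0, 0.5)
      } else {
        th0 <- stats::runif(1, 0, 2 * pi)
        rpx <- 0.75 / scale
        pos <- c(cx + rpx * cos(th0), cy - rpx * sin(th0))
        ang <- atan2(pos[2] - cy, pos[1] - cx) * -1  # outward (y down)
        ang <- atan2(-(cy - pos[2]), pos[1] - cx) + stats::rnorm(1, 0, 0.4)
      }
      walkers[[i]] <- list(pos = pos, ang = ang,
                           width = sample(2:3, 1L), steps = 0L,
                           u = stats::runif(1))
    }
    brushes <- lapply(1:3, brush_offsets)
    reached <- FALSE
    while (length(walkers) && !reached) {
      nxt <- list()
      for (wk in walkers) {
        pos <- wk$pos; ang <- wk$ang
        width <- wk$width; steps <- wk$steps; uw <- wk$u
        alive <- TRUE
        while (alive && steps < cfg$max_steps) {
          steps <- steps + 1L
          ang <- ang + stats::rnorm(1, 0, 0.25)
          pos2 <- pos + cfg$step_px * c(cos(ang), sin(ang))
          i2 <- ceiling(pos2[2]); j2 <- ceiling(pos2[1])
          if (i2 < 1 || i2 > nr || j2 < 1 || j2 > nc) { alive <- FALSE; break }
          if (forbid[i2, j2]) { alive <- FALSE; break }
          ## stamp the brush along the segment so strokes stay connected
          nsub <- max(1L, ceiling(cfg$step_px / 0.7))
          tfrac <- seq_len(nsub) / nsub
          pi_ <- ceiling(pos[2] + tfrac * (pos2[2] - pos[2]))
          pj_ <- ceiling(pos[1] + tfrac * (pos2[1] - pos[1]))
          off <- brushes[[width]]
          ri <- rep(pi_, each = nrow(off)) + off[, 1]
          ci <- rep(pj_, each = nrow(off)) + off[, 2]
          keep <- ri >= 1 & ri <= nr & ci >= 1 & ci <= nc
          lin <- unique((ci[keep] - 1L) * nr + ri[keep])
          lin <- lin[!forbid[lin]]
          potential[lin] <- TRUE
          drawn[lin[uw < mult_img[lin]]] <- TRUE
          pos <- pos2
          if (stats::runif(1) < cfg$branch_prob) {
            bang <- ang + sample(c(-1, 1), 1) * stats::runif(1, pi / 6, pi / 3)
            nxt[[length(nxt) + 1L]] <- list(pos = pos, ang = bang,
                                            width = max(1L, width - 1L),
                                            steps = steps, u = stats::runif(1))
          }
          if (sum(potential) >= target_px) { reached <- TRUE; break }
        }
      }
      walkers <- if (reached) list() else nxt
    }
    if (!reached && sum(potential) < target_px)
      stop_octa("undersaturated",
                "base_density %.3f unreachable with n_seeds = %d (coverage %.3f)",
                cfg$base_density, cfg$n_seeds, sum(potential) / npx)
  }

  ## --- intensity image with multiplicative speckle ---
  base <- matrix(cfg$background_intensity, nr, nc)
  base[drawn] <- cfg$vessel_intensity
  if (!macula && !is.null(disc_mask)) base[disc_mask] <- 0.9
  if (cfg$noise_sd > 0) {
    z <- matrix(stats::rnorm(npx, 0, cfg$noise_sd), nr, nc)
    base <- base * exp(z - cfg$noise_sd^2 / 2)
  }
  pixels <- matrix(as.integer(round(clip01(base) * 255)), nr, nc)

  region_true_density <- vapply(masks, function(m) {
    if (sum(m) == 0L) return(0)
    sum(drawn & m) / sum(m)
  }, numeric(1))

  list(image = enface_angiogram(pixels, spec),
       truth = list(vessel_mask = drawn,
                    region_true_density = region_true_density,
                    faz_polygon = faz_polygon,
                    disc_mask = disc_mask))
}

#' Configuration for a two-group synthetic cohort
#'
#' Defines the simulated study population: group sizes (defaults echo a
#' 39-control / 51-case design), a fractional temporal vessel-density deficit
#' `temporal_deficit` planted in the case (SSD) group, demographics, and the
#' variance components of the planted repeated-measures structure (random
#' subject intercept, random eye-within-subject intercept, residual). Ages
#' are drawn from a normal distribution truncated to [18, 70]. An optional
#' `deficit_old` makes the deficit age-dependent: subjects aged > 30 receive
#' `deficit_old` instead of `temporal_deficit`.
#'
#' @param n_control,n_ssd subjects per group.
#' @param temporal_deficit fractional density reduction (0-1) in the SSD
#'   group's temporal region.
#' @param deficit_old optional deficit for SSD subjects aged > 30 (defaults
#'   to `temporal_deficit`, i.e. no age dependence).
#' @param age_mean,age_sd,age_range age distribution (years).
#' @param male_frac_control,male_frac_ssd probability of male sex per group.
#' @param base_density mean density on the measurement scale.
#' @param subject_sd,eye_sd,residual_sd planted variance components.
#' @param ring_offset additive inner-minus-outer density offset (ONH).
#' @param rnfl_slope,rnfl_sd RNFL thickness simulated as
#'   `90 + rnfl_slope * (density - base_density) + N(0, rnfl_sd)` per quadrant.
#' @param seed integer RNG seed.
#' @return An object of class `cohort_sim_config`.
#' @export
cohort_sim_config <- function(n_control = 39L, n_ssd = 51L,
                              temporal_deficit = 0.3, deficit_old = NULL,
                              age_mean = 35.7, age_sd = 12.5,
                              age_range = c(18, 70),
                              male_frac_control = 17 / 39,
                              male_frac_ssd = 39 / 51,
                              base_density = 0.07,
                              subject_sd = 0.008, eye_sd = 0.004,
                              residual_sd = 0.010,
                              ring_offset = 0,
                              rnfl_slope = 400, rnfl_sd = 8,
                              seed = 1L) {
  if (temporal_deficit < 0 || temporal_deficit > 1)
    stop_octa("invalid-config", "temporal_deficit must lie in [0, 1]")
  if (subject_sd < 0 || eye_sd < 0 || residual_sd < 0)
    stop_octa("invalid-config", "variance components must be >= 0")
  if (n_control < 1L || n_ssd < 1L)
    stop_octa("invalid-config", "both groups need at least one subject")
  structure(list(n_control = as.integer(n_control), n_ssd = as.integer(n_ssd),
                 temporal_deficit = temporal_deficit,
                 deficit_old = deficit_old %||% temporal_deficit,
                 age_mean = age_mean, age_sd = age_sd, age_range = age_range,
                 male_frac_control = male_frac_control,
                 male_frac_ssd = male_frac_ssd,
                 base_density = base_density, subject_sd = subject_sd,
                 eye_sd = eye_sd, residual_sd = residual_sd,
                 ring_offset = ring_offset,
                 rnfl_slope = rnfl_slope, rnfl_sd = rnfl_sd,
                 seed = as.integer(seed)),
            class = "cohort_sim_config")
}

rtrunc_norm <- function(n, mean, sd, lo, hi) {
  x <- stats::rnorm(n, mean, sd)
  bad <- which(x < lo | x > hi)
  while (length(bad)) {
    x[bad] <- stats::rnorm(length(bad), mean, sd)
    bad <- bad[x[bad] < lo | x[bad] > hi]
  }
  x
}

## Subject-level demographics shared by both cohort simulators.
simulate_subjects <- function(cfg) {
  n <- cfg$n_control + cfg$n_ssd
  data.frame(
    subject = sprintf("S%03d", seq_len(n)),
    diagnosis = rep(c("control", "ssd"), c(cfg$n_control, cfg$n_ssd)),
    age = round(rtrunc_norm(n, cfg$age_mean, cfg$age_sd,
                            cfg$age_range[1], cfg$age_range[2]), 1),
    sex = ifelse(stats::runif(n) < rep(c(cfg$male_frac_control, cfg$male_frac_ssd),
                                       c(cfg$n_control, cfg$n_ssd)), "M", "F"),
    axial_length = round(stats::rnorm(n, 23.8, 0.9), 2),
    ssi = pmin(10L, pmax(7L, as.integer(round(stats::rnorm(n, 9.3, 0.7))))),
    stringsAsFactors = FALSE)
}

subject_deficit <- function(cfg, diagnosis, age) {
  ifelse(diagnosis == "ssd",
         ifelse(age > 30, cfg$deficit_old, cfg$temporal_deficit), 0)
}

#' Simulate measurement-level regional densities for a cohort
#'
#' Draws per-region skeletonized vessel densities directly from the planted
#' mixed-effects measurement model, without rasterizing images:
#' `density = base * (1 - deficit * temporal) + ring_offset/2 * inner -
#' ring_offset/2 * outer + b_subject + b_eye + noise`, with independent
#' Gaussian random intercepts for subject and eye-within-subject. This is the
#' generator used for statistical calibration (type-I error, power, age
#' stratification), where thousands of cohort replicates are needed; the
#' image-level path ([generate_cohort()]) plants the same structure through
#' actual rasterized angiograms.
#'
#' Densities falling outside [0, 1] are clipped and counted in the
#' `clipped` attribute.
#'
#' @param cfg a [cohort_sim_config()].
#' @param site `"onh"` (4 quadrants x 2 rings x 2 eyes) or `"macula"`
#'   (4 quadrants x 2 eyes).
#' @return data.frame of density records: `subject`, `eye`, `diagnosis`,
#'   `age`, `sex`, `site`, `quadrant`, `ring`, `density`, plus simulated
#'   per-quadrant `rnfl` thickness (ONH).
#' @export
simulate_cohort_densities <- function(cfg, site = c("onh", "macula")) {
  site <- match.arg(site)
  stopifnot(inherits(cfg, "cohort_sim_config"))
  with_seed(cfg$seed, {
    subj <- simulate_subjects(cfg)
    n <- nrow(subj)
    rings <- if (site == "onh") c("inner", "outer") else "inner"
    d <- expand.grid(quadrant = c("superior", "nasal", "inferior", "temporal"),
                     ring = rings, eye = c("OD", "OS"),
                     subject = subj$subject,
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    d <- merge(d, subj, by = "subject", sort = FALSE)
    d <- d[order(d$subject, d$eye, d$ring, d$quadrant), ]
    rownames(d) <- NULL
    b_subj <- stats::rnorm(n, 0, cfg$subject_sd)
    names(b_subj) <- subj$subject
    eye_key <- paste(d$subject, d$eye)
    ueyes <- unique(eye_key)
    b_eye <- stats::rnorm(length(ueyes), 0, cfg$eye_sd)
    names(b_eye) <- ueyes
    delta <- subject_deficit(cfg, d$diagnosis, d$age)
    mu <- cfg$base_density * (1 - delta * (d$quadrant == "temporal")) +
      ifelse(d$ring == "inner", cfg$ring_offset / 2, -cfg$ring_offset / 2)
    dens <- mu + b_subj[d$subject] + b_eye[eye_key] +
      stats::rnorm(nrow(d), 0, cfg$residual_sd)
    nclip <- sum(dens < 0 | dens > 1)
    if (nclip > 0)
      warning(sprintf("%d simulated densities clipped to [0, 1]", nclip))
    d$site <- site
    d$density <- clip01(dens)
    if (site == "onh")
      d$rnfl <- round(90 + cfg$rnfl_slope * (d$density - cfg$base_density) +
                        stats::rnorm(nrow(d), 0, cfg$rnfl_sd), 1)
    attr(d, "clipped") <- nclip
    attr(d, "truth") <- list(base_density = cfg$base_density,
                             temporal_deficit = cfg$temporal_deficit,
                             deficit_old = cfg$deficit_old)
    d
  })
}

#' Generate a full image-level synthetic cohort
#'
#' For every subject and eye, generates a macula and an ONH angiogram whose
#' per-eye base density carries the planted subject and eye random offsets,
#' and whose temporal ETDRS region is thinned by the group deficit for SSD
#' eyes. Intended for end-to-end pipeline validation at modest sample sizes
#' (image rasterization dominates run time).
#'
#' @param spec_macula,spec_onh [image_spec()] templates (laterality is set
#'   per eye).
#' @param cfg a [cohort_sim_config()].
#' @param img_cfg a [vessel_sim_config()] template for the per-eye images.
#' @return A list with `cohort` (one row per eye: demographics + per-eye
#'   seeds) and `eyes`, a list of per-eye entries `(subject, eye, macula,
#'   onh)` where each site holds the [generate_angiogram()] output.
#' @export
generate_cohort <- function(spec_macula, spec_onh, cfg,
                            img_cfg = vessel_sim_config()) {
  stopifnot(inherits(cfg, "cohort_sim_config"))
  subj <- with_seed(cfg$seed, {
    s <- simulate_subjects(cfg)
    n <- nrow(s)
    s$b_subject <- stats::rnorm(n, 0, cfg$subject_sd)
    s
  })
  rows <- list(); eyes <- list()
  k <- 0L
  for (i in seq_len(nrow(subj))) {
    for (eye in c("OD", "OS")) {
      k <- k + 1L
      eye_seed <- derive_seed(cfg$seed, k)
      b_eye <- with_seed(eye_seed, stats::rnorm(1, 0, cfg$eye_sd))
      base_i <- img_cfg$base_density + subj$b_subject[i] + b_eye
      clipped <- base_i < 0.01 || base_i > 0.95
      base_i <- min(0.95, max(0.01, base_i))
      delta <- subject_deficit(cfg, subj$diagnosis[i], subj$age[i])
      mult <- img_cfg$regional_multipliers
      mult["temporal"] <- (1 - delta)
      row_cfg <- vessel_sim_config(
        n_seeds = img_cfg$n_seeds, branch_prob = img_cfg$branch_prob,
        step_px = img_cfg$step_px, max_steps = img_cfg$max_steps,
        base_density = base_i, regional_multipliers = mult,
        faz_area_mm2 = img_cfg$faz_area_mm2,
        faz_irregularity = img_cfg$faz_irregularity,
        noise_sd = img_cfg$noise_sd,
        vessel_intensity = img_cfg$vessel_intensity,
        background_intensity = img_cfg$background_intensity,
        seed = derive_seed(eye_seed, 1L))
      sm <- spec_macula; sm$laterality <- eye
      so <- spec_onh; so$laterality <- eye
      mac <- generate_angiogram(sm, row_cfg)
      onh_cfg <- row_cfg; onh_cfg$seed <- derive_seed(eye_seed, 2L)
      onh <- generate_angiogram(so, onh_cfg)
      if (clipped)
        warning(sprintf("eye %s/%s: planted base density clipped into range",
                        subj$subject[i], eye))
      rows[[k]] <- cbind(subj[i, c("subject", "diagnosis", "age", "sex",
                                   "axial_length", "ssi")],
                         data.frame(eye = eye, eye_seed = eye_seed,
                                    planted_base = base_i,
                                    planted_deficit = delta,
                                    stringsAsFactors = FALSE))
      eyes[[k]] <- list(subject = subj$subject[i], eye = eye,
                        macula = mac, onh = onh)
    }
  }
  cohort <- do.call(rbind, rows)
  rownames(cohort) <- NULL
  list(cohort = cohort, eyes = eyes)
}
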