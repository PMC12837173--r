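#' Build an end-to-end run configuration
#'
#' Collects every knob of a full synthetic-cohort run: image geometry,
#' per-site threshold parameters (macula routed to Phansalkar and ONH to
#' Niblack by default), the cohort simulation settings, grid-centering
#' jitter, statistics options and the global seed. Every stochastic stage
#' derives its own seed deterministically from `seed`, and the configuration
#' round-trips losslessly through its YAML file form.
#'
#' @param seed global integer seed.
#' @param n_control,n_ssd cohort group sizes.
#' @param temporal_deficit planted fractional temporal density deficit.
#' @param deficit_old optional deficit for SSD subjects aged > 30.
#' @param img_px image side in pixels for both sites.
#' @param base_density,noise_sd,faz_area_mm2,faz_irregularity image generator
#'   settings (see [vessel_sim_config()]).
#' @param n_seeds,branch_prob,max_steps walker settings.
#' @param center_jitter_px SD of the random grid-centering offset emulating
#'   manual centering (0 disables).
#' @param ddf mixed-model degrees-of-freedom method.
#' @param extra named list merged into the config (reserved keys win).
#' @return An object of class `octa_run_config` (a named list).
#' @export
run_config <- function(seed = 1L, n_control = 8L, n_ssd = 8L,
                       temporal_deficit = 0.35, deficit_old = NULL,
                       img_px = 192L, base_density = 0.12, noise_sd = 0.1,
                       faz_area_mm2 = 0.3, faz_irregularity = 0.3,
                       n_seeds = 40L, branch_prob = 0.05, max_steps = 1500L,
                       center_jitter_px = 0, ddf = "satterthwaite",
                       extra = list()) {
  cfg <- list(seed = as.integer(seed), n_control = as.integer(n_control),
              n_ssd = as.integer(n_ssd),
              temporal_deficit = temporal_deficit,
              deficit_old = deficit_old,
              img_px = as.integer(img_px), base_density = base_density,
              noise_sd = noise_sd, faz_area_mm2 = faz_area_mm2,
              faz_irregularity = faz_irregularity,
              n_seeds = as.integer(n_seeds), branch_prob = branch_prob,
              max_steps = as.integer(max_steps),
              center_jitter_px = center_jitter_px, ddf = ddf,
              macula_method = "phansalkar", onh_method = "niblack",
              window_px = 15L)
  for (nm in setdiff(names(extra), names(cfg))) cfg[[nm]] <- extra[[nm]]
  structure(cfg, class = "octa_run_config")
}

#' Read / write a run configuration as YAML
#' @param cfg an [run_config()] object.
#' @param path file path.
#' @export
write_run_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  do.call(run_config, c(cfg[intersect(names(cfg), names(formals(run_config)))],
                        list(extra = cfg[setdiff(names(cfg), names(formals(run_config)))])))
}

pipeline_log <- function(lines, path) {
  stamp <- format(Sys.time(), "%Y-%m-%dT%H:%M:%S")
  cat(paste0(stamp, " ", lines, "\n"), file = path, append = TRUE, sep = "")
}

#' Run the full synthetic-cohort analysis pipeline
#'
#' simulate -> binarize -> skeletonize -> regional density / FAZ -> analyze.
#' Stage outputs are files under `out_dir` so each stage is independently
#' inspectable: per-eye PNGs (angiogram, vessel mask, skeleton), a
#' long-format density CSV (one row per subject x eye x region), a FAZ
#' metrics CSV, demographics and model/contrast tables per site, and a
#' manifest listing every artifact with an MD5 of the config. Identical
#' configurations produce byte-identical CSV outputs.
#'
#' @param cfg an [run_config()].
#' @param out_dir output directory (created if needed).
#' @param write_images write per-eye PNGs (default TRUE; the CSVs and tables
#'   are always written).
#' @return Invisibly, a list with the cohort table, density records, FAZ
#'   table and the statistics results per site.
#' @export
run_pipeline <- function(cfg, out_dir, write_images = TRUE) {
  stopifnot(inherits(cfg, "octa_run_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  img_dir <- file.path(out_dir, "images")
  if (write_images) dir.create(img_dir, showWarnings = FALSE)
  logf <- file.path(out_dir, "run.log")
  cat(NULL, file = logf)
  pipeline_log(sprintf("run start (seed %d)", cfg$seed), logf)

  cfgfile <- file.path(out_dir, "config.yaml")
  write_run_config(cfg, cfgfile)
  cfg_hash <- unname(tools::md5sum(cfgfile))

  spec_mac <- image_spec(cfg$img_px, cfg$img_px, 3, "macula", "OD")
  spec_onh <- image_spec(cfg$img_px, cfg$img_px, 6, "onh", "OD")
  ccfg <- cohort_sim_config(n_control = cfg$n_control, n_ssd = cfg$n_ssd,
                            temporal_deficit = cfg$temporal_deficit,
                            deficit_old = cfg$deficit_old,
                            seed = derive_seed(cfg$seed, 1L))
  icfg <- vessel_sim_config(n_seeds = cfg$n_seeds, branch_prob = cfg$branch_prob,
                            max_steps = cfg$max_steps,
                            base_density = cfg$base_density,
                            faz_area_mm2 = cfg$faz_area_mm2,
                            faz_irregularity = cfg$faz_irregularity,
                            noise_sd = cfg$noise_sd)
  sim <- generate_cohort(spec_mac, spec_onh, ccfg, icfg)
  pipeline_log(sprintf("simulated %d eyes", length(sim$eyes)), logf)

  pm_mac <- threshold_params(cfg$macula_method, window_px = cfg$window_px)
  pm_onh <- threshold_params(cfg$onh_method, window_px = cfg$window_px)

  density_rows <- list(); faz_rows <- list()
  artifacts <- character(0)
  for (k in seq_along(sim$eyes)) {
    e <- sim$eyes[[k]]
    meta <- sim$cohort[k, c("subject", "eye", "diagnosis", "age", "sex")]
    jseed <- derive_seed(cfg$seed, 1000L + k)
    for (site in c("macula", "onh")) {
      stage_id <- sprintf("%s_%s_%s", e$subject, e$eye, site)
      res <- tryCatch({
        img <- e[[site]]$image
        pm <- if (site == "macula") pm_mac else pm_onh
        bm <- binarize(img, pm)
        sk <- skeletonize(bm)
        offset <- if (cfg$center_jitter_px > 0)
          with_seed(jseed, stats::rnorm(2, 0, cfg$center_jitter_px)) else c(0, 0)
        grid <- center_grid(img, offset_px = offset)
        meta_s <- cbind(meta, site = site)
        dens <- extract_region_densities(sk, grid, meta = meta_s)
        if (write_images) {
          fa <- file.path(img_dir, paste0(stage_id, ".png"))
          fm <- file.path(img_dir, paste0(stage_id, "_mask.png"))
          fs <- file.path(img_dir, paste0(stage_id, "_skel.png"))
          write_angiogram_png(img, fa); write_mask_png(bm$mask, fm)
          write_mask_png(sk$skeleton, fs)
          artifacts <- c(artifacts, fa, fm, fs)
        }
        if (site == "macula") {
          fz <- tryCatch({
            out <- auto_faz_outline(bm$mask, img$spec)
            m <- faz_metrics(out)
            cbind(meta, area_mm2 = m$area_mm2, perimeter_mm = m$perimeter_mm,
                  acircularity = m$acircularity)
          }, octaquant_error = function(cond) {
            pipeline_log(sprintf("%s: FAZ excluded (%s)", stage_id,
                                 class(cond)[1]), logf)
            NULL
          })
          if (!is.null(fz)) faz_rows[[length(faz_rows) + 1L]] <- fz
        }
        dens
      }, octaquant_error = function(cond) {
        stop_octa("stage-failed", "stage %s failed on %s: %s",
                  site, stage_id, conditionMessage(cond))
      })
      density_rows[[length(density_rows) + 1L]] <- res
    }
  }
  density <- do.call(rbind, density_rows)
  faz <- if (length(faz_rows)) do.call(rbind, faz_rows) else NULL

  f_cohort <- file.path(out_dir, "cohort.csv")
  f_density <- file.path(out_dir, "density.csv")
  utils::write.csv(sim$cohort, f_cohort, row.names = FALSE)
  utils::write.csv(density, f_density, row.names = FALSE)
  files <- c(f_cohort, f_density)
  if (!is.null(faz)) {
    f_faz <- file.path(out_dir, "faz.csv")
    utils::write.csv(faz, f_faz, row.names = FALSE)
    files <- c(files, f_faz)
  }

  ## ---- statistics stage ----
  stats_out <- list()
  demo <- demographics_table(sim$cohort)
  f_demo <- file.path(out_dir, "demographics.csv")
  utils::write.csv(demo, f_demo, row.names = FALSE)
  files <- c(files, f_demo)
  stats_out$demographics <- demo

  for (site in c("onh", "macula")) {
    recs <- density[density$site == site & density$region != "mean", ]
    ana <- analyze_site(recs, site, ddf = cfg$ddf)
    pipeline_log(sprintf("%s: ring_p=%s collapsed=%s singular=%s", site,
                         format(ana$ring_p), ana$collapsed, ana$singular), logf)
    f_int <- file.path(out_dir, sprintf("model_%s_interactions.csv", site))
    f_con <- file.path(out_dir, sprintf("model_%s_contrasts.csv", site))
    utils::write.csv(ana$interactions, f_int, row.names = FALSE)
    utils::write.csv(ana$contrasts, f_con, row.names = FALSE)
    files <- c(files, f_int, f_con)
    stats_out[[site]] <- ana
  }
  if (!is.null(faz) && all(table(factor(faz$diagnosis,
                                        levels = c("control", "ssd"))) >= 3L)) {
    fz <- faz_group_regression(faz)
    f_fz <- file.path(out_dir, "faz_regression.csv")
    utils::write.csv(fz, f_fz, row.names = FALSE)
    files <- c(files, f_fz)
    stats_out$faz_regression <- fz
  }

  manifest <- data.frame(artifact = basename(c(files, artifacts)),
                         config_md5 = cfg_hash, stringsAsFactors = FALSE)
  manifest <- manifest[order(manifest$artifact), ]
  utils::write.csv(manifest, file.path(out_dir, "manifest.csv"), row.names = FALSE)
  pipeline_log("run complete", logf)
  invisible(list(cohort = sim$cohort, density = density, faz = faz,
                 stats = stats_out, config_md5 = cfg_hash))
}
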