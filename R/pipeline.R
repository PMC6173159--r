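## Configuration-driven orchestration: traits -> repeatability -> PO
## regression -> PCA -> clustering -> survival, with seeded stages and a
## hashed output manifest. Stages are ordinary exported functions; the
## pipeline is a reproducibility convenience, not a separate engine.

#' Pipeline configuration
#'
#' Builds (and validates) the configuration list driving [run_traits()] and
#' [run_full()]. Either pass a YAML file path or a list of overrides; all
#' unset values take the documented defaults. Every stage seed is derived
#' from the single global `seed`, so a config reruns to identical outputs.
#'
#' @param config Path to a YAML file, or a named list of overrides, or NULL
#'   for all defaults.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(config = NULL) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (is.null(config)) config <- list()
  def <- list(
    seed = 20120101,
    output_dir = "spotmetrics-output",
    images = NULL,                      # optional: metadata CSV with
                                        # image_path,x0,y0,x1,y1,animal_id
    scene = list(n_animals = 24, rect_width_px = 320, rect_height_px = 240,
                 n_spots = 14, mean_radius_gu = 0.06, radius_cv = 0.3,
                 aspect_ratio_mean = 1.7, boundary_roughness = 0.2,
                 noise_sd = 6, illumination_gradient = 0.08),
    extraction = list(saturated_fraction = 0.007, min_area_gu2 = 1e-5),
    heritability = list(n_pairs = 31, po_slope = 0.26, trait_var = 1,
                        n_individuals = 30, n_reps = 3, R_true = 0.85,
                        n_boot = 200),
    clustering = list(k_max = 6, B = 30, force_k = NULL),
    cmr = list(n_released_per_occasion = 20, s_intercept = 1.735,
               s_age_slope = 0.2, gamma_prime = 0.1, gamma_dprime = 0.1,
               p = 0.6, c = 0.6))
  merge <- function(d, o) {
    for (nm in names(o))
      d[[nm]] <- if (is.list(o[[nm]]) && is.list(d[[nm]]))
        merge(d[[nm]], o[[nm]]) else o[[nm]]
    d
  }
  structure(merge(def, config), class = "pipeline_config")
}

.config_hash <- function(config) {
  cfg <- unclass(config)
  cfg$output_dir <- NULL   # where outputs land must not change what they are
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(deparse(cfg), tmp)
  unname(tools::md5sum(tmp))
}

.stage_header <- function(config, stage) {
  base::c(sprintf("spotmetrics stage: %s", stage),
          sprintf("seed: %d", config$seed),
          sprintf("config_hash: %s", .config_hash(config)))
}

#' Measure spot traits for a batch of photographs
#'
#' With an `images` metadata CSV (`image_path,x0,y0,x1,y1,animal_id`) the
#' listed photographs are processed; otherwise synthetic coat scenes are
#' generated per the `scene` config block. Each image runs through the
#' extraction chain and trait measurement; animals with no measurable spots
#' are excluded and logged. Writes `traits.csv` (one row per animal) and
#' `traits_summary.csv` (mean, SD, CV per trait) into `output_dir`.
#'
#' @param config A [pipeline_config()] (or list/path accepted by it).
#' @return The per-animal trait data frame, invisibly.
#' @export
run_traits <- function(config = NULL) {
  config <- pipeline_config(config)
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  rows <- list(); excluded <- character()
  if (!is.null(config$images)) {
    meta <- utils::read.csv(config$images)
    for (i in seq_len(nrow(meta))) {
      img <- tryCatch(read_coat_image(meta$image_path[i]), error = function(e) {
        message("skipping unreadable image ", meta$image_path[i], ": ",
                conditionMessage(e)); NULL
      })
      if (is.null(img)) { excluded <- base::c(excluded, meta$animal_id[i]); next }
      rect <- analysis_rect(meta$x0[i], meta$y0[i], meta$x1[i], meta$y1[i])
      ex <- extract_spots(img, rect, config$extraction$saturated_fraction,
                          config$extraction$min_area_gu2)
      spots <- measure_spots(ex$spot_map)
      if (nrow(spots) == 0L) { excluded <- base::c(excluded, meta$animal_id[i]); next }
      prof <- aggregate_profile(spots, ex$color_rect)
      prof$animal_id <- meta$animal_id[i]
      rows[[length(rows) + 1L]] <- prof
    }
  } else {
    sc <- config$scene
    for (i in seq_len(sc$n_animals)) {
      params <- coat_scene_params(
        rect_width_px = sc$rect_width_px, rect_height_px = sc$rect_height_px,
        n_spots = sc$n_spots, mean_radius_gu = sc$mean_radius_gu,
        radius_cv = sc$radius_cv, aspect_ratio_mean = sc$aspect_ratio_mean,
        boundary_roughness = sc$boundary_roughness, noise_sd = sc$noise_sd,
        illumination_gradient = sc$illumination_gradient,
        seed = derive_seed(config$seed, paste0("scene", i)))
      scene <- gen_coat_image(params)
      ex <- extract_spots(scene$image, scene$rect,
                          config$extraction$saturated_fraction,
                          config$extraction$min_area_gu2)
      spots <- measure_spots(ex$spot_map)
      if (nrow(spots) == 0L) {
        excluded <- base::c(excluded, sprintf("animal%03d", i)); next
      }
      prof <- aggregate_profile(spots, ex$color_rect)
      prof$animal_id <- sprintf("animal%03d", i)
      rows[[length(rows) + 1L]] <- prof
    }
  }
  if (!length(rows)) stop("no animal yielded measurable spots")
  traits <- do.call(rbind, rows)
  traits <- traits[, base::c("animal_id", trait_names(), "mode_shade")]
  write_header_csv(traits, file.path(config$output_dir, "traits.csv"),
                   .stage_header(config, "traits"))
  num <- traits[, trait_names()]
  summ <- data.frame(trait = trait_names(),
                     mean = vapply(num, mean, numeric(1)),
                     sd = vapply(num, stats::sd, numeric(1)))
  summ$cv <- summ$sd / abs(summ$mean)
  write_header_csv(summ, file.path(config$output_dir, "traits_summary.csv"),
                   .stage_header(config, "traits_summary"))
  if (length(excluded))
    message("excluded (no measurable spots): ", paste(excluded, collapse = ", "))
  invisible(traits)
}

#' Run the full analysis pipeline
#'
#' Executes, in order: trait measurement ([run_traits()]), measurement
#' repeatability, mother-offspring regression with heritability, PCA of the
#' z-scored traits, k-means phenotyping with gap-statistic group selection,
#' and robust-design survival modelling (null and age-trend models) on
#' simulated encounter histories. Every stage writes a CSV into
#' `output_dir`; a final `manifest.csv` lists each output with its MD5
#' hash, so reruns can be verified byte-for-byte.
#'
#' @param config A [pipeline_config()] (or list/path accepted by it).
#' @return The manifest data frame, invisibly.
#' @export
run_full <- function(config = NULL) {
  config <- pipeline_config(config)
  out <- config$output_dir
  stage <- "traits"
  manifest_files <- character()
  tryCatch({
    traits <- run_traits(config)
    manifest_files <- base::c(manifest_files, "traits.csv", "traits_summary.csv")

    stage <- "repeatability"
    h <- config$heritability
    rep_tab <- gen_repeat_measurements(h$n_individuals, h$n_reps, h$R_true,
                                       seed = derive_seed(config$seed, "repeat"))
    rp <- repeatability(rep_tab, n_boot = h$n_boot,
                        seed = derive_seed(config$seed, "repboot"))
    write_header_csv(data.frame(R = rp$R, R_se = rp$R_se, p_value = rp$p_value),
                     file.path(out, "repeatability.csv"),
                     .stage_header(config, stage))
    manifest_files <- base::c(manifest_files, "repeatability.csv")

    stage <- "heritability"
    pairs <- gen_po_pairs(h$n_pairs, trait_var = h$trait_var,
                          po_slope = h$po_slope,
                          seed = derive_seed(config$seed, "pairs"))
    po <- po_regression(pairs)
    diag <- regression_diagnostics(po)
    write_header_csv(
      data.frame(slope = po$slope, slope_se = po$slope_se,
                 heritability = po$heritability,
                 heritability_se = po$heritability_se,
                 F_stat = po$F_stat, p_value = po$p_value,
                 bonferroni_alpha = as.numeric(bonferroni_alpha(0.05, 11)),
                 normality_p = diag$normality_p,
                 heteroscedasticity_p = diag$heteroscedasticity_p),
      file.path(out, "heritability.csv"), .stage_header(config, stage))
    manifest_files <- base::c(manifest_files, "heritability.csv")

    stage <- "pca"
    X <- standardize_traits(traits[, trait_names()])
    pca <- trait_pca(X)
    write_header_csv(
      data.frame(dimension = seq_along(pca$eigenvalues),
                 eigenvalue = pca$eigenvalues,
                 percent_variance = pca$percent_variance),
      file.path(out, "pca_summary.csv"), .stage_header(config, stage))
    manifest_files <- base::c(manifest_files, "pca_summary.csv")

    stage <- "clustering"
    cl <- config$clustering
    gap <- gap_statistic(X, k_max = min(cl$k_max, nrow(X) - 1L), B = cl$B,
                         seed = derive_seed(config$seed, "gap"))
    k_use <- if (!is.null(cl$force_k)) cl$force_k else max(gap$chosen_k, 1L)
    km <- kmeans_fit(X, k_use, seed = derive_seed(config$seed, "kmeans"))
    write_header_csv(gap$curve, file.path(out, "gap_curve.csv"),
                     .stage_header(config, stage))
    write_header_csv(data.frame(animal_id = traits$animal_id,
                                group = km$assignment),
                     file.path(out, "phenotype_groups.csv"),
                     .stage_header(config, stage))
    manifest_files <- base::c(manifest_files, "gap_curve.csv",
                              "phenotype_groups.csv")

    stage <- "survival"
    cm <- config$cmr
    des <- cmr_sim_design(schedule = giraffe_schedule(),
                          n_released_per_occasion = cm$n_released_per_occasion,
                          s_intercept = cm$s_intercept,
                          s_age_slope = cm$s_age_slope,
                          gamma_prime = cm$gamma_prime,
                          gamma_dprime = cm$gamma_dprime,
                          p_per_occasion = cm$p, c_per_occasion = cm$c,
                          seed = derive_seed(config$seed, "cmr"))
    eh <- gen_encounter_histories(des)
    write_inp(eh, file.path(out, "histories.inp"))
    fits <- list(fit_rd(eh, S = ~1, n_restarts = 1, model_name = "S(.)"),
                 fit_rd(eh, S = ~A, n_restarts = 1, model_name = "S(A)"))
    write_header_csv(model_table(fits), file.path(out, "survival_models.csv"),
                     .stage_header(config, stage))
    avg <- model_average(fits, "S", newdata = data.frame(A = 0:8))
    avg$age_seasons <- 0:8
    write_header_csv(avg, file.path(out, "survival_estimates.csv"),
                     .stage_header(config, stage))
    manifest_files <- base::c(manifest_files, "histories.inp",
                              "survival_models.csv", "survival_estimates.csv")
  }, error = function(e) {
    stop(sprintf("pipeline stage '%s' failed: %s", stage,
                 conditionMessage(e)), call. = FALSE)
  })
  paths <- file.path(out, manifest_files)
  manifest <- data.frame(file = manifest_files,
                         md5 = unname(tools::md5sum(paths)))
  utils::write.csv(manifest, file.path(out, "manifest.csv"), row.names = FALSE)
  invisible(manifest)
}
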