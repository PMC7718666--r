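#' Pipeline configuration
#'
#' Collects every tunable of the image post-processing and statistics
#' stages, with defaults reproducing the standard analysis settings:
#' a fovea-centered annulus of inner radius 0.5 mm and outer radius
#' 1.25 mm, alpha = 0.05 Bonferroni-split over a family of 2 outcomes, and
#' a 0.415-specificity ROC operating point.
#'
#' @param inner_radius_mm,outer_radius_mm Annulus radii (mm).
#' @param binarize_window_px,binarize_offset,binarize_min_object_px
#'   Binarization parameters (see [binarize()]).
#' @param large_vessel_scales_px,large_vessel_threshold,large_vessel_width_floor_px
#'   Large-vessel detection parameters (see [detect_large_vessels()]).
#' @param fd_min_box_px,fd_max_box_px Box-counting ladder bounds; `NULL` for
#'   the resolution-dependent default.
#' @param capillary_only_vd If `TRUE`, the large-vessel mask is subtracted
#'   from the binarized plexus before skeletonization (sensitivity
#'   analysis); the default keeps the full plexus.
#' @param covariates Adjustment covariates for the regression stage.
#' @param alpha Family-wise significance level.
#' @param k_outcomes Outcome family size for the Bonferroni split.
#' @param specificity ROC operating point for reported sensitivities.
#' @param n_per_group Cohort sizes used by [run_simulate()].
#' @param seed Master seed for simulation.
#' @return A list of class `octa_config`.
#' @export
octa_config <- function(inner_radius_mm = 0.5, outer_radius_mm = 1.25,
                        binarize_window_px = 11L, binarize_offset = "auto",
                        binarize_min_object_px = 5L,
                        large_vessel_scales_px = c(2, 3, 4),
                        large_vessel_threshold = 0.25,
                        large_vessel_width_floor_px = 3,
                        fd_min_box_px = 2L, fd_max_box_px = NULL,
                        capillary_only_vd = FALSE,
                        covariates = c("age", "gender", "race", "diabetes",
                                       "sbp", "dbp", "signal_strength"),
                        alpha = 0.05, k_outcomes = 2L,
                        specificity = 0.415,
                        n_per_group = c(AD = 24L, MCI = 37L, control = 29L),
                        seed = 1L) {
  if (inner_radius_mm <= 0 || outer_radius_mm <= inner_radius_mm) {
    stop("annulus radii must satisfy 0 < inner < outer", call. = FALSE)
  }
  stop_if_not_scalar_number(alpha, "alpha", lower = 1e-12, upper = 1 - 1e-12)
  stop_if_not_scalar_number(specificity, "specificity", lower = 0, upper = 1)
  structure(
    list(inner_radius_mm = inner_radius_mm, outer_radius_mm = outer_radius_mm,
         binarize_window_px = binarize_window_px,
         binarize_offset = binarize_offset,
         binarize_min_object_px = binarize_min_object_px,
         large_vessel_scales_px = large_vessel_scales_px,
         large_vessel_threshold = large_vessel_threshold,
         large_vessel_width_floor_px = large_vessel_width_floor_px,
         fd_min_box_px = fd_min_box_px, fd_max_box_px = fd_max_box_px,
         capillary_only_vd = isTRUE(capillary_only_vd),
         covariates = covariates, alpha = alpha,
         k_outcomes = as.integer(k_outcomes),
         specificity = specificity,
         n_per_group = n_per_group, seed = as.integer(seed)),
    class = "octa_config"
  )
}

#' Load a pipeline configuration from YAML or JSON
#'
#' Fields absent from the file keep their [octa_config()] defaults.
#'
#' @param path `.yaml`/`.yml` or `.json` file.
#' @return An `octa_config`.
#' @export
load_config <- function(path) {
  ext <- tolower(tools::file_ext(path))
  vals <- if (ext %in% c("yaml", "yml")) {
    yaml::read_yaml(path)
  } else if (ext == "json") {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    stop("unsupported config extension: ", ext, call. = FALSE)
  }
  vals <- vals[names(vals) %in% names(formals(octa_config))]
  if (!is.null(vals$n_per_group)) vals$n_per_group <- unlist(vals$n_per_group)
  do.call(octa_config, vals)
}

#' MD5 hash of a pipeline configuration
#'
#' Used to stamp every manifest and results file so outputs can be traced
#' to the exact configuration that produced them.
#'
#' @param config An [octa_config()].
#' @return A 32-character hex string.
#' @export
config_hash <- function(config) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(unclass(config), tmp, auto_unbox = TRUE, digits = NA,
                       null = "null")
  unname(tools::md5sum(tmp))
}

#' Simulate a fixture directory of angiograms and a cohort table
#'
#' Writes, for each synthetic participant, SCP and DCP angiogram images
#' (16-bit TIFF) with JSON sidecars and FAZ polygon CSVs, plus a cohort CSV
#' and a manifest echoing the configuration, its hash, and per-participant
#' seeds. The per-participant SCP/DCP capillary densities and FAZ areas are
#' taken from that participant's cohort metric values, so image-derived
#' metrics track the cohort's statistical structure.
#'
#' @param config An [octa_config()].
#' @param out_dir Output directory (created if needed).
#' @param cohort_params A [cohort_params()]; group sizes and seed default to
#'   the config's.
#' @return Invisibly, the manifest list.
#' @export
run_simulate <- function(config, out_dir,
                         cohort_params = NULL) {
  stopifnot(inherits(config, "octa_config"))
  if (is.null(cohort_params)) {
    cohort_params <- cohort_params(n_per_group = config$n_per_group,
                                   seed = config$seed)
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) stop("cannot create output directory", call. = FALSE)
  gen <- generate_cohort(cohort_params)
  cohort <- gen$cohort
  files <- list()
  for (i in seq_len(nrow(cohort))) {
    pid <- cohort$participant_id[i]
    for (plexus in c("SCP", "DCP")) {
      vd <- if (plexus == "SCP") cohort$vd_scp[i] else cohort$vd_dcp[i]
      fazmm2 <- if (plexus == "SCP") cohort$faz_area_scp[i] else cohort$faz_area_dcp[i]
      sp <- angio_scene_params(
        plexus = plexus,
        capillary_density = max(vd, 1),
        faz_area_mm2 = max(fazmm2, 0.05),
        seed = config$seed * 10000L + i * 10L + (plexus == "DCP")
      )
      truth <- generate_vessel_network(sp)
      truth$image$participant_id <- pid
      truth$image$eye <- cohort$eye[i]
      stem <- file.path(out_dir, sprintf("%s_%s", pid, tolower(plexus)))
      write_angiogram(truth$image, paste0(stem, ".tiff"))
      write_faz_polygon(truth$faz_polygon, paste0(stem, "_faz.csv"))
      jsonlite::write_json(
        list(skeleton_length_mm = truth$skeleton_length_mm,
             faz_area_mm2 = faz_area(truth$faz_polygon),
             seed = sp$seed),
        paste0(stem, "_truth.json"), auto_unbox = TRUE, digits = NA)
      files[[length(files) + 1L]] <- basename(paste0(stem, ".tiff"))
    }
  }
  utils::write.csv(cohort, file.path(out_dir, "cohort.csv"), row.names = FALSE)
  manifest <- list(config = unclass(config),
                   config_hash = config_hash(config),
                   n_participants = nrow(cohort),
                   images = unlist(files))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}

#' Compute metric records for every participant in a fixture directory
#'
#' Reads each participant's SCP/DCP images and FAZ polygons, runs
#' [compute_metric_record()], and writes the metric table. A failing image
#' is logged (as a warning) and skipped; remaining rows are still produced.
#'
#' @param config An [octa_config()].
#' @param fixture_dir Directory written by [run_simulate()] (or populated
#'   with the same layout from real exports).
#' @param out_csv Output metrics CSV path.
#' @return The metric data frame, invisibly, with attribute `n_failed`.
#' @export
run_metrics <- function(config, fixture_dir, out_csv) {
  stopifnot(inherits(config, "octa_config"))
  scp_images <- sort(list.files(fixture_dir, pattern = "_scp\\.(tiff?|png)$",
                                full.names = TRUE))
  if (!length(scp_images)) stop("no SCP images found in ", fixture_dir, call. = FALSE)
  rows <- list()
  n_failed <- 0L
  for (scp_path in scp_images) {
    stem <- sub("_scp\\.[^.]+$", "", scp_path)
    res <- tryCatch({
      scp <- read_angiogram(scp_path, sub("\\.[^.]+$", ".json", scp_path))
      scp_faz <- read_faz_polygon(paste0(stem, "_scp_faz.csv"))
      dcp_path <- sub("_scp\\.", "_dcp.", scp_path)
      dcp <- dcp_faz <- NULL
      if (file.exists(dcp_path)) {
        dcp <- read_angiogram(dcp_path, sub("\\.[^.]+$", ".json", dcp_path))
        dcp_faz <- read_faz_polygon(paste0(stem, "_dcp_faz.csv"))
      }
      compute_metric_record(scp, dcp, scp_faz, dcp_faz, config = config)
    }, error = function(e) {
      warning(sprintf("skipping %s: %s", basename(scp_path), conditionMessage(e)),
              call. = FALSE)
      NULL
    })
    if (is.null(res)) n_failed <- n_failed + 1L else rows[[length(rows) + 1L]] <- res
  }
  metrics <- do.call(rbind, rows)
  write_metrics(metrics, out_csv)
  attr(metrics, "n_failed") <- n_failed
  invisible(metrics)
}

#' Run the cohort statistics stage
#'
#' Joins the metric table to the cohort covariates by participant id and
#' produces: the baseline characteristics table (ANOVA / chi-square), one
#' covariate-adjusted model per OCTA metric with the Bonferroni threshold
#' applied within the primary (VD, FD) and secondary (PD, FAZ) outcome
#' families, ROC results (AUC, sensitivity at the configured specificity,
#' and paired AUC comparisons among the three best markers) for
#' discriminating AD/MCI from controls, and a post hoc power report from
#' the observed control/AD summaries.
#'
#' @param config An [octa_config()].
#' @param metrics Metric table (data frame or CSV path).
#' @param cohort Cohort table (data frame or CSV path).
#' @param out_dir Optional directory; when given, results are written as
#'   `results.json` and a Table-2-style `adjusted_models.csv`.
#' @return A list of class `octa_stats_result`.
#' @export
run_stats <- function(config, metrics, cohort, out_dir = NULL) {
  stopifnot(inherits(config, "octa_config"))
  if (is.character(metrics)) metrics <- read_metrics(metrics)
  if (is.character(cohort)) {
    cohort <- utils::read.csv(cohort, colClasses = c(participant_id = "character"))
  }
  cohort_cols <- setdiff(names(cohort), setdiff(names(metrics), "participant_id"))
  joined <- merge(cohort[, cohort_cols], metrics, by = "participant_id")
  orphans <- c(setdiff(cohort$participant_id, metrics$participant_id),
               setdiff(metrics$participant_id, cohort$participant_id))
  if (length(orphans)) {
    stop("participant ids missing from one table: ",
         paste(sort(unique(orphans)), collapse = ", "), call. = FALSE)
  }
  missing_cov <- setdiff(config$covariates, names(joined))
  if (length(missing_cov)) {
    stop("missing covariate columns: ", paste(missing_cov, collapse = ", "),
         call. = FALSE)
  }
  joined$group <- factor(joined$group, levels = cohort_groups)

  baseline_vars <- intersect(c("age", "gender", "race", "diabetes", "sbp",
                               "dbp", "mmse", "signal_strength"), names(joined))
  baseline <- lapply(baseline_vars, function(v) {
    x <- joined[[v]]
    if (is.character(x) || length(unique(x)) <= 2L) x <- factor(x)
    baseline_comparison(data.frame(group = joined$group, v = x), "v")
  })
  names(baseline) <- baseline_vars

  families <- list(primary = c("vd_scp", "vd_dcp", "fd_scp", "fd_dcp"),
                   secondary = c("pd_large_scp", "faz_area_scp", "faz_area_dcp"))
  thr <- bonferroni_threshold(config$alpha, config$k_outcomes)
  models <- list()
  for (fam in names(families)) {
    for (metric in intersect(families[[fam]], names(joined))) {
      fit <- fit_adjusted_model(joined, metric, covariates = config$covariates)
      fit$family <- fam
      fit$significance_threshold <- thr
      models[[metric]] <- fit
    }
  }

  impaired <- joined$group %in% c("AD", "MCI")
  roc_markers <- intersect(c("vd_scp", "vd_dcp", "fd_scp", "fd_dcp"), names(joined))
  rocs <- lapply(roc_markers, function(m) {
    # density/complexity fall with impairment: score by the negated metric
    sc <- -joined[[m]]
    list(marker = m,
         auc = roc_auc(sc, impaired)$auc,
         sensitivity = sensitivity_at_specificity(sc, impaired,
                                                  config$specificity))
  })
  names(rocs) <- roc_markers
  aucs <- vapply(rocs, `[[`, numeric(1), "auc")
  top3 <- names(sort(aucs, decreasing = TRUE))[seq_len(min(3L, length(aucs)))]
  paired <- list()
  if (length(top3) >= 2L) {
    for (i in seq_len(length(top3) - 1L)) {
      for (j in (i + 1L):length(top3)) {
        key <- paste(top3[i], top3[j], sep = "_vs_")
        paired[[key]] <- compare_auc_paired(-joined[[top3[i]]],
                                            -joined[[top3[j]]], impaired)
      }
    }
  }

  ad <- joined$group == "AD"; ctrl <- joined$group == "control"
  power <- lapply(intersect(c("vd_scp", "vd_dcp"), names(joined)), function(m) {
    posthoc_power(mean(joined[[m]][ad]), stats::sd(joined[[m]][ad]), sum(ad),
                  mean(joined[[m]][ctrl]), stats::sd(joined[[m]][ctrl]), sum(ctrl),
                  alpha = config$alpha)
  })
  names(power) <- intersect(c("vd_scp", "vd_dcp"), names(joined))

  result <- structure(
    list(n = nrow(joined), baseline = baseline, models = models,
         bonferroni_threshold = thr, roc = rocs, paired_auc = paired,
         posthoc_power = power, config_hash = config_hash(config)),
    class = "octa_stats_result"
  )

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    tab <- do.call(rbind, lapply(names(models), function(m) {
      fit <- models[[m]]
      merged <- merge(fit$groups, rbind(
        data.frame(group = "control", estimate = NA_real_, ci_lower = NA_real_,
                   ci_upper = NA_real_, p_value = NA_real_), fit$betas),
        by = "group")
      cbind(metric = m, family = fit$family, merged)
    }))
    utils::write.csv(tab, file.path(out_dir, "adjusted_models.csv"),
                     row.names = FALSE)
    json <- list(
      n = result$n,
      bonferroni_threshold = thr,
      config_hash = result$config_hash,
      baseline = lapply(baseline, function(b) b[c("type", "statistic", "p_value")]),
      models = lapply(models, function(fit) {
        list(family = fit$family, groups = fit$groups, betas = fit$betas)
      }),
      roc = rocs,
      paired_auc = lapply(paired, function(p) p[c("auc_a", "auc_b", "difference",
                                                  "p_value")]),
      posthoc_power = power)
    jsonlite::write_json(json, file.path(out_dir, "results.json"),
                         auto_unbox = TRUE, digits = NA, na = "null",
                         dataframe = "rows")
  }
  result
}
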