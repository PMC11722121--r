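#' Default pipeline configuration
#'
#' Single list of every tunable parameter of the imaging and cohort
#' chains, with the package defaults. Decision flags mark the conventions
#' this package fixes where the underlying methods literature leaves a
#' choice open (PD/VD exclusion convention, averaging mode, diameter and
#' fractal estimators, tortuosity-2 normalisation, Strahler root policy,
#' LOOCV unit).
#'
#' @param ... overrides of the default entries.
#' @return named list (class `pipeline_config`).
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    averaging_mode = "mean",
    registration_stages = c("translation", "affine"),
    inhomogeneity_kernel_mm = 0.5,
    segmentation = list(scales = c(0.7, 1.1, 1.8), beta = 1.5,
                        low_frac = 0.25, min_size_px = 10L),
    prune_min_len_px = 5,
    strahler_roots = "auto",
    pd_exclusion = "both",
    tortuosity_min_len_px = 10,
    faz_closing_radius_px = 5,
    device_assumed_al_mm = 23.95,
    screen_alpha = 0.10,
    report_alpha = 0.05,
    forced_retests = c("faz_area_mm2", "tort_m1_capillaries",
                       "tort_m2_capillaries"),
    manual_exclusions = "prp",
    r_threshold = 0.9,
    loocv_unit = "eye",
    seed = 1L,
    decision_flags = c("pd_exclusion_both", "diameter_distance_transform",
                       "fractal_box_counting", "tortuosity2_vti",
                       "strahler_auto_root_spanning_tree",
                       "acircularity_perimeter_form", "feret_calipers",
                       "loocv_per_eye"))
  over <- list(...)
  cfg[names(over)] <- over
  structure(cfg, class = "pipeline_config")
}

#' Image chain for one eye: averaged image to metrics row
#'
#' Runs segmentation, skeletonization, graph construction with Strahler
#' classification, vascular metrics and FAZ metrics on an averaged en face
#' image, applying the magnification correction when an axial length is
#' supplied.
#'
#' @param image averaged [enface_image].
#' @param axial_length_mm eye's axial length for magnification correction
#'   (NULL skips correction).
#' @param av_mask optional user-supplied AV pixel mask (logical matrix)
#'   mirroring an interactive arteriole/venule delineation; default uses
#'   the Strahler band.
#' @param config a [pipeline_config].
#' @return named list of metrics (one eye).
#' @export
analyze_eye <- function(image, axial_length_mm = NULL, av_mask = NULL,
                        config = pipeline_config()) {
  sg <- config$segmentation
  mask <- binarize_vessels(image, scales = sg$scales, beta = sg$beta,
                           low_frac = sg$low_frac,
                           min_size_px = sg$min_size_px)
  skel <- skeletonize_mask(mask)
  graph <- build_graph(skel, mask)
  graph <- prune_spurs(graph, config$prune_min_len_px)
  graph <- classify_vessels(strahler_order(graph, config$strahler_roots))
  if (is.null(av_mask)) av_mask <- av_mask_from_graph(graph)
  vm <- vascular_metrics(mask, skel, graph, av_mask,
                         exclusion = config$pd_exclusion)
  fz <- tryCatch(segment_faz(mask,
                             closing_radius_px = config$faz_closing_radius_px),
                 error = function(e) NULL)
  fm <- if (!is.null(fz)) faz_metrics(fz) else NULL
  s <- if (!is.null(axial_length_mm))
    magnification_scale(axial_length_mm, config$device_assumed_al_mm) else 1
  if (!is.null(fm)) fm <- apply_magnification(fm, s)
  list(perfusion_density = vm$perfusion_density,
       vessel_density = vm$vessel_density,
       vessel_diameter_mm = vm$mean_diameter_mm * s,
       fractal_dimension = vm$fractal_dimension,
       tort_m1_av = vm$tortuosity_m1[["AV"]],
       tort_m1_capillaries = vm$tortuosity_m1[["capillary"]],
       tort_m2_av = vm$tortuosity_m2[["AV"]],
       tort_m2_capillaries = vm$tortuosity_m2[["capillary"]],
       faz_area_mm2 = if (!is.null(fm)) fm$area_mm2 else NA_real_,
       faz_perimeter_mm = if (!is.null(fm)) fm$perimeter_mm else NA_real_,
       faz_eccentricity = if (!is.null(fm)) fm$eccentricity else NA_real_,
       faz_axis_ratio = if (!is.null(fm)) fm$axis_ratio else NA_real_,
       faz_acircularity = if (!is.null(fm)) fm$acircularity_index else NA_real_,
       faz_min_distance_mm = if (!is.null(fm)) fm$min_feret_mm else NA_real_,
       faz_max_distance_mm = if (!is.null(fm)) fm$max_feret_mm else NA_real_,
       magnification_scale = s,
       decision_flags = paste(config$decision_flags, collapse = ";"))
}

#' Run the image pipeline over a batch of eyes
#'
#' Each element of `eyes` is a list with `id`, a [frame_stack] (`stack`)
#' or a pre-averaged [enface_image] (`image`), and optional
#' `axial_length_mm` and `av_mask`. Failures are isolated per eye and
#' logged; remaining eyes are still processed.
#'
#' @param eyes list of per-eye inputs.
#' @param config a [pipeline_config].
#' @param out_csv optional path for a per-eye metrics CSV.
#' @return list with `results` (data frame, one row per successful eye)
#'   and `failures` (named character vector of error messages).
#' @export
run_image_pipeline <- function(eyes, config = pipeline_config(),
                               out_csv = NULL) {
  rows <- list(); failures <- character(0)
  for (e in eyes) {
    res <- tryCatch({
      img <- if (!is.null(e$image)) e$image else
        preprocess_stack(e$stack, mode = config$averaging_mode,
                         stages = config$registration_stages,
                         kernel_mm = config$inhomogeneity_kernel_mm)$image
      m <- analyze_eye(img, e$axial_length_mm, e$av_mask, config)
      c(list(eye_id = e$id), m)
    }, error = function(err) err)
    if (inherits(res, "error")) {
      failures[e$id] <- conditionMessage(res)
      message(sprintf("eye %s failed: %s", e$id, conditionMessage(res)))
    } else {
      rows[[length(rows) + 1L]] <- as.data.frame(res,
                                                 stringsAsFactors = FALSE)
    }
  }
  results <- if (length(rows)) do.call(rbind, rows) else data.frame()
  if (!is.null(out_csv) && nrow(results))
    utils::write.csv(results, out_csv, row.names = FALSE)
  list(results = results, failures = failures)
}

#' Run the cohort statistics pipeline
#'
#' Executes the full inference chain on a per-eye cohort table:
#' random-forest imputation, univariate screening, mixed-model retesting
#' of flagged variables, correlation pruning of the numeric candidates,
#' maximal-model backward-AIC selection, and leave-one-out
#' cross-validated ROC of the final model.
#'
#' @param table cohort data frame (or path to a cohort CSV).
#' @param config a [pipeline_config].
#' @param out_json optional path for the results bundle as JSON.
#' @return list (class `cohort_results`): `screen`, `retests`,
#'   `pruned`, `selection`, `roc`, `config`.
#' @export
run_cohort_pipeline <- function(table, config = pipeline_config(),
                                out_json = NULL) {
  if (is.character(table)) table <- read_cohort_csv(table)
  if (!"pnp_present" %in% names(table)) stop("cohort lacks pnp_present")
  imp <- impute_rf(table, seed = config$seed)
  screen <- univariate_screen(imp, alpha = config$screen_alpha,
                              forced_retests = config$forced_retests)
  retest_vars <- screen$variable[screen$retest_requested]
  retests <- lapply(retest_vars, function(v) {
    out <- tryCatch({
      x <- imp[[v]]
      if (is.numeric(x)) {
        f <- fit_lmm(imp, v, "auto")
        data.frame(variable = v, model = "lmm", p_value = f$p_value,
                   singular = f$singular,
                   transformation = f$transformation)
      } else if (length(unique(x)) == 2L) {
        f <- fit_logistic_mixed(imp, v)
        data.frame(variable = v, model = "logistic_mixed",
                   p_value = f$p_value, singular = f$singular,
                   transformation = "none")
      } else {
        f <- fit_multinomial_mixed(imp, v)
        data.frame(variable = v, model = "multinomial_mixed",
                   p_value = f$p_value, singular = f$singular,
                   transformation = "none")
      }
    }, error = function(e)
      data.frame(variable = v, model = "failed", p_value = NA_real_,
                 singular = NA, transformation = conditionMessage(e)))
    out
  })
  retests <- if (length(retests)) do.call(rbind, retests) else
    data.frame(variable = character(0), model = character(0),
               p_value = numeric(0), singular = logical(0),
               transformation = character(0))
  candidates <- setdiff(retest_vars, c("patient_id", "pnp_present"))
  pruned <- correlation_prune(imp, candidates,
                              r_threshold = config$r_threshold,
                              manual_exclusions = config$manual_exclusions)
  selection <- backward_aic_select(imp, pruned$kept)
  roc <- if (length(selection$final_terms))
    loocv_auc(imp, selection$final_terms, unit = config$loocv_unit) else
      NULL
  out <- structure(list(screen = screen, retests = retests,
                        pruned = pruned, selection = selection,
                        roc = roc, config = config),
                   class = "cohort_results")
  if (!is.null(out_json)) {
    bundle <- list(
      screen = screen, retests = retests,
      pruned = pruned,
      final_terms = selection$final_terms,
      final_p = selection$final_p,
      elimination_trace = selection$trace,
      aic = selection$aic,
      loocv_auc = if (!is.null(roc)) roc$auc else NA,
      auc_ci = if (!is.null(roc)) roc$ci else NA,
      decision_flags = config$decision_flags)
    jsonlite::write_json(bundle, out_json, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE, force = TRUE)
  }
  out
}

#' @export
print.cohort_results <- function(x, ...) {
  cat("<cohort_results>\n")
  cat(sprintf(" %d variables screened, %d flagged for retest\n",
              nrow(x$screen), sum(x$screen$retest_requested)))
  cat(" final model:",
      if (length(x$selection$final_terms))
        paste(x$selection$final_terms, collapse = ", ") else "(intercept only)",
      "\n")
  if (!is.null(x$roc))
    cat(sprintf(" LOOCV AUC %.3f [%.3f, %.3f]\n", x$roc$auc,
                x$roc$ci[1], x$roc$ci[2]))
  invisible(x)
}

#' Write canonical small fixtures for tests and demos
#'
#' @param kind `"phantom"` (TIFF + ground-truth JSON), `"stack"`
#'   (multi-frame TIFFs + transform JSON) or `"cohort"` (48-row CSV).
#' @param dir output directory (created if needed).
#' @param seed integer seed.
#' @return character vector of written paths.
#' @export
make_fixtures <- function(kind = c("phantom", "stack", "cohort"),
                          dir = tempdir(), seed = 1L) {
  kind <- match.arg(kind)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  if (kind == "cohort") {
    path <- file.path(dir, sprintf("cohort_seed%d.csv", seed))
    write_cohort_csv(generate_cohort(cohort_spec(seed = seed)), path)
    return(path)
  }
  ph <- generate_vessel_phantom(phantom_spec(seed = seed,
                                             grid_size = c(160L, 160L),
                                             field_mm = 1.6))
  if (kind == "phantom") {
    tif <- file.path(dir, sprintf("phantom_seed%d.tiff", seed))
    js <- file.path(dir, sprintf("phantom_seed%d_truth.json", seed))
    write_enface_tiff(ph$image, tif)
    jsonlite::write_json(list(
      centerlines = ph$truth$centerlines, widths = ph$truth$widths,
      strahler_order = ph$truth$strahler_order,
      vessel_class = ph$truth$vessel_class,
      tortuosity_m1 = ph$truth$tortuosity_m1,
      faz_area_mm2 = ph$truth$faz_area_mm2,
      faz_eccentricity = ph$truth$faz_eccentricity,
      faz_perimeter_mm = ph$truth$faz_perimeter_mm),
      js, digits = NA)
    return(c(tif, js))
  }
  st <- generate_frame_stack(ph$image, n_frames = 4, motion_sd = 1.5,
                             noise_sd = 0.12, seed = seed)
  paths <- character(0)
  for (i in seq_along(st$frames)) {
    p <- file.path(dir, sprintf("stack_seed%d_f%02d.tiff", seed, i))
    write_enface_tiff(st$frames[[i]], p)
    paths <- c(paths, p)
  }
  js <- file.path(dir, sprintf("stack_seed%d_transforms.json", seed))
  jsonlite::write_json(attr(st, "true_transforms"), js, digits = NA)
  c(paths, js)
}
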