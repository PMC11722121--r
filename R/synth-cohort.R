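#' Default per-variable definitions for the synthetic cohort
#'
#' Group-wise means and SDs (numeric variables) and level counts
#' (categorical variables) for eyes with and without peripheral
#' non-perfusion, patterned on the published group summaries of a 48-eye
#' DME cohort. Counts are per group (PNP present n = 22, absent n = 26);
#' ordinal level counts are normalised to sampling probabilities.
#'
#' @return list with data frames `numeric` (variable, mean_pnp, sd_pnp,
#'   mean_nopnp, sd_nopnp, lower) and `categorical` (variable, levels,
#'   count_pnp, count_nopnp as comma-separated strings).
#' @export
cohort_variable_defs <- function() {
  num <- read.csv(text = "variable,mean_pnp,sd_pnp,mean_nopnp,sd_nopnp,lower
age,52,15,59,12,18
visual_acuity,69.1,16.1,76.5,11.3,0
dm_duration,22,7.5,18.8,9.4,0.5
hba1c,9.3,2.2,8.2,2.0,4
egfr,78.5,21.2,67.7,22.9,5
creatinine,83.2,42.3,117.3,110.5,20
ldl,2.8,0.8,2.6,1.2,0.3
hdl,1.3,0.4,1.2,0.4,0.3
axial_length,23.4,1.02,23.7,0.94,20
crt_1mm,403.1,129.8,375.4,120.4,150
crt_3mm,383.5,144,388.2,88.7,150
crt_6mm,358.2,230,366.4,126,150
tort_m1_arterioles,1.66,0.11,1.67,0.06,1
tort_m1_venules,1.66,0.11,1.67,0.06,1
tort_m1_capillaries,1.67,0.07,1.68,0.05,1
tort_m2_arterioles,1.06,0.12,1.06,0.11,0
tort_m2_venules,1.05,0.14,1.06,0.12,0
tort_m2_capillaries,1.04,0.15,1.025,0.07,0
perfusion_density,0.41,0.05,0.45,0.06,0.05
vessel_density,0.097,0.014,0.106,0.014,0.02
vessel_diameter_mm,0.024,0.002,0.023,0.002,0.005
fractal_dimension,1.88,0.01,1.89,0.01,1.2
faz_min_distance_mm,0.49,0.14,0.45,0.13,0.05
faz_max_distance_mm,0.82,0.21,0.81,0.22,0.1
faz_area_mm2,0.36,0.15,0.35,0.16,0.02
faz_eccentricity,0.65,0.14,0.67,0.12,0.05
faz_axis_ratio,1.73,0.32,1.86,0.42,1
faz_perimeter_mm,3.37,1.17,3.43,1.39,0.5
faz_acircularity,1.61,0.29,1.67,0.45,1",
                  stringsAsFactors = FALSE)
  cat_ <- read.csv(text = 'variable,levels,count_pnp,count_nopnp
sex_male,"n,y","10,12","6,20"
dm_type2,"n,y","8,14","4,22"
insulin,"n,y","4,18","12,14"
smoking,"n,y","16,6","20,6"
lipid_lowering,"n,y","13,9","8,18"
hypertension,"n,y","7,15","6,20"
ischemic_heart_disease,"n,y","20,2","19,7"
stroke,"n,y","22,0","23,3"
prp,"n,y","2,20","16,10"
pseudophakic,"n,y","17,5","19,7"
past_anti_vegf,"n,y","12,10","17,9"
past_steroids,"n,y","21,1","25,1"
previous_vitrectomy,"n,y","21,1","26,0"
hard_exudates,"n,y","11,11","12,14"
subretinal_fluid,"n,y","12,10","24,2"
cystoid_inl,"n,y","8,14","7,19"
cystoid_onl,"n,y","3,19","0,26"
intact_ez,"n,y","3,19","0,26"
dril,"n,y","17,5","17,9"
intact_capillary_ring,"n,y","18,4","16,10"
perifoveal_capillary_loss,"n,y","3,19","1,25"
microaneurysms,"none,lt10,ge10","0,12,10","0,5,23"
fluorescein_leakage,"focal,intermediate,diffuse","3,4,15","12,7,9"
hrf_count,"0,lt10,b10_20,gt20","6,6,4,6","3,11,5,7"',
                   stringsAsFactors = FALSE)
  list(numeric = num, categorical = cat_)
}

#' Specification of a synthetic clinical cohort
#'
#' @param n_patients number of patients (default 33).
#' @param n_bilateral patients contributing both eyes (default 15); total
#'   eyes = `n_patients + n_bilateral`.
#' @param group_sizes named vector `c(pnp = 22, no_pnp = 26)`; must sum to
#'   the total number of eyes.
#' @param variable_defs as returned by [cohort_variable_defs].
#' @param patient_random_sd between-patient intercept SD expressed as a
#'   fraction of each numeric variable's pooled SD (default 0.45).
#' @param missingness named integer vector: number of cells to blank per
#'   variable. Default matches the study: 1 for HbA1c; 2 each for DM
#'   duration, LDL, HDL, past anti-VEGF and past steroids.
#' @param seed integer seed.
#' @return object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_patients = 33L, n_bilateral = 15L,
                        group_sizes = c(pnp = 22L, no_pnp = 26L),
                        variable_defs = cohort_variable_defs(),
                        patient_random_sd = 0.45,
                        missingness = c(hba1c = 1L, dm_duration = 2L,
                                        ldl = 2L, hdl = 2L,
                                        past_anti_vegf = 2L,
                                        past_steroids = 2L),
                        seed = 1L) {
  if (n_bilateral > n_patients) stop("n_bilateral must be <= n_patients")
  n_eyes <- n_patients + n_bilateral
  if (sum(group_sizes) != n_eyes)
    stop(sprintf("group sizes must sum to the %d eyes", n_eyes))
  structure(list(n_patients = as.integer(n_patients),
                 n_bilateral = as.integer(n_bilateral),
                 n_eyes = as.integer(n_eyes),
                 group_sizes = group_sizes, variable_defs = variable_defs,
                 patient_random_sd = patient_random_sd,
                 missingness = missingness, seed = as.integer(seed)),
            class = "cohort_spec")
}

#' Generate a synthetic per-eye cohort table
#'
#' One row per eye. Numeric variables are drawn group-wise from
#' `Normal(mean, SD)` with an added patient-shared intercept
#' (`patient_random_sd` x pooled SD), so bilateral eyes are correlated.
#' Categorical variables are drawn from the group-wise level frequencies.
#' The PNP label is assigned to match the group sizes exactly. The default
#' missingness plan is then applied.
#'
#' @param spec a [cohort_spec].
#' @return data frame with columns `patient_id`, `pnp_present`, the numeric
#'   variables and the categorical variables (as character); `NA` marks
#'   missing cells.
#' @export
generate_cohort <- function(spec = cohort_spec()) {
  set.seed(spec$seed)
  pid <- c(rep(seq_len(spec$n_bilateral), each = 2),
           seq(spec$n_bilateral + 1, spec$n_patients))
  n <- length(pid)
  grp <- rep("n", n)
  grp[sample.int(n, spec$group_sizes[["pnp"]])] <- "y"
  df <- data.frame(patient_id = sprintf("P%02d", pid), pnp_present = grp,
                   stringsAsFactors = FALSE)
  nd <- spec$variable_defs$numeric
  for (i in seq_len(nrow(nd))) {
    b <- stats::rnorm(spec$n_patients)          # patient intercepts
    sd_pool <- (nd$sd_pnp[i] + nd$sd_nopnp[i]) / 2
    rho <- spec$patient_random_sd
    mu <- ifelse(grp == "y", nd$mean_pnp[i], nd$mean_nopnp[i])
    sdg <- ifelse(grp == "y", nd$sd_pnp[i], nd$sd_nopnp[i])
    val <- mu + rho * sd_pool * b[pid] +
      sqrt(max(0, 1 - rho^2)) * sdg * stats::rnorm(n)
    df[[nd$variable[i]]] <- pmax(val, nd$lower[i])
  }
  cd <- spec$variable_defs$categorical
  for (i in seq_len(nrow(cd))) {
    lev <- strsplit(cd$levels[i], ",")[[1]]
    wp <- as.numeric(strsplit(cd$count_pnp[i], ",")[[1]])
    wn <- as.numeric(strsplit(cd$count_nopnp[i], ",")[[1]])
    val <- character(n)
    val[grp == "y"] <- sample(lev, sum(grp == "y"), replace = TRUE,
                              prob = wp / sum(wp))
    val[grp == "n"] <- sample(lev, sum(grp == "n"), replace = TRUE,
                              prob = wn / sum(wn))
    df[[cd$variable[i]]] <- val
  }
  inject_missingness(df, spec$missingness, seed = spec$seed + 1L)
}

#' Blank cells completely at random
#'
#' @param table cohort data frame.
#' @param plan named integer vector variable -> number of cells to blank.
#' @param seed integer seed.
#' @return the table with the requested cells set to `NA`.
#' @export
inject_missingness <- function(table, plan, seed = 1L) {
  if (length(plan) == 0L) return(table)
  set.seed(seed)
  for (v in names(plan)) {
    if (!v %in% names(table)) stop(sprintf("unknown variable '%s'", v))
    k <- plan[[v]]
    if (k > nrow(table)) stop("more missing cells requested than rows")
    table[[v]][sample.int(nrow(table), k)] <- NA
  }
  table
}

#' Write / read a cohort table as CSV
#'
#' Missing values are written as empty strings; `patient_id` is mandatory.
#'
#' @param table cohort data frame.
#' @param path file path.
#' @return `read_cohort_csv` returns the data frame; `write_cohort_csv`
#'   returns `path` invisibly.
#' @export
write_cohort_csv <- function(table, path) {
  utils::write.csv(table, path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_cohort_csv
#' @export
read_cohort_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        na.strings = c("", "NA"))
  if (!"patient_id" %in% names(df)) stop("cohort CSV lacks patient_id")
  df
}

#' Simulate a cohort with planted logistic predictors
#'
#' Simulation tool for validating the selection chain: numeric predictors
#' are standard normal (shared patient intercept optional); the binary
#' response is drawn from a mixed logistic model with the given
#' coefficients on the named predictors and a patient random intercept.
#'
#' @param n_patients patients; each contributes `eyes_per_patient` eyes.
#' @param eyes_per_patient default 2.
#' @param betas named coefficient vector on the log-odds scale (names
#'   become predictor columns); unnamed extra noise predictors can be
#'   added with `n_noise`.
#' @param n_noise number of pure-noise predictors (named noise1, ...).
#' @param intercept log-odds intercept.
#' @param random_sd SD of the patient random intercept on the response.
#' @param predictor_icc fraction of predictor variance shared within
#'   patient.
#' @param seed integer seed.
#' @return data frame with `patient_id`, `pnp_present` ("y"/"n") and the
#'   predictor columns.
#' @export
simulate_logistic_cohort <- function(n_patients = 100, eyes_per_patient = 2,
                                     betas = c(), n_noise = 0,
                                     intercept = 0, random_sd = 1,
                                     predictor_icc = 0.3, seed = 1L) {
  set.seed(seed)
  pid <- rep(seq_len(n_patients), each = eyes_per_patient)
  n <- length(pid)
  vars <- c(names(betas), if (n_noise > 0) paste0("noise", seq_len(n_noise)))
  df <- data.frame(patient_id = sprintf("P%04d", pid))
  eta <- rep(intercept, n) + stats::rnorm(n_patients, 0, random_sd)[pid]
  for (v in vars) {
    bshare <- stats::rnorm(n_patients)[pid]
    x <- sqrt(predictor_icc) * bshare +
      sqrt(1 - predictor_icc) * stats::rnorm(n)
    df[[v]] <- x
    if (v %in% names(betas)) eta <- eta + betas[[v]] * x
  }
  df$pnp_present <- ifelse(stats::runif(n) < stats::plogis(eta), "y", "n")
  df[, c("patient_id", "pnp_present", vars)]
}
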