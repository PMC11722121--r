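test_that("phantom ground truth matches its generating geometry", {
  # straight segments have exactly unit arc/chord ratio
  ph0 <- generate_vessel_phantom(small_phantom_spec(2, tortuosity_amp = 0))
  tt <- ph0$truth$tortuosity_m1
  expect_true(all(abs(tt[!is.na(tt)] - 1) < 1e-6))
  # circular FAZ: zero eccentricity and pi r^2 area
  phc <- generate_vessel_phantom(small_phantom_spec(3,
    faz_axes_mm = c(0.25, 0.25)))
  expect_equal(phc$truth$faz_eccentricity, 0)
  expect_equal(phc$truth$faz_area_mm2, pi * 0.25^2)
  # determinism
  a <- generate_vessel_phantom(small_phantom_spec(5))
  b <- generate_vessel_phantom(small_phantom_spec(5))
  expect_identical(a$truth$mask, b$truth$mask)
  expect_identical(a$image$pixels, b$image$pixels)
})

test_that("phantom rasterization agrees with a brute-force stamping oracle", {
  ph <- generate_vessel_phantom(phantom_spec(seed = 1, grid_size = c(96L, 96L),
                                             field_mm = 1.0, n_trees = 2L,
                                             faz_axes_mm = c(0.12, 0.10)))
  oracle <- oracle_rasterize(ph$truth$centerlines, ph$truth$widths,
                             c(96L, 96L))
  expect_identical(sum(ph$truth$mask), sum(oracle))
  expect_identical(ph$truth$mask, oracle)
})

test_that("no vessel pixels intrude into the eroded FAZ ellipse", {
  for (s in 1:5) {
    ph <- generate_vessel_phantom(small_phantom_spec(s))
    sp <- ph$truth$spec
    nr <- sp$grid_size[1]; nc <- sp$grid_size[2]
    xs <- matrix(rep(1:nc, each = nr), nr, nc)
    ys <- matrix(rep(1:nr, nc), nr, nc)
    inside <- ((xs - sp$faz_center_px[1]) / (sp$faz_axes_px[1] - 1))^2 +
      ((ys - sp$faz_center_px[2]) / (sp$faz_axes_px[2] - 1))^2 < 1
    expect_equal(sum(ph$truth$mask & inside), 0)
  }
})

test_that("invalid phantom specs are rejected", {
  expect_error(phantom_spec(faz_axes_mm = c(3, 3)), "exceeds")
  expect_error(phantom_spec(field_mm = -1), "field_mm")
  expect_error(phantom_spec(tortuosity_amp = -0.1), "tortuosity_amp")
})

test_that("generator Strahler bookkeeping matches recursive recursion on its topology", {
  for (s in 1:20) {
    ph <- generate_vessel_phantom(small_phantom_spec(s,
      capillary_density_target = 0, branch_depth = 5L))
    for (topo in ph$truth$tree_topologies) {
      ed <- data.frame(
        from = vapply(topo, function(e)
          if (is.na(e$parent)) 0L else e$parent, integer(1)),
        to = vapply(topo, `[[`, integer(1), "id"))
      # oracle over the edge-parent topology: node v = edge id, root = 0
      ords <- oracle_strahler(ed, root = 0L)
      gen <- vapply(topo, `[[`, integer(1), "order")
      expect_identical(ords, gen)
    }
  }
})

test_that("frame stacks record their true motions and are reproducible", {
  ph <- generate_vessel_phantom(small_phantom_spec(1))
  st0 <- generate_frame_stack(ph$image, 1, motion_sd = 0, noise_sd = 0,
                              seed = 4)
  expect_equal(st0$frames[[1]]$pixels, ph$image$pixels)
  a <- generate_frame_stack(ph$image, 4, motion_sd = 2, noise_sd = 0.1,
                            seed = 7)
  b <- generate_frame_stack(ph$image, 4, motion_sd = 2, noise_sd = 0.1,
                            seed = 7)
  expect_identical(lapply(a$frames, `[[`, "pixels"),
                   lapply(b$frames, `[[`, "pixels"))
  # sampled translations have roughly the requested spread
  tx <- unlist(lapply(1:25, function(s)
    attr(generate_frame_stack(ph$image, 8, motion_sd = 2, noise_sd = 0,
                              seed = s), "true_transforms")$tx))
  expect_gt(sd(tx), 1)
  expect_lt(sd(tx), 3)
})

test_that("cohort generator reproduces the study structure", {
  co <- generate_cohort(cohort_spec(seed = 1))
  expect_equal(nrow(co), 48L)
  expect_equal(length(unique(co$patient_id)), 33L)
  expect_equal(sum(co$pnp_present == "y"), 22L)
  expect_equal(sum(co$pnp_present == "n"), 26L)
  expect_equal(sum(is.na(co$hba1c)), 1L)
  expect_equal(sum(is.na(co$ldl)), 2L)
  expect_equal(sum(is.na(co$past_steroids)), 2L)
  # 29 numeric + 24 categorical + patient id + label
  expect_equal(ncol(co), 55L)
  expect_equal(sum(vapply(co, is.numeric, logical(1))), 29L)
})

test_that("cohort group means track the specification over replicates", {
  defs <- cohort_variable_defs()$numeric
  vars <- c("hba1c", "perfusion_density", "faz_area_mm2")
  nrep <- 60
  reps <- array(NA_real_, c(nrep, length(vars), 2),
                dimnames = list(NULL, vars, c("y", "n")))
  for (s in seq_len(nrep)) {
    co <- generate_cohort(cohort_spec(seed = 100 + s, missingness = c()))
    for (v in vars) for (g in c("y", "n"))
      reps[s, v, g] <- mean(co[[v]][co$pnp_present == g])
  }
  for (v in vars) {
    d <- defs[defs$variable == v, ]
    for (g in c("y", "n")) {
      spec_mean <- if (g == "y") d$mean_pnp else d$mean_nopnp
      se <- sd(reps[, v, g]) / sqrt(nrep)   # empirical SE of the grand mean
      expect_lt(abs(mean(reps[, v, g]) - spec_mean), 4 * se + 0.01 * spec_mean)
    }
  }
})

test_that("zero patient effect yields uncorrelated bilateral pairs", {
  cors <- vapply(1:100, function(s) {
    co <- generate_cohort(cohort_spec(seed = s, patient_random_sd = 0,
                                      missingness = c()))
    bi <- co[duplicated(co$patient_id) | duplicated(co$patient_id,
                                                    fromLast = TRUE), ]
    v <- bi$egfr - ave(bi$egfr, bi$pnp_present)  # remove group effect
    first <- v[seq(1, length(v), 2)]
    second <- v[seq(2, length(v), 2)]
    cor(first, second)
  }, numeric(1))
  expect_lt(abs(mean(cors)), 0.2)
})

test_that("missingness injection is exact, reproducible and validated", {
  co <- generate_cohort(cohort_spec(seed = 3, missingness = c()))
  expect_identical(inject_missingness(co, c()), co)
  one <- inject_missingness(co, c(hba1c = 1L), seed = 5)
  expect_equal(sum(is.na(one$hba1c)), 1L)
  all_gone <- inject_missingness(co, c(ldl = 48L), seed = 5)
  expect_equal(sum(is.na(all_gone$ldl)), 48L)
  expect_error(inject_missingness(co, c(nope = 1L)), "unknown variable")
  expect_error(inject_missingness(co, c(ldl = 99L)), "more missing")
})

test_that("cohort CSV round-trips with empty-string missing markers", {
  co <- generate_cohort(cohort_spec(seed = 2))
  path <- tempfile(fileext = ".csv")
  write_cohort_csv(co, path)
  back <- read_cohort_csv(path)
  expect_equal(back$patient_id, co$patient_id)
  expect_equal(sum(is.na(back$hba1c)), sum(is.na(co$hba1c)))
  expect_equal(back$perfusion_density, co$perfusion_density,
               tolerance = 1e-12)
})
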