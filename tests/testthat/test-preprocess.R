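test_that("quality gate applies the strict SSI/quality thresholds", {
  expect_true(quality_gate(list(ssi = 51)))
  expect_false(quality_gate(list(ssi = 50, quality = 8)))
  expect_true(quality_gate(list(quality = 9)))
  expect_false(quality_gate(list(ssi = 50)))
  expect_true(quality_gate(list(ssi = 50.5)))
  expect_error(quality_gate(list(device = "x")), "neither")
})

test_that("inhomogeneity correction removes a smooth bias field", {
  flat <- enface_image(matrix(0.5, 120, 120), 0.01)
  out <- correct_inhomogeneity(flat, 0.5)
  expect_lt(max(abs(out$pixels - 0.5)) / 0.5, 1e-6)
  expect_error(correct_inhomogeneity(flat, 0), "positive")
  # stationary texture times a smooth gradient: recovered within 5% RMS
  set.seed(2)
  tex <- 0.5 + as.matrix(EBImage::gblur(matrix(rnorm(160 * 160, 0, 1),
                                               160, 160), 3)) * 0.8
  grad <- outer(seq(0.75, 1.25, length.out = 160),
                seq(0.85, 1.15, length.out = 160))
  biased <- enface_image(tex * grad, 0.01)
  rec <- correct_inhomogeneity(biased, 0.6)
  rms <- sqrt(mean((rec$pixels - tex)^2)) / sqrt(mean(tex^2))
  expect_lt(rms, 0.05)
})

test_that("intensity normalization matches reference moments exactly", {
  ph <- generate_vessel_phantom(small_phantom_spec(1))
  img <- ph$image
  expect_lt(max(abs(normalize_intensity(img, img)$pixels - img$pixels)),
            1e-6)
  scaled <- enface_image(2 * img$pixels + 10, img$pixel_size_mm)
  back <- normalize_intensity(scaled, img)
  expect_lt(max(abs(back$pixels - img$pixels)), 1e-6)
  other <- enface_image(matrix(runif(160 * 160), 160, 160),
                        img$pixel_size_mm)
  out <- normalize_intensity(other, img)
  expect_equal(mean(out$pixels), mean(img$pixels), tolerance = 1e-9)
  expect_equal(sd(out$pixels), sd(img$pixels), tolerance = 1e-9)
  expect_error(normalize_intensity(enface_image(matrix(1, 160, 160),
                                                img$pixel_size_mm), img),
               "zero-variance")
})

test_that("registration recovers known translations and rotations", {
  ph <- generate_vessel_phantom(small_phantom_spec(1))
  ref <- ph$image
  nr <- nrow(ref$pixels); nc <- ncol(ref$pixels)
  # identity
  rr <- register_frame(ref, ref, stages = "translation")
  expect_lt(max(abs(rr$estimates[[1]]$parameters)), 0.1)
  expect_false(rr$excluded)
  # pure shift (3, -2) px
  id <- octamorph:::identity_map(nr, nc)
  sh <- octamorph:::warp_by_map(ref$pixels, id$r - (-2), id$c - 3,
                                fill = mean(ref$pixels))
  rs <- register_frame(enface_image(sh, ref$pixel_size_mm), ref,
                       stages = "translation")
  expect_lt(max(abs(rs$estimates[[1]]$parameters - c(3, -2))), 0.5)
  # 5 degree rotation about centre, affine stage
  th <- 5 * pi / 180; ctr <- c((nr + 1) / 2, (nc + 1) / 2)
  rm <- id$r - ctr[1]; cm <- id$c - ctr[2]
  rot <- octamorph:::warp_by_map(ref$pixels,
                                 cos(th) * rm + sin(th) * cm + ctr[1],
                                 -sin(th) * rm + cos(th) * cm + ctr[2],
                                 fill = mean(ref$pixels))
  ra <- register_frame(enface_image(rot, ref$pixel_size_mm), ref,
                       stages = c("translation", "affine"))
  est_deg <- abs(ra$estimates[[2]]$parameters[3]) * 180 / pi
  expect_lt(abs(est_deg - 5), 1)
})

test_that("each registration stage maintains or reduces the dissimilarity", {
  ph <- generate_vessel_phantom(small_phantom_spec(2))
  st <- generate_frame_stack(ph$image, 2, motion_sd = 2, noise_sd = 0.1,
                             seed = 3)
  rr <- register_frame(st$frames[[2]], st$frames[[1]],
                       stages = c("translation", "affine", "elastic"))
  resid <- vapply(rr$estimates, `[[`, numeric(1), "residual")
  expect_true(all(diff(resid) <= 1e-9))
})

test_that("stack averaging: modes, permutation invariance, SNR gain", {
  ph <- generate_vessel_phantom(small_phantom_spec(1))
  one <- frame_stack(list(ph$image))
  expect_equal(average_stack(one, "mean")$pixels, ph$image$pixels)
  zeros <- enface_image(matrix(0, 4, 4), 1)
  ones <- enface_image(matrix(1, 4, 4), 1)
  expect_true(all(average_stack(frame_stack(list(zeros, ones)),
                                "max")$pixels == 1))
  # permutation invariance of the mean
  st <- generate_frame_stack(ph$image, 5, motion_sd = 0, noise_sd = 0.2,
                             seed = 5)
  perm <- frame_stack(st$frames[c(3, 1, 5, 2, 4)])
  expect_equal(average_stack(st, "mean")$pixels,
               average_stack(perm, "mean")$pixels)
  # averaging 8 registered noisy frames beats the median single frame
  st8 <- generate_frame_stack(ph$image, 8, motion_sd = 1.5, noise_sd = 0.15,
                              seed = 6)
  pp <- preprocess_stack(st8, stages = "translation")
  rms <- function(a) sqrt(mean((a - ph$image$pixels)^2))
  singles <- vapply(st8$frames, function(f) rms(f$pixels), numeric(1))
  expect_lt(rms(pp$image$pixels), median(singles))
})

test_that("residual noise of the average decreases with frame count", {
  # integer translations: the warp is exact, so the residual against the
  # noise-free reference isolates the noise component
  ph <- generate_vessel_phantom(small_phantom_spec(3))
  ref <- ph$image$pixels
  nr <- nrow(ref); nc <- ncol(ref)
  shift_int <- function(m, dy, dx) {
    out <- matrix(mean(m), nr, nc)
    rs <- max(1, 1 + dy):min(nr, nr + dy)
    cs <- max(1, 1 + dx):min(nc, nc + dx)
    out[rs, cs] <- m[rs - dy, cs - dx]
    out
  }
  rms_for_n <- function(n, seed) {
    set.seed(seed)
    frames <- lapply(seq_len(n), function(i) {
      d <- if (i == 1) c(0, 0) else sample(-3:3, 2, replace = TRUE)
      f <- shift_int(ref, d[1], d[2]) +
        matrix(rnorm(nr * nc, 0, 0.12), nr, nc)
      enface_image(pmax(f, 0), ph$image$pixel_size_mm,
                   device_meta = list(quality = 10))
    })
    pp <- preprocess_stack(frame_stack(frames), stages = "translation",
                           kernel_mm = 10)   # near-flat background estimate
    inner <- 20:(nr - 20)
    sqrt(mean((pp$image$pixels[inner, inner] - ref[inner, inner])^2))
  }
  means <- vapply(c(2, 4, 8), function(n)
    mean(vapply(1:8, function(s) rms_for_n(n, 10 * n + s), numeric(1))),
    numeric(1))
  expect_true(all(diff(means) < 0))
})
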