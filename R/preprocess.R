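#' Gate a frame on device quality metadata
#'
#' A frame is usable when its signal strength index exceeds 50 or its scan
#' quality score exceeds 8 out of 10 (strict inequalities).
#'
#' @param meta named list; recognised entries `ssi` and `quality`.
#' @return `TRUE` if the frame passes, `FALSE` otherwise.
#' @export
quality_gate <- function(meta) {
  ssi <- meta$ssi; q <- meta$quality
  if (is.null(ssi) && is.null(q))
    stop("device_meta carries neither a signal strength index nor a quality score")
  isTRUE(ssi > 50) || isTRUE(q > 8)
}

#' Correct intensity inhomogeneity by background division
#'
#' Estimates a smooth multiplicative bias field by heavy Gaussian smoothing
#' and divides it out, rescaling so the global mean intensity is preserved.
#' Flat images map to themselves.
#'
#' @param image an [enface_image].
#' @param kernel_mm Gaussian kernel sigma in mm; must exceed typical vessel
#'   spacing (default 0.5 mm).
#' @return corrected [enface_image] (provenance `"corrected"`).
#' @export
correct_inhomogeneity <- function(image, kernel_mm = 0.5) {
  if (!is.numeric(kernel_mm) || kernel_mm <= 0)
    stop("kernel_mm must be positive")
  px <- image$pixels
  sigma_px <- kernel_mm / image$pixel_size_mm
  bg <- pmax(heavy_blur(px, sigma_px), 1e-8)
  out <- px / bg
  out <- out * (mean(px) / mean(out))
  enface_image(out, image$pixel_size_mm, image$device_meta, "corrected")
}

#' Match intensity moments to a reference frame
#'
#' Linearly rescales intensities so the output has the reference's mean and
#' standard deviation.
#'
#' @param image,reference [enface_image] objects of the same shape.
#' @return normalized [enface_image].
#' @export
normalize_intensity <- function(image, reference) {
  if (!identical(dim(image$pixels), dim(reference$pixels)))
    stop("image and reference must share shape")
  s <- stats::sd(image$pixels)
  if (s == 0) stop("zero-variance image cannot be normalized")
  out <- (image$pixels - mean(image$pixels)) / s * stats::sd(reference$pixels) +
    mean(reference$pixels)
  enface_image(out, image$pixel_size_mm, image$device_meta, image$provenance)
}

# FFT cross-correlation translation estimate with sub-pixel parabolic
# refinement. Returns c(tx, ty): the shift that was APPLIED to fixed to get
# moving, i.e. moving(x) ~ fixed(x - t).
estimate_translation <- function(moving, fixed) {
  a <- fixed - mean(fixed); b <- moving - mean(moving)
  nr <- nrow(a); nc <- ncol(a)
  X <- stats::fft(stats::fft(a) * Conj(stats::fft(b)), inverse = TRUE)
  cc <- Re(X) / length(a)
  pk <- which(cc == max(cc), arr.ind = TRUE)[1, ]
  subpix <- function(m, i, n) {
    im <- if (i == 1) n else i - 1L
    ip <- if (i == n) 1L else i + 1L
    c(im, i, ip)
  }
  ri <- subpix(cc, pk[1], nr); ci <- subpix(cc, pk[2], nc)
  para <- function(ym, y0, yp) {
    den <- ym - 2 * y0 + yp
    if (abs(den) < 1e-12) 0 else 0.5 * (ym - yp) / den
  }
  dr <- para(cc[ri[1], pk[2]], cc[pk[1], pk[2]], cc[ri[3], pk[2]])
  dc <- para(cc[pk[1], ci[1]], cc[pk[1], pk[2]], cc[pk[1], ci[3]])
  sh <- c(pk[1] - 1 + dr, pk[2] - 1 + dc)
  if (sh[1] > nr / 2) sh[1] <- sh[1] - nr
  if (sh[2] > nc / 2) sh[2] <- sh[2] - nc
  # cc peak at (dy, dx) where moving = shift(fixed by +d)
  c(tx = -sh[2], ty = -sh[1])
}

# Coordinate map for an affine transform p = (tx, ty, theta, log_sx, log_sy,
# shear) about the image centre: maps output (r, c) to input coordinates.
affine_map <- function(p, nr, nc) {
  id <- identity_map(nr, nc)
  ctr <- c((nr + 1) / 2, (nc + 1) / 2)
  th <- p[3]; sx <- exp(p[4]); sy <- exp(p[5]); sh <- p[6]
  rr <- id$r - ctr[1] - p[2]
  cc <- id$c - ctr[2] - p[1]
  # inverse of scale/shear/rotation applied in x (col), y (row)
  cosr <- cos(th); sinr <- sin(th)
  xr <- cosr * cc + sinr * rr
  yr <- -sinr * cc + cosr * rr
  xs <- xr / sx
  ys <- (yr - sh * xr) / sy
  list(r = ys + ctr[1], c = xs + ctr[2])
}

#' Register a moving frame onto a fixed frame
#'
#' Applies the requested alignment stages in order: `"translation"` (FFT
#' cross-correlation with sub-pixel refinement), `"affine"` (Nelder-Mead
#' maximisation of normalized cross-correlation over translation, rotation,
#' anisotropic scale and shear), and `"elastic"` (local block-matching
#' translations on a coarse control grid, interpolated to a smooth dense
#' displacement field). The dissimilarity score is the negative normalized
#' cross-correlation. All stages are composed into a single coordinate map
#' so the moving frame is resampled exactly once.
#'
#' @param moving,fixed [enface_image] objects of the same shape.
#' @param stages character vector, ordered subset of
#'   `c("translation", "affine", "elastic")`.
#' @param elastic_spacing_px control-grid spacing for the elastic stage.
#' @param epsilon minimum required dissimilarity improvement at the
#'   translation stage; non-improvement flags the frame as excluded.
#' @return list with `image` (registered [enface_image]), `estimates` (list
#'   of per-stage estimates: stage, parameters, residual) and `excluded`
#'   (logical).
#' @export
register_frame <- function(moving, fixed,
                           stages = c("translation", "affine", "elastic"),
                           elastic_spacing_px = 32, epsilon = 0) {
  if (!identical(dim(moving$pixels), dim(fixed$pixels)))
    stop("moving and fixed must share shape")
  stages <- match.arg(stages, c("translation", "affine", "elastic"),
                      several.ok = TRUE)
  mv <- moving$pixels; fx <- fixed$pixels
  nr <- nrow(mv); nc <- ncol(mv)
  id <- identity_map(nr, nc)
  map <- id                       # output coord -> moving coord
  estimates <- list()
  excluded <- FALSE
  score0 <- -ncc(mv, fx)
  current <- mv
  p_aff <- rep(0, 6)
  for (st in stages) {
    if (st == "translation") {
      t_est <- estimate_translation(current, fx)
      p_new <- p_aff
      p_new[1:2] <- p_new[1:2] - t_est    # correcting shift = -motion
      map_new <- affine_map(p_new, nr, nc)
      cand <- warp_by_map(mv, map_new$r, map_new$c, fill = mean(mv))
      score1 <- -ncc(cand, fx)
      moved <- (abs(t_est[1]) + abs(t_est[2])) > 0.05
      if (score1 < score0 - epsilon || !moved) {
        if (score1 <= score0) {
          p_aff <- p_new; map <- map_new; current <- cand; score0 <- score1
        }
      } else {
        excluded <- TRUE
      }
      estimates[[length(estimates) + 1L]] <-
        list(stage = "translation", parameters = t_est, residual = score0)
    } else if (st == "affine") {
      # optimize on a 2x-decimated grid for speed, translations halved
      ds <- if (min(nr, nc) > 128) 2L else 1L
      mv_s <- mv[seq(1, nr, ds), seq(1, nc, ds)]
      fx_s <- fx[seq(1, nr, ds), seq(1, nc, ds)]
      nrs <- nrow(mv_s); ncs <- ncol(mv_s)
      obj_s <- function(p) {
        m <- affine_map(p, nrs, ncs)
        -ncc(warp_by_map(mv_s, m$r, m$c, fill = mean(mv_s)), fx_s)
      }
      p0 <- p_aff; p0[1:2] <- p0[1:2] / ds
      # joint rotation/translation pre-search: quasi-periodic capillary
      # texture aliases the translation stage under rotation, so for each
      # candidate angle the translation is re-estimated by FFT before
      # scoring
      thetas <- seq(-10, 10, by = 1) * pi / 180
      best <- list(score = obj_s(p0), p = p0)
      for (th in thetas) {
        mrot <- affine_map(c(0, 0, th, 0, 0, 0), nrs, ncs)
        w <- warp_by_map(mv_s, mrot$r, mrot$c, fill = mean(mv_s))
        t_est <- estimate_translation(w, fx_s)
        cand <- c(-t_est, th, 0, 0, 0)
        sc <- obj_s(cand)
        if (sc < best$score) best <- list(score = sc, p = cand)
      }
      p0 <- best$p
      opt <- stats::optim(p0, obj_s, method = "Nelder-Mead",
                          control = list(maxit = 250, reltol = 1e-7,
                                         parscale = c(1, 1, 0.02, 0.02, 0.02, 0.02)))
      opt$par[1:2] <- opt$par[1:2] * ds
      obj <- function(p) {
        m <- affine_map(p, nr, nc)
        -ncc(warp_by_map(mv, m$r, m$c, fill = mean(mv)), fx)
      }
      opt <- stats::optim(opt$par, obj, method = "Nelder-Mead",
                          control = list(maxit = 120, reltol = 1e-8,
                                         parscale = c(1, 1, 0.02, 0.02, 0.02, 0.02)))
      if (opt$value <= score0) {
        p_aff <- opt$par
        map <- affine_map(p_aff, nr, nc)
        current <- warp_by_map(mv, map$r, map$c, fill = mean(mv))
        score0 <- opt$value
      }
      estimates[[length(estimates) + 1L]] <-
        list(stage = "affine", parameters = p_aff, residual = score0)
    } else if (st == "elastic") {
      sp <- elastic_spacing_px
      grid_r <- unique(c(seq(1, nr, by = sp), nr))
      grid_c <- unique(c(seq(1, nc, by = sp), nc))
      dr <- matrix(0, length(grid_r), length(grid_c))
      dc <- matrix(0, length(grid_r), length(grid_c))
      half <- sp                       # block half-size
      for (i in seq_along(grid_r)) for (j in seq_along(grid_c)) {
        r0 <- max(1, grid_r[i] - half); r1 <- min(nr, grid_r[i] + half)
        c0 <- max(1, grid_c[j] - half); c1 <- min(nc, grid_c[j] + half)
        if ((r1 - r0) < 8 || (c1 - c0) < 8) next
        blk_f <- fx[r0:r1, c0:c1]; blk_m <- current[r0:r1, c0:c1]
        if (stats::sd(blk_f) < 1e-8 || stats::sd(blk_m) < 1e-8) next
        t_loc <- estimate_translation(blk_m, blk_f)
        t_loc <- pmax(pmin(t_loc, 3), -3)   # cap local displacement
        dc[i, j] <- t_loc[1]; dr[i, j] <- t_loc[2]
      }
      # light smoothing of the control grid, then dense bilinear field
      smooth3 <- function(m) {
        if (nrow(m) < 3 || ncol(m) < 3) return(m)
        out <- m
        out[2:(nrow(m) - 1), 2:(ncol(m) - 1)] <-
          (m[1:(nrow(m) - 2), 2:(ncol(m) - 1)] + m[3:nrow(m), 2:(ncol(m) - 1)] +
           m[2:(nrow(m) - 1), 1:(ncol(m) - 2)] + m[2:(nrow(m) - 1), 3:ncol(m)] +
           4 * m[2:(nrow(m) - 1), 2:(ncol(m) - 1)]) / 8
        out
      }
      dr <- smooth3(dr); dc <- smooth3(dc)
      interp_field <- function(dm) {
        rows <- stats::approx(grid_r, seq_along(grid_r), xout = seq_len(nr),
                              rule = 2)$y
        cols <- stats::approx(grid_c, seq_along(grid_c), xout = seq_len(nc),
                              rule = 2)$y
        bilinear_sample(dm, rep(rows, nc), rep(cols, each = nr)) |>
          matrix(nr, nc)
      }
      fld_r <- interp_field(dr); fld_c <- interp_field(dc)
      cand_map <- list(r = bilinear_sample(map$r, as.vector(id$r - fld_r),
                                           as.vector(id$c - fld_c)) |> matrix(nr, nc),
                       c = bilinear_sample(map$c, as.vector(id$r - fld_r),
                                           as.vector(id$c - fld_c)) |> matrix(nr, nc))
      cand <- warp_by_map(mv, cand_map$r, cand_map$c, fill = mean(mv))
      sc <- -ncc(cand, fx)
      if (sc <= score0) {
        map <- cand_map; current <- cand; score0 <- sc
        pars <- c(mean_abs_dr = mean(abs(fld_r)), mean_abs_dc = mean(abs(fld_c)))
      } else {
        pars <- c(mean_abs_dr = 0, mean_abs_dc = 0)
      }
      estimates[[length(estimates) + 1L]] <-
        list(stage = "elastic", parameters = pars, residual = score0)
    }
  }
  out <- enface_image(current, moving$pixel_size_mm, moving$device_meta,
                      "corrected")
  list(image = out, estimates = estimates, excluded = excluded)
}

#' Average a registered frame stack into one image
#'
#' Pixelwise mean (default, used for quantification) or maximum projection
#' across frames.
#'
#' @param stack a [frame_stack] of registered, normalized frames.
#' @param mode `"mean"` or `"max"`.
#' @return [enface_image] with provenance `"averaged"`.
#' @export
average_stack <- function(stack, mode = c("mean", "max")) {
  mode <- match.arg(mode)
  if (length(stack$frames) == 0L) stop("empty stack")
  arr <- vapply(stack$frames, function(f) f$pixels,
                stack$frames[[1]]$pixels)
  dim(arr) <- c(dim(stack$frames[[1]]$pixels), length(stack$frames))
  out <- if (mode == "mean") apply(arr, c(1, 2), mean) else
    apply(arr, c(1, 2), max)
  enface_image(out, stack$frames[[1]]$pixel_size_mm,
               stack$frames[[1]]$device_meta, "averaged")
}

#' Full preprocessing chain for a frame stack
#'
#' Gates frames on quality metadata, corrects intensity inhomogeneity,
#' registers every frame onto the reference (the gated frame with the
#' highest quality score, ties broken by lowest index), normalizes
#' intensities to the reference, and averages.
#'
#' @param stack a [frame_stack].
#' @param mode averaging mode, `"mean"` or `"max"`.
#' @param stages registration stages (see [register_frame]).
#' @param kernel_mm inhomogeneity-correction kernel (mm).
#' @return list with `image` (averaged [enface_image]), `kept` (indices of
#'   frames that survived gating and registration) and `estimates`
#'   (per-kept-frame registration estimates).
#' @export
preprocess_stack <- function(stack, mode = "mean",
                             stages = c("translation", "affine"),
                             kernel_mm = 0.5) {
  gated <- which(vapply(stack$frames, function(f)
    tryCatch(quality_gate(f$device_meta), error = function(e) TRUE),
    logical(1)))
  if (length(gated) == 0L) stop("no frame passes the quality gate")
  qscore <- vapply(stack$frames[gated], function(f)
    f$device_meta$quality %||% f$device_meta$ssi %||% 0, numeric(1))
  ref_idx <- gated[which.max(qscore)]
  corrected <- lapply(stack$frames, correct_inhomogeneity, kernel_mm = kernel_mm)
  fixed <- corrected[[ref_idx]]
  kept <- integer(0); regd <- list(); ests <- list()
  for (i in gated) {
    if (i == ref_idx) {
      regd[[length(regd) + 1L]] <- fixed; kept <- c(kept, i)
      next
    }
    rr <- register_frame(corrected[[i]], fixed, stages = stages)
    if (rr$excluded) next
    regd[[length(regd) + 1L]] <- normalize_intensity(rr$image, fixed)
    ests[[length(ests) + 1L]] <- rr$estimates
    kept <- c(kept, i)
  }
  avg <- average_stack(frame_stack(regd), mode = mode)
  list(image = avg, kept = kept, estimates = ests)
}
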