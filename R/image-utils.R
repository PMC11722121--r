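#' En face angiogram container
#'
#' Lightweight container for a 2D en face OCTA intensity image together with
#' its physical pixel size and free-form device metadata (signal strength
#' index, scan quality score, ...).
#'
#' @param pixels numeric matrix of non-negative intensities (rows = y,
#'   columns = x).
#' @param pixel_size_mm physical size of one pixel in millimetres.
#' @param device_meta named list of device metadata; recognised entries are
#'   `ssi` (signal strength index) and `quality` (scan quality score).
#' @param provenance one of `"raw"`, `"corrected"`, `"averaged"`.
#' @return An object of class `enface_image`.
#' @export
enface_image <- function(pixels, pixel_size_mm, device_meta = list(),
                         provenance = "raw") {
  pixels <- as.matrix(pixels)
  if (length(pixels) == 0L) stop("image grid must be non-empty")
  if (!is.numeric(pixel_size_mm) || pixel_size_mm <= 0)
    stop("pixel_size_mm must be > 0")
  provenance <- match.arg(provenance, c("raw", "corrected", "averaged"))
  structure(list(pixels = pixels, pixel_size_mm = pixel_size_mm,
                 device_meta = device_meta, provenance = provenance),
            class = "enface_image")
}

#' @export
print.enface_image <- function(x, ...) {
  cat(sprintf("<enface_image> %d x %d px, %.5f mm/px, provenance: %s\n",
              nrow(x$pixels), ncol(x$pixels), x$pixel_size_mm, x$provenance))
  invisible(x)
}

#' @export
dim.enface_image <- function(x) dim(x$pixels)

as_enface <- function(x, pixel_size_mm = NULL, template = NULL) {
  if (inherits(x, "enface_image")) return(x)
  if (!is.null(template))
    return(enface_image(x, template$pixel_size_mm, template$device_meta,
                        template$provenance))
  enface_image(x, pixel_size_mm %||% 1)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Ordered stack of en face frames
#'
#' @param frames list of [enface_image] objects sharing shape and pixel size.
#' @param reference_index index of the reference frame for registration.
#' @return An object of class `frame_stack`.
#' @export
frame_stack <- function(frames, reference_index = 1L) {
  if (length(frames) < 1L) stop("a frame stack needs at least one frame")
  d <- dim(frames[[1]]$pixels)
  ps <- frames[[1]]$pixel_size_mm
  for (f in frames) {
    if (!identical(dim(f$pixels), d)) stop("all frames must share shape")
    if (abs(f$pixel_size_mm - ps) > 1e-12)
      stop("all frames must share pixel size")
  }
  if (reference_index < 1L || reference_index > length(frames))
    stop("reference_index out of range")
  structure(list(frames = frames, reference_index = as.integer(reference_index)),
            class = "frame_stack")
}

#' @export
length.frame_stack <- function(x) length(x$frames)

#' Read / write en face images as 16-bit grayscale TIFF
#'
#' Intensities are clipped to `[0, 1]` on write. Pixel size is not stored in
#' the TIFF; supply it on read.
#'
#' @param image an [enface_image].
#' @param path file path.
#' @param pixel_size_mm pixel size to attach on read.
#' @return `read_enface_tiff` returns an [enface_image]; `write_enface_tiff`
#'   returns `path` invisibly.
#' @export
write_enface_tiff <- function(image, path) {
  px <- pmax(pmin(image$pixels, 1), 0)
  tiff::writeTIFF(px, path, bits.per.sample = 16L)
  invisible(path)
}

#' @rdname write_enface_tiff
#' @export
read_enface_tiff <- function(path, pixel_size_mm) {
  px <- tiff::readTIFF(path)
  if (length(dim(px)) == 3L) px <- px[, , 1]
  enface_image(px, pixel_size_mm)
}

# Bilinear sampling of matrix `m` at (row, col) positions; outside values
# are filled with `fill`.
bilinear_sample <- function(m, r, c, fill = 0) {
  nr <- nrow(m); nc <- ncol(m)
  r0 <- floor(r); c0 <- floor(c)
  fr <- r - r0; fc <- c - c0
  val <- function(ri, ci) {
    ok <- ri >= 1 & ri <= nr & ci >= 1 & ci <= nc
    out <- rep(fill, length(ri))
    out[ok] <- m[cbind(ri[ok], ci[ok])]
    out
  }
  v00 <- val(r0, c0); v01 <- val(r0, c0 + 1)
  v10 <- val(r0 + 1, c0); v11 <- val(r0 + 1, c0 + 1)
  (1 - fr) * ((1 - fc) * v00 + fc * v01) + fr * ((1 - fc) * v10 + fc * v11)
}

# Warp matrix by a dense coordinate map: out[i,j] = m(map_r[i,j], map_c[i,j]).
warp_by_map <- function(m, map_r, map_c, fill = 0) {
  out <- bilinear_sample(m, as.vector(map_r), as.vector(map_c), fill = fill)
  matrix(out, nrow(m), ncol(m))
}

# Identity coordinate map for an nr x nc grid.
identity_map <- function(nr, nc) {
  list(r = matrix(rep(seq_len(nr), nc), nr, nc),
       c = matrix(rep(seq_len(nc), each = nr), nr, nc))
}

# Heavy Gaussian blur that stays cheap for sigma comparable to the image
# size: blur on a decimated grid, then resample back.
heavy_blur <- function(m, sigma) {
  nr <- nrow(m); nc <- ncol(m)
  blur_rep <- function(x, sg)            # replicate boundary, not circular
    as.matrix(EBImage::gblur(x, sigma = sg, boundary = "replicate"))
  k <- max(1, floor(sigma / 8))
  if (k == 1 && 2 * ceiling(3 * sigma) + 1 < min(nr, nc))
    return(blur_rep(m, sigma))
  small <- as.matrix(EBImage::resize(m, w = max(8, ceiling(nr / k)),
                                     h = max(8, ceiling(nc / k))))
  sg <- sigma / k
  if (2 * ceiling(3 * sg) + 1 >= min(dim(small)))
    sg <- (min(dim(small)) - 3) / 6.5
  small <- blur_rep(small, max(sg, 0.5))
  as.matrix(EBImage::resize(small, w = nr, h = nc))
}

# Normalized cross-correlation between two equally shaped matrices.
ncc <- function(a, b) {
  a <- as.vector(a); b <- as.vector(b)
  sa <- stats::sd(a); sb <- stats::sd(b)
  if (sa == 0 || sb == 0) return(0)
  mean((a - mean(a)) * (b - mean(b))) / (sa * sb)
}
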