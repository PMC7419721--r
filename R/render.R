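#' Random-dot stereogram specification
#'
#' Geometry and contrast for a dichoptic random-dot stereogram: a field
#' of isotropic log-Gabor micropatterns in which the dots inside a disc
#' (minus a missing 90-degree sector) are given horizontal disparity, so
#' that the fused percept is a floating pie shape. The missing sector can
#' point up, down, left or right (the 4AFC alternatives).
#'
#' @param disparity disparity of the pie region in arcsec, `[0, 4096]`.
#' @param sector_position integer 1--4: 1 = up, 2 = down, 3 = left,
#'   4 = right.
#' @param disc_diameter disc diameter in degrees (default 10).
#' @param element_size log-Gabor element size (envelope scale) in
#'   arcmin (default 10).
#' @param sector_angle angular width of the missing sector, degrees.
#' @param contrast_left,contrast_right per-eye Michelson contrast in
#'   percent, `[1, 100]`.
#' @param pixels_per_degree display sampling; at least 20 so 1-arcsec
#'   disparities remain representable sub-pixel.
#' @param dot_density elements per square degree (default 25).
#' @param margin background margin around the disc, degrees.
#' @param seed integer seed fixing the dot layout.
#' @return an object of class `"rds_spec"`.
#' @export
rds_spec <- function(disparity, sector_position = 1L, disc_diameter = 10,
                     element_size = 10, sector_angle = 90,
                     contrast_left = 80, contrast_right = 80,
                     pixels_per_degree = 30L, dot_density = 25,
                     margin = 0.5, seed = 1L) {
  if (disparity < 0 || disparity > 4096)
    stop("`disparity` must lie in [0, 4096] arcsec")
  if (!sector_position %in% 1:4) stop("`sector_position` must be 1..4")
  check_contrast(contrast_left, "contrast_left")
  check_contrast(contrast_right, "contrast_right")
  if (pixels_per_degree < 20)
    stop("disparity not representable: pixels_per_degree must be >= 20 ",
         "(sub-pixel placement resolves 1 arcsec only above this sampling)")
  structure(
    list(disparity = disparity, sector_position = as.integer(sector_position),
         disc_diameter = disc_diameter, element_size = element_size,
         sector_angle = sector_angle, contrast_left = contrast_left,
         contrast_right = contrast_right,
         pixels_per_degree = as.integer(pixels_per_degree),
         dot_density = dot_density, margin = margin, seed = as.integer(seed)),
    class = "rds_spec"
  )
}

# Isotropic log-Gabor kernel sampled on an `os`-times oversampled pixel
# grid, built in the frequency domain (log-Gaussian radial spectrum,
# 1-octave bandwidth: sigma_on_f = 0.745) and returned centred, peak
# normalised to 1.
log_gabor_kernel <- function(element_size_arcmin, pixels_per_degree, os = 8L) {
  elem_deg <- element_size_arcmin / 60
  f0 <- 1 / elem_deg # peak frequency, cycles/deg
  half_deg <- 1.5 * elem_deg
  n <- 2^ceiling(log2(2 * half_deg * pixels_per_degree * os))
  fs <- pixels_per_degree * os # samples per degree
  fr <- c(0:(n / 2), -(n / 2 - 1):-1) / n * fs
  f2 <- sqrt(outer(fr^2, fr^2, "+"))
  sigma_ln <- -log(0.745) # 1-octave FWHM
  G <- exp(-(log(pmax(f2, 1e-12) / f0))^2 / (2 * sigma_ln^2))
  G[1, 1] <- 0 # zero DC: elements are zero-mean
  k <- Re(fft(G, inverse = TRUE)) / n^2
  # rotate so the kernel centre sits at (n/2 + 1, n/2 + 1)
  idx <- c((n / 2 + 1):n, 1:(n / 2))
  k <- k[idx, idx]
  centre <- n / 2 + 1
  half_px <- ceiling(half_deg * pixels_per_degree)
  # splatting windows the kernel at +-half_px; remove the small residual
  # mean inside that window so each element is zero-mean as rendered
  w <- max(1, centre - half_px * os):min(n, centre + half_px * os)
  k <- k - mean(k[w, w])
  list(k = k / max(k), centre = centre, os = os, half_px = half_px)
}

# Accumulate kernel copies at continuous dot positions (degrees) into a
# pixel field, bilinear-interpolating the oversampled kernel so dot
# placement is sub-pixel accurate.
splat_dots <- function(nrow_px, ncol_px, xs, ys, kern, ppd) {
  field <- matrix(0, nrow_px, ncol_px)
  os <- kern$os; K <- kern$k; c0 <- kern$centre; hw <- kern$half_px
  nk <- nrow(K)
  for (d in seq_along(xs)) {
    cx <- xs[d] * ppd + 0.5 # continuous pixel coords (centres at i - 0.5)
    cy <- ys[d] * ppd + 0.5
    ii <- max(1, ceiling(cx - hw)):min(ncol_px, floor(cx + hw))
    jj <- max(1, ceiling(cy - hw)):min(nrow_px, floor(cy + hw))
    if (!length(ii) || !length(jj)) next
    u <- (ii - cx) * os + c0
    v <- (jj - cy) * os + c0
    iu <- floor(u); fu <- u - iu
    iv <- floor(v); fv <- v - iv
    ok_u <- iu >= 1 & iu < nk
    ok_v <- iv >= 1 & iv < nk
    if (!any(ok_u) || !any(ok_v)) next
    iu <- iu[ok_u]; fu <- fu[ok_u]; ii <- ii[ok_u]
    iv <- iv[ok_v]; fv <- fv[ok_v]; jj <- jj[ok_v]
    patch <- outer(1 - fv, 1 - fu) * K[iv, iu, drop = FALSE] +
      outer(1 - fv, fu) * K[iv, iu + 1L, drop = FALSE] +
      outer(fv, 1 - fu) * K[iv + 1L, iu, drop = FALSE] +
      outer(fv, fu) * K[iv + 1L, iu + 1L, drop = FALSE]
    field[jj, ii] <- field[jj, ii] + patch
  }
  field
}

# Map a zero-mean field to normalised luminance in [0, 1] such that the
# rendered Michelson contrast equals `contrast_pct` exactly: overlapping
# elements sum and are clipped symmetrically at the smaller of the two
# field extremes, so Lmax = (1 + m)/2 and Lmin = (1 - m)/2 are both
# attained.
field_to_luminance <- function(field, contrast_pct) {
  a <- max(field); b <- -min(field)
  m <- contrast_pct / 100
  c0 <- min(a, b)
  if (c0 <= 0) return(matrix(0.5, nrow(field), ncol(field)))
  clipped <- pmin(pmax(field, -c0), c0)
  0.5 + (m / 2) * clipped / c0
}

#' Render a dichoptic random-dot stereogram pair
#'
#' Generates left- and right-eye images in normalised luminance
#' `[0, 1]`. Both eyes share an identical dot layout; dots inside the
#' pie region (disc minus missing sector) are displaced horizontally by
#' half the disparity in each eye, with sub-pixel accurate placement
#' (positive disparity is crossed: the left-eye copy shifts right, the
#' right-eye copy shifts left). Each dot is an isotropic log-Gabor
#' micropattern; per-eye amplitude is calibrated so the rendered
#' Michelson contrast equals the requested value.
#'
#' @param spec an [rds_spec()].
#' @return a list of class `"rds_pair"`: `left`, `right` (matrices),
#'   `pie_mask` (logical matrix of the displaced region), `spec`.
#' @examples
#' pair <- render_rds(rds_spec(disparity = 600, seed = 2,
#'                             disc_diameter = 4, pixels_per_degree = 24))
#' @export
render_rds <- function(spec) {
  stopifnot(inherits(spec, "rds_spec"))
  ppd <- spec$pixels_per_degree
  side_deg <- spec$disc_diameter + 2 * spec$margin
  npx <- round(side_deg * ppd)
  kern <- log_gabor_kernel(spec$element_size, ppd)

  with_seed(spec$seed, {
    n_dots <- round(spec$dot_density * side_deg^2)
    xs <- runif(n_dots, 0, side_deg)
    ys <- runif(n_dots, 0, side_deg)

    cx <- side_deg / 2; cy <- side_deg / 2
    r <- sqrt((xs - cx)^2 + (ys - cy)^2)
    ang <- atan2(cy - ys, xs - cx) * 180 / pi # y up: 90 = up
    sector_centre <- c(90, -90, 180, 0)[spec$sector_position]
    dang <- abs(((ang - sector_centre + 180) %% 360) - 180)
    in_pie <- r <= spec$disc_diameter / 2 & dang > spec$sector_angle / 2

    half_shift <- spec$disparity / 2 / 3600 # degrees
    xl <- ifelse(in_pie, xs + half_shift, xs)
    xr <- ifelse(in_pie, xs - half_shift, xs)

    fl <- splat_dots(npx, npx, xl, ys, kern, ppd)
    fr <- splat_dots(npx, npx, xr, ys, kern, ppd)
    left <- field_to_luminance(fl, spec$contrast_left)
    right <- field_to_luminance(fr, spec$contrast_right)

    px <- (seq_len(npx) - 0.5) / ppd
    rr <- sqrt(outer((px - cy)^2, (px - cx)^2, "+"))
    pang <- atan2(cy - outer(px, rep(1, npx)),
                  outer(rep(1, npx), px) - cx) * 180 / pi
    pdang <- abs(((pang - sector_centre + 180) %% 360) - 180)
    pie_mask <- rr <= spec$disc_diameter / 2 & pdang > spec$sector_angle / 2

    structure(list(left = left, right = right, pie_mask = pie_mask,
                   spec = spec), class = "rds_pair")
  })
}

#' Michelson contrast of a rendered image
#'
#' `(Lmax - Lmin) / (Lmax + Lmin)` over the image.
#'
#' @param image numeric matrix of luminances.
#' @return the Michelson contrast in `[0, 1]`.
#' @export
michelson_contrast <- function(image) {
  (max(image) - min(image)) / (max(image) + min(image))
}

#' Pearson correlation between the two eyes' images
#'
#' Diagnostic for interocular decorrelation: the pixelwise Pearson
#' correlation of luminances, optionally restricted to a window.
#'
#' @param left,right equal-sized luminance matrices.
#' @param rows,cols optional index vectors selecting a window.
#' @return the correlation coefficient; `NA` (with a warning) when either
#'   windowed image is constant.
#' @export
interocular_correlation <- function(left, right, rows = NULL, cols = NULL) {
  if (!all(dim(left) == dim(right))) stop("images must be equal-sized")
  if (!is.null(rows)) { left <- left[rows, , drop = FALSE]; right <- right[rows, , drop = FALSE] }
  if (!is.null(cols)) { left <- left[, cols, drop = FALSE]; right <- right[, cols, drop = FALSE] }
  a <- as.vector(left); b <- as.vector(right)
  if (sd(a) == 0 || sd(b) == 0) {
    warning("correlation undefined: constant image in window")
    return(NA_real_)
  }
  cor(a, b)
}

#' Write a stereogram pair to PNG
#'
#' Writes 8-bit grayscale left and right images plus a side-by-side
#' proof sheet.
#'
#' @param pair an `"rds_pair"` from [render_rds()].
#' @param prefix output path prefix; writes `<prefix>_left.png`,
#'   `<prefix>_right.png`, `<prefix>_pair.png`.
#' @return the three paths, invisibly.
#' @export
write_rds_png <- function(pair, prefix) {
  stopifnot(inherits(pair, "rds_pair"))
  paths <- paste0(prefix, c("_left.png", "_right.png", "_pair.png"))
  png::writePNG(pair$left, paths[1])
  png::writePNG(pair$right, paths[2])
  gap <- matrix(0.5, nrow(pair$left), 8)
  png::writePNG(cbind(pair$left, gap, pair$right), paths[3])
  invisible(paths)
}
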