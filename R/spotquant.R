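# Image-analysis chain: channel registration by 2-D correlation, Gaussian
# smoothing, local-maximum spot seeding, 2D Gaussian + constant background
# fitting, integrated spot intensities, total cell fluorescence and geometry.

#' Register two channels by maximizing 2-D correlation over integer shifts
#'
#' Exhaustively searches integer shifts `(dx, dy)` with `|dx|, |dy| <=
#' max_shift` and returns the shift of `moving` that maximizes the Pearson
#' correlation of the overlapping region with `reference`. Ties are broken by
#' smaller shift magnitude, then lexicographically (dx, then dy).
#'
#' @param reference,moving numeric matrices of identical shape.
#' @param max_shift maximum absolute shift searched, pixels.
#' @return integer vector `c(dx, dy)`: `moving[y, x]` corresponds to
#'   `reference[y + dy, x + dx]`.
#' @export
register_channels <- function(reference, moving, max_shift = 5L) {
  assert_matrix_image(reference, "reference")
  assert_matrix_image(moving, "moving")
  if (!all(dim(reference) == dim(moving))) {
    stop_pf("images must have the same shape", class = "pf_bad_input")
  }
  stopifnot(max_shift >= 0)
  if (sd(reference) == 0 || sd(moving) == 0) {
    stop_pf("degenerate correlation: a constant image cannot be registered",
            class = "pf_degenerate")
  }
  ny <- nrow(reference); nx <- ncol(reference)
  best <- NULL
  for (dy in -max_shift:max_shift) {
    for (dx in -max_shift:max_shift) {
      rx <- max(1, 1 + dx):min(nx, nx + dx)
      ry <- max(1, 1 + dy):min(ny, ny + dy)
      mx <- rx - dx; my <- ry - dy
      a <- reference[ry, rx]; b <- moving[my, mx]
      if (sd(a) == 0 || sd(b) == 0) next
      r <- stats::cor(as.vector(a), as.vector(b))
      key <- c(-r, abs(dx) + abs(dy), dx, dy)
      if (is.null(best) || isTRUE(vector_less(key, best$key))) {
        best <- list(key = key, shift = c(dx = dx, dy = dy))
      }
    }
  }
  if (is.null(best)) {
    stop_pf("degenerate correlation over all overlaps", class = "pf_degenerate")
  }
  best$shift
}

# lexicographic comparison of numeric vectors
vector_less <- function(a, b) {
  for (i in seq_along(a)) {
    if (a[i] < b[i]) return(TRUE)
    if (a[i] > b[i]) return(FALSE)
  }
  FALSE
}

#' Apply the shift found by [register_channels()] to an image
#'
#' Translates `moving` by `(dx, dy)`, filling exposed borders with the image
#' median.
#' @param moving numeric matrix.
#' @param shift integer `c(dx, dy)`.
#' @return shifted matrix of the same shape.
#' @export
apply_shift <- function(moving, shift) {
  assert_matrix_image(moving, "moving")
  dx <- shift[[1]]; dy <- shift[[2]]
  ny <- nrow(moving); nx <- ncol(moving)
  out <- matrix(median(moving), ny, nx)
  rx <- max(1, 1 + dx):min(nx, nx + dx)
  ry <- max(1, 1 + dy):min(ny, ny + dy)
  out[ry, rx] <- moving[ry - dy, rx - dx]
  out
}

# 1D Gaussian kernel truncated at `radius`, normalized to sum 1.
gaussian_kernel <- function(radius, sigma) {
  k <- exp(-((-radius):radius)^2 / (2 * sigma^2))
  k / sum(k)
}

# Separable convolution with reflected (mirror) boundaries.
convolve_separable <- function(image, kernel) {
  r <- (length(kernel) - 1L) / 2L
  pad_reflect <- function(m, r) {
    top <- m[pmin(r:1 + 1, nrow(m)), , drop = FALSE]
    bot <- m[pmax(nrow(m) - (1:r), 1), , drop = FALSE]
    rbind(top, m, bot)
  }
  conv_rows <- function(m) {
    p <- pad_reflect(m, r)
    out <- matrix(0, nrow(m), ncol(m))
    for (j in seq_along(kernel)) {
      out <- out + kernel[j] * p[(j - 1) + seq_len(nrow(m)), , drop = FALSE]
    }
    out
  }
  t(conv_rows(t(conv_rows(image))))
}

#' Gaussian smoothing of a fluorescence image
#'
#' Convolves with an isotropic Gaussian kernel of support `radius` pixels
#' (kernel width `2 * radius + 1`) and standard deviation `sigma`
#' (default `radius / 3`, so the stated radius carries ~3 sigma of the
#' kernel). Boundaries are mirror-reflected, so a constant image is returned
#' unchanged and total intensity is preserved away from the border.
#'
#' @param image numeric matrix.
#' @param radius kernel support radius in pixels (default 5).
#' @param sigma Gaussian standard deviation in pixels.
#' @return smoothed matrix of the same shape.
#' @export
smooth_image <- function(image, radius = 5, sigma = radius / 3) {
  assert_matrix_image(image)
  stopifnot(radius > 0, sigma > 0)
  convolve_separable(image, gaussian_kernel(as.integer(radius), sigma))
}

#' Find candidate spot locations inside one cell
#'
#' Returns pixels inside the cell mask that are strict local maxima of the
#' smoothed image under 8-connectivity, whose prominence above the in-cell
#' background (median of in-mask pixels) is at least `min_prominence`.
#' An empty result is meaningful: cells without spots carry a count of zero.
#'
#' @param smoothed smoothed image from [smooth_image()].
#' @param mask integer label image (0 background).
#' @param cell_id label of the cell to search.
#' @param min_prominence minimum height above the in-cell median;
#'   `NULL` (default) uses `3 * mad(in-cell pixels) + 1e-9`.
#' @return data.frame (x, y, value, prominence), sorted by descending value.
#' @export
find_spot_seeds <- function(smoothed, mask, cell_id, min_prominence = NULL) {
  assert_matrix_image(smoothed)
  idx <- which(mask == cell_id, arr.ind = TRUE)
  if (nrow(idx) == 0) {
    stop_pf("cell_id ", cell_id, " not present in mask", class = "pf_bad_input")
  }
  vals <- smoothed[idx]
  bg <- median(vals)
  if (is.null(min_prominence)) min_prominence <- 3 * mad(vals) + 1e-9
  ny <- nrow(smoothed); nx <- ncol(smoothed)
  is_max <- rep(TRUE, nrow(idx))
  v0 <- smoothed[idx]
  for (ddx in -1:1) {
    for (ddy in -1:1) {
      if (ddx == 0 && ddy == 0) next
      yy <- idx[, 1] + ddy; xx <- idx[, 2] + ddx
      ok <- yy >= 1 & yy <= ny & xx >= 1 & xx <= nx
      nb <- rep(-Inf, nrow(idx))
      nb[ok] <- smoothed[cbind(yy[ok], xx[ok])]
      is_max <- is_max & v0 > nb
    }
  }
  prom <- v0 - bg
  keep <- is_max & prom >= min_prominence
  out <- data.frame(x = idx[keep, 2], y = idx[keep, 1],
                    value = v0[keep], prominence = prom[keep])
  out[order(-out$value), , drop = FALSE]
}

#' Fit a 2D Gaussian with constant background around a seed pixel
#'
#' Nonlinear least squares (Levenberg-Marquardt) of
#' `b + A * exp(-(x - x0)^2 / (2 sx^2) - (y - y0)^2 / (2 sy^2))`
#' over a square window centred on the seed. The spot intensity is the
#' background-free integral of the fitted Gaussian, `2 * pi * A * sx * sy`.
#' Fits are rejected (with a recorded reason) when the optimizer fails, the
#' centre escapes the window by more than 2 px, the widths collapse or
#' explode, or the amplitude is indistinguishable from the residual noise.
#'
#' @param image raw (unsmoothed) numeric matrix.
#' @param seed_xy numeric `c(x, y)` seed pixel.
#' @param window half-width of the fit window, pixels (default 7).
#' @param psf_sigma initial width guess, pixels.
#' @param amp_snr_min minimum fitted amplitude in units of the residual
#'   standard deviation for acceptance.
#' @return one-row data.frame (x, y, sigma_x, sigma_y, amplitude, background,
#'   integral, rss, status, reason); `status == "ok"` for accepted fits.
#' @export
fit_spot <- function(image, seed_xy, window = 7L, psf_sigma = 1.5,
                     amp_snr_min = 3) {
  assert_matrix_image(image)
  x0 <- seed_xy[[1]]; y0 <- seed_xy[[2]]
  xs <- max(1L, round(x0) - window):min(ncol(image), round(x0) + window)
  ys <- max(1L, round(y0) - window):min(nrow(image), round(y0) + window)
  if (length(xs) * length(ys) < 10) {
    stop_pf("fit window has fewer than 10 pixels", class = "pf_bad_input")
  }
  z <- image[ys, xs]
  gx <- matrix(xs, length(ys), length(xs), byrow = TRUE)
  gy <- matrix(ys, length(ys), length(xs))
  b0 <- median(z)
  a0 <- max(image[round(y0), round(x0)] - b0, max(z) - b0, 1e-6)
  par0 <- c(b = b0, A = a0, x0 = x0, y0 = y0, sx = psf_sigma, sy = psf_sigma)
  resid_fun <- function(p) {
    as.vector(z - (p[1] + p[2] * exp(-(gx - p[3])^2 / (2 * p[5]^2) -
                                       (gy - p[4])^2 / (2 * p[6]^2))))
  }
  reject <- function(reason) {
    data.frame(x = NA_real_, y = NA_real_, sigma_x = NA_real_,
               sigma_y = NA_real_, amplitude = NA_real_,
               background = NA_real_, integral = NA_real_, rss = NA_real_,
               status = "rejected", reason = reason)
  }
  fit <- tryCatch(
    minpack.lm::nls.lm(par = par0, fn = resid_fun,
                       lower = c(-Inf, 0, min(xs) - 2, min(ys) - 2, 0.3, 0.3),
                       upper = c(Inf, Inf, max(xs) + 2, max(ys) + 2,
                                 2 * window, 2 * window),
                       control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit) || fit$info %in% c(0, 9)) return(reject("no convergence"))
  p <- fit$par
  res <- resid_fun(p)
  if (p[3] < min(xs) - 2 || p[3] > max(xs) + 2 ||
      p[4] < min(ys) - 2 || p[4] > max(ys) + 2) {
    return(reject("centre escaped window"))
  }
  if (p[5] <= 0.3 + 1e-9 || p[6] <= 0.3 + 1e-9 ||
      p[5] >= 2 * window - 1e-9 || p[6] >= 2 * window - 1e-9) {
    return(reject("degenerate width"))
  }
  noise_sd <- sd(res)
  if (p[2] <= amp_snr_min * noise_sd || p[2] < 1e-9 * max(abs(z), 1)) {
    return(reject("amplitude indistinguishable from background"))
  }
  data.frame(x = p[3], y = p[4], sigma_x = p[5], sigma_y = p[6],
             amplitude = p[2], background = p[1],
             integral = 2 * pi * p[2] * p[5] * p[6],
             rss = sum(res^2), status = "ok", reason = "")
}

# Minor-axis extent of a mask label in pixels: span of pixel-centre
# projections on the second principal axis plus one pixel footprint.
mask_minor_extent <- function(mask, cell_id) {
  idx <- which(mask == cell_id, arr.ind = TRUE)
  if (nrow(idx) == 1) return(1)
  xy <- cbind(idx[, 2], idx[, 1])
  ctr <- sweep(xy, 2, colMeans(xy))
  ev <- eigen(stats::cov(ctr), symmetric = TRUE)$vectors
  proj <- ctr %*% ev[, 2]
  diff(range(proj)) + 1
}

# Same for the major axis.
mask_major_extent <- function(mask, cell_id) {
  idx <- which(mask == cell_id, arr.ind = TRUE)
  if (nrow(idx) == 1) return(1)
  xy <- cbind(idx[, 2], idx[, 1])
  ctr <- sweep(xy, 2, colMeans(xy))
  ev <- eigen(stats::cov(ctr), symmetric = TRUE)$vectors
  proj <- ctr %*% ev[, 1]
  diff(range(proj)) + 1
}

# Drop fits whose centres are closer than 1 combined sigma, keeping the
# larger integral.
dedupe_spots <- function(fits) {
  if (nrow(fits) <= 1) return(fits)
  ord <- order(-fits$integral)
  fits <- fits[ord, , drop = FALSE]
  keep <- rep(TRUE, nrow(fits))
  for (i in seq_len(nrow(fits))) {
    if (!keep[i]) next
    for (j in seq_len(nrow(fits))) {
      if (j <= i || !keep[j]) next
      d <- sqrt((fits$x[i] - fits$x[j])^2 + (fits$y[i] - fits$y[j])^2)
      s <- mean(c(fits$sigma_x[i], fits$sigma_y[i],
                  fits$sigma_x[j], fits$sigma_y[j]))
      if (d < s) keep[j] <- FALSE
    }
  }
  fits[keep, , drop = FALSE]
}

#' Quantify one cell across channels
#'
#' Runs the full chain for a single cell: smooth each registered channel,
#' seed spots inside the mask, fit each seed with [fit_spot()] on the raw
#' image, deduplicate fits closer than one PSF width (larger integral wins),
#' and assemble geometry (area; width = minor-axis extent of the mask;
#' volume = area in um^2 times width in um) and per-channel totals (sum of
#' in-mask pixels).
#'
#' @param images named list of registered channel matrices.
#' @param mask integer label image.
#' @param cell_id cell label to quantify.
#' @param pixel_size micrometres per pixel.
#' @param smooth_radius,smooth_sigma smoothing parameters, see
#'   [smooth_image()].
#' @param window fit window half-width, pixels.
#' @param min_prominence seeding threshold, see [find_spot_seeds()].
#' @param psf_sigma initial PSF width for fits.
#' @param smoothed optional named list of pre-smoothed channels (computed
#'   once per image by [quantify_cells()]).
#' @return list with `cell` (one-row data.frame: cell_id, area_px, area_um2,
#'   width_um, length_um, volume_um3, total_<channel>...) and `spots`
#'   (data.frame of accepted SpotFits with cell_id and channel columns) and
#'   `rejected` (fit rejections with reasons).
#' @export
quantify_cell <- function(images, mask, cell_id, pixel_size = 0.1,
                          smooth_radius = 5, smooth_sigma = smooth_radius / 3,
                          window = 7L, min_prominence = NULL, psf_sigma = 1.5,
                          smoothed = NULL) {
  stopifnot(is.list(images), length(images) >= 1, !is.null(names(images)))
  if (!any(mask == cell_id)) {
    stop_pf("cell_id ", cell_id, " not present in mask", class = "pf_bad_input")
  }
  area_px <- sum(mask == cell_id)
  area_um2 <- area_px * pixel_size^2
  width_um <- mask_minor_extent(mask, cell_id) * pixel_size
  length_um <- mask_major_extent(mask, cell_id) * pixel_size
  cell <- data.frame(cell_id = cell_id, area_px = area_px,
                     area_um2 = area_um2, width_um = width_um,
                     length_um = length_um,
                     volume_um3 = area_um2 * width_um)
  spots <- list(); rejected <- list()
  for (ch in names(images)) {
    img <- images[[ch]]
    cell[[paste0("total_", ch)]] <- sum(img[mask == cell_id])
    sm <- if (!is.null(smoothed)) smoothed[[ch]] else {
      smooth_image(img, radius = smooth_radius, sigma = smooth_sigma)
    }
    seeds <- find_spot_seeds(sm, mask, cell_id, min_prominence)
    if (nrow(seeds) == 0) next
    fits <- do.call(rbind, lapply(seq_len(nrow(seeds)), function(i) {
      fit_spot(img, c(seeds$x[i], seeds$y[i]), window = window,
               psf_sigma = psf_sigma)
    }))
    ok <- fits[fits$status == "ok", , drop = FALSE]
    bad <- fits[fits$status != "ok", , drop = FALSE]
    if (nrow(ok) > 0) {
      ok <- dedupe_spots(ok)
      ok$cell_id <- cell_id; ok$channel <- ch
      spots[[ch]] <- ok
    }
    if (nrow(bad) > 0) {
      bad$cell_id <- cell_id; bad$channel <- ch
      rejected[[ch]] <- bad
    }
  }
  empty <- data.frame(x = double(), y = double(), sigma_x = double(),
                      sigma_y = double(), amplitude = double(),
                      background = double(), integral = double(),
                      rss = double(), status = character(),
                      reason = character(), cell_id = integer(),
                      channel = character())
  list(cell = cell,
       spots = if (length(spots)) do.call(rbind, spots) else empty,
       rejected = if (length(rejected)) do.call(rbind, rejected) else empty)
}

#' Quantify every cell in a labelled image set
#'
#' Smooths each channel once, then applies [quantify_cell()] to every label
#' in the mask.
#'
#' @inheritParams quantify_cell
#' @return list with `cells` (one row per cell) and `spots` / `rejected`
#'   (per-spot tables across cells).
#' @export
quantify_cells <- function(images, mask, pixel_size = 0.1, smooth_radius = 5,
                           smooth_sigma = smooth_radius / 3, window = 7L,
                           min_prominence = NULL, psf_sigma = 1.5) {
  labels <- sort(setdiff(unique(as.vector(mask)), 0L))
  smoothed <- lapply(images, smooth_image, radius = smooth_radius,
                     sigma = smooth_sigma)
  res <- lapply(labels, function(cid) {
    quantify_cell(images, mask, cid, pixel_size = pixel_size,
                  smooth_radius = smooth_radius, smooth_sigma = smooth_sigma,
                  window = window, min_prominence = min_prominence,
                  psf_sigma = psf_sigma, smoothed = smoothed)
  })
  list(cells = do.call(rbind, lapply(res, `[[`, "cell")),
       spots = do.call(rbind, lapply(res, `[[`, "spots")),
       rejected = do.call(rbind, lapply(res, `[[`, "rejected")))
}

#' Fallback threshold segmentation (plumbing only, not validated)
#'
#' A minimal Otsu-threshold plus 4-connected-components labeller for use when
#' no segmentation masks are available. This is plumbing for exploratory
#' runs; quantitative results should use masks from a dedicated segmentation
#' tool.
#'
#' @param image numeric matrix (e.g. a constitutive-reporter channel).
#' @param min_area discard components smaller than this many pixels.
#' @return integer label matrix.
#' @export
segment_threshold <- function(image, min_area = 20L) {
  assert_matrix_image(image)
  # Otsu threshold on a 256-bin histogram
  v <- as.vector(image)
  rng <- range(v)
  if (diff(rng) == 0) return(matrix(0L, nrow(image), ncol(image)))
  h <- tabulate(findInterval(v, seq(rng[1], rng[2], length.out = 257),
                             rightmost.closed = TRUE), nbins = 256)
  p <- h / sum(h)
  omega <- cumsum(p)
  mu <- cumsum(p * seq_len(256))
  mu_t <- mu[256]
  sigma_b <- (mu_t * omega - mu)^2 / (omega * (1 - omega))
  sigma_b[!is.finite(sigma_b)] <- 0
  k <- which.max(sigma_b)
  thr <- rng[1] + diff(rng) * k / 256
  fg <- image > thr
  # 4-connected components by flood fill
  lab <- matrix(0L, nrow(image), ncol(image))
  nextlab <- 0L
  ny <- nrow(image); nx <- ncol(image)
  for (start in which(fg & lab == 0L)) {
    nextlab <- nextlab + 1L
    stack <- start
    while (length(stack)) {
      i <- stack[length(stack)]; stack <- stack[-length(stack)]
      if (!fg[i] || lab[i] != 0L) next
      lab[i] <- nextlab
      r <- (i - 1L) %% ny + 1L; cc <- (i - 1L) %/% ny + 1L
      if (r > 1) stack <- c(stack, i - 1L)
      if (r < ny) stack <- c(stack, i + 1L)
      if (cc > 1) stack <- c(stack, i - ny)
      if (cc < nx) stack <- c(stack, i + ny)
    }
  }
  sizes <- tabulate(lab, nbins = nextlab)
  relab <- integer(nextlab)
  relab[sizes >= min_area] <- seq_len(sum(sizes >= min_area))
  lab[lab > 0L] <- relab[lab[lab > 0L]]
  lab
}
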