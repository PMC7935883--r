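# Seeded synthetic-data generator: label masks, rendered fluorescence
# channels, joint (plasmid, mRNA) population tables and rifampicin-style
# decay time courses, all with exact ground truth.

#' Camera and optics model for synthetic channel rendering
#'
#' @param unit_intensity integrated photon count contributed by a single
#'   labelled molecule. Default 1000 photons.
#' @param psf_sigma standard deviation of the isotropic 2D Gaussian point
#'   spread function, in pixels. Default 1.5 px, roughly diffraction limited
#'   for a 100x objective at ~0.1 um/px sampling.
#' @param background constant background level, photons per pixel.
#' @param shot_noise apply Poisson shot noise to photon counts?
#' @param read_noise_sd additive Gaussian read noise, photons (0 disables).
#' @return an object of class `noise_model`.
#' @export
noise_model <- function(unit_intensity = 1000, psf_sigma = 1.5,
                        background = 50, shot_noise = TRUE,
                        read_noise_sd = 2) {
  stopifnot(unit_intensity > 0, psf_sigma > 0, background >= 0,
            read_noise_sd >= 0)
  structure(list(unit_intensity = unit_intensity, psf_sigma = psf_sigma,
                 background = background, shot_noise = isTRUE(shot_noise),
                 read_noise_sd = read_noise_sd),
            class = "noise_model")
}

# Rasterize one capsule (rectangle with semicircular caps) or rectangle into
# logical in-cell values over a local bounding box. Returns integer pixel
# index pairs (x = col, y = row).
rasterize_cell <- function(cx, cy, length_px, width_px, theta, shape, dim_yx) {
  half_w <- width_px / 2
  half_seg <- if (shape == "capsule") max(length_px / 2 - half_w, 0) else length_px / 2
  reach <- length_px / 2 + 1
  xs <- max(1L, floor(cx - reach)):min(dim_yx[2], ceiling(cx + reach))
  ys <- max(1L, floor(cy - reach)):min(dim_yx[1], ceiling(cy + reach))
  g <- expand.grid(x = xs, y = ys)
  # rotate into the cell frame
  dx <- (g$x - cx) * cos(theta) + (g$y - cy) * sin(theta)
  dy <- -(g$x - cx) * sin(theta) + (g$y - cy) * cos(theta)
  inside <- if (shape == "capsule") {
    ax <- pmax(abs(dx) - half_seg, 0)
    ax^2 + dy^2 <= half_w^2
  } else {
    abs(dx) <= length_px / 2 - 0.5 + 1e-9 & abs(dy) <= half_w - 0.5 + 1e-9
  }
  g[inside, , drop = FALSE]
}

#' Generate non-overlapping rod-shaped cell masks
#'
#' Places `n_cells` rod-shaped cells (capsules, optionally near-rectangles)
#' at random positions and small random orientations in an image, rejecting
#' placements that touch an existing cell. Deterministic given `seed`.
#'
#' @param n_cells number of cells to place (>= 0).
#' @param image_shape integer `c(n_rows, n_cols)` of the label image.
#' @param length_um,width_um two-element ranges (min, max) for cell length
#'   and width in micrometres. A single value is treated as a fixed size.
#' @param pixel_size micrometres per pixel.
#' @param rotation_sd standard deviation of the random orientation (radians)
#'   about the horizontal axis; 0 gives axis-aligned cells.
#' @param shape `"capsule"` (default) or `"rectangle"`.
#' @param seed integer seed; same seed gives identical output.
#' @param max_attempts placement attempts before giving up.
#' @return list with `mask` (integer label matrix, 0 = background, k = cell k)
#'   and `cells` (data.frame: cell_id, centre, orientation, drawn length and
#'   width in um, area in px and um^2, volume_um3 = area_um2 * width_um).
#' @export
make_cell_masks <- function(n_cells, image_shape = c(256L, 256L),
                            length_um = c(2.5, 4), width_um = c(0.8, 1.1),
                            pixel_size = 0.1, rotation_sd = 0.15,
                            shape = c("capsule", "rectangle"),
                            seed = NULL, max_attempts = 200L * max(n_cells, 1L)) {
  shape <- match.arg(shape)
  stopifnot(n_cells >= 0, pixel_size > 0, all(length_um > 0), all(width_um > 0))
  if (length(length_um) == 1) length_um <- rep(length_um, 2)
  if (length(width_um) == 1) width_um <- rep(width_um, 2)
  mask <- matrix(0L, nrow = image_shape[1], ncol = image_shape[2])
  cells <- data.frame(cell_id = integer(), x = double(), y = double(),
                      theta = double(), length_um = double(),
                      width_um = double(), area_px = integer(),
                      area_um2 = double(), volume_um3 = double())
  if (n_cells == 0) return(list(mask = mask, cells = cells))

  with_seed(seed, {
    placed <- 0L
    attempts <- 0L
    while (placed < n_cells) {
      attempts <- attempts + 1L
      if (attempts > max_attempts) {
        stop_pf("could not place ", n_cells, " non-overlapping cells in a ",
                image_shape[1], "x", image_shape[2], " image after ",
                max_attempts, " attempts; enlarge the image or reduce n_cells",
                class = "pf_placement_failure")
      }
      L <- runif(1, length_um[1], length_um[2]) / pixel_size
      W <- runif(1, width_um[1], width_um[2]) / pixel_size
      theta <- if (rotation_sd > 0) rnorm(1, 0, rotation_sd) else 0
      margin <- L / 2 + 2
      if (2 * margin >= min(image_shape)) {
        stop_pf("cells of length ", round(L), " px cannot fit in the image",
                class = "pf_placement_failure")
      }
      cx <- runif(1, margin, image_shape[2] - margin)
      cy <- runif(1, margin, image_shape[1] - margin)
      if (shape == "rectangle" && theta == 0) {
        # snap the centre so an axis-aligned L x W rectangle covers exactly
        # round(L) x round(W) pixel centres
        L <- round(L); W <- round(W)
        cx <- floor(cx) + if (L %% 2 == 0) 0.5 else 0
        cy <- floor(cy) + if (W %% 2 == 0) 0.5 else 0
      }
      px <- rasterize_cell(cx, cy, L, W, theta, shape, image_shape)
      if (nrow(px) < 8) next
      idx <- cbind(px$y, px$x)
      # 1-px clearance: reject if any pixel or 8-neighbour is occupied
      clear <- TRUE
      for (ddx in -1:1) {
        for (ddy in -1:1) {
          ny <- pmin(pmax(px$y + ddy, 1L), image_shape[1])
          nx <- pmin(pmax(px$x + ddx, 1L), image_shape[2])
          if (any(mask[cbind(ny, nx)] != 0L)) { clear <- FALSE; break }
        }
        if (!clear) break
      }
      if (!clear) next
      placed <- placed + 1L
      mask[idx] <- placed
      area_um2 <- nrow(px) * pixel_size^2
      w_um <- W * pixel_size
      cells <- rbind(cells, data.frame(
        cell_id = placed, x = cx, y = cy, theta = theta,
        length_um = L * pixel_size, width_um = w_um,
        area_px = nrow(px), area_um2 = area_um2,
        volume_um3 = area_um2 * w_um))
    }
  })
  list(mask = mask, cells = cells)
}

# Pixels of a mask label whose full 8-neighbourhood is inside the same label
# (1-px erosion), as a data.frame (x, y).
eroded_pixels <- function(mask, cell_id) {
  idx <- which(mask == cell_id, arr.ind = TRUE)
  if (nrow(idx) == 0) return(data.frame(x = integer(), y = integer()))
  keep <- rep(TRUE, nrow(idx))
  ny <- nrow(mask); nx <- ncol(mask)
  for (ddx in -1:1) {
    for (ddy in -1:1) {
      yy <- idx[, 1] + ddy
      xx <- idx[, 2] + ddx
      ok <- yy >= 1 & yy <= ny & xx >= 1 & xx <= nx
      inlab <- ok
      inlab[ok] <- mask[cbind(yy[ok], xx[ok])] == cell_id
      keep <- keep & inlab
    }
  }
  data.frame(x = idx[keep, 2], y = idx[keep, 1])
}

#' Assign molecules to diffraction-limited spots within cells
#'
#' Distributes each cell's true molecule count over one or more spots
#' (clusters), placing spot centres uniformly over the 1-px-eroded cell mask
#' with subpixel jitter and a soft minimum pairwise separation. The sum of
#' spot multiplicities in a cell always equals the cell's count.
#'
#' @param mask label image from [make_cell_masks()].
#' @param counts integer vector of true molecule counts, one per cell label
#'   `1..length(counts)`.
#' @param channel channel name recorded with each spot.
#' @param mode `"clusters"` groups molecules into up to `max_spots` spots
#'   (brighter spots = more molecules in a cluster); `"singles"` gives every
#'   molecule its own spot.
#' @param max_spots maximum spots per cell in cluster mode.
#' @param min_separation preferred minimum centre separation, pixels.
#' @param seed integer seed.
#' @return data.frame (cell_id, channel, x, y, multiplicity).
#' @export
assign_spots <- function(mask, counts, channel = "ch1",
                         mode = c("clusters", "singles"), max_spots = 4L,
                         min_separation = 5, seed = NULL) {
  mode <- match.arg(mode)
  stopifnot(all(counts >= 0))
  with_seed(seed, {
    out <- vector("list", length(counts))
    for (cid in seq_along(counts)) {
      n <- counts[cid]
      if (n == 0) next
      er <- eroded_pixels(mask, cid)
      if (nrow(er) == 0) {
        stop_pf("cell ", cid, " too thin to hold an interior spot",
                class = "pf_bad_input")
      }
      if (mode == "singles") {
        mult <- rep(1L, n)
      } else {
        n_spots <- min(n, sample.int(max_spots, 1))
        assign_to <- sample.int(n_spots, n, replace = TRUE)
        mult <- as.integer(table(factor(assign_to, levels = seq_len(n_spots))))
        mult <- mult[mult > 0]
      }
      k <- length(mult)
      # sample centres with a soft minimum separation
      pos <- matrix(NA_real_, k, 2)
      for (j in seq_len(k)) {
        best <- NULL
        for (try in 1:30) {
          i <- sample.int(nrow(er), 1)
          cand <- c(er$x[i] + runif(1, -0.3, 0.3), er$y[i] + runif(1, -0.3, 0.3))
          if (j == 1) { best <- cand; break }
          d <- sqrt(rowSums((pos[seq_len(j - 1), , drop = FALSE] -
                               matrix(cand, j - 1, 2, byrow = TRUE))^2))
          if (all(d >= min_separation)) { best <- cand; break }
          if (is.null(best)) best <- cand
        }
        pos[j, ] <- best
      }
      out[[cid]] <- data.frame(cell_id = cid, channel = channel,
                               x = pos[, 1], y = pos[, 2],
                               multiplicity = as.integer(mult))
    }
    res <- do.call(rbind, out)
    if (is.null(res)) {
      res <- data.frame(cell_id = integer(), channel = character(),
                        x = double(), y = double(), multiplicity = integer())
    }
    rownames(res) <- NULL
    res
  })
}

#' Render a fluorescence channel from ground-truth spots
#'
#' Each spot contributes an isotropic 2D Gaussian sampled at pixel centres
#' with total integrated photon count `multiplicity * unit_intensity`, on a
#' constant background. Poisson shot noise and Gaussian read noise are
#' applied if enabled in the noise model. With all noise off, the
#' background-subtracted image sums to the total molecule photon budget
#' within discretization error.
#'
#' @param image_shape `c(n_rows, n_cols)`.
#' @param spots data.frame from [assign_spots()] (needs x, y, multiplicity).
#' @param noise a [noise_model()].
#' @param seed integer seed (only noise draws consume randomness).
#' @return numeric matrix of pixel intensities (photons).
#' @export
render_channel <- function(image_shape, spots, noise = noise_model(),
                           seed = NULL) {
  stopifnot(inherits(noise, "noise_model"))
  img <- matrix(noise$background, nrow = image_shape[1], ncol = image_shape[2])
  if (nrow(spots) > 0) {
    if (any(spots$multiplicity < 1)) {
      stop_pf("spot multiplicities must be >= 1", class = "pf_bad_input")
    }
    if (any(spots$x < 1 | spots$x > image_shape[2] |
            spots$y < 1 | spots$y > image_shape[1])) {
      stop_pf("spot centre outside image bounds", class = "pf_bad_input")
    }
    s <- noise$psf_sigma
    r <- ceiling(6 * s)
    for (i in seq_len(nrow(spots))) {
      x0 <- spots$x[i]; y0 <- spots$y[i]
      amp <- spots$multiplicity[i] * noise$unit_intensity / (2 * pi * s^2)
      xs <- max(1L, floor(x0 - r)):min(image_shape[2], ceiling(x0 + r))
      ys <- max(1L, floor(y0 - r)):min(image_shape[1], ceiling(y0 + r))
      gx <- exp(-(xs - x0)^2 / (2 * s^2))
      gy <- exp(-(ys - y0)^2 / (2 * s^2))
      img[ys, xs] <- img[ys, xs] + amp * outer(gy, gx)
    }
  }
  with_seed(seed, {
    if (noise$shot_noise) {
      img[] <- rpois(length(img), lambda = pmax(img, 0))
    }
    if (noise$read_noise_sd > 0) {
      img[] <- img + rnorm(length(img), 0, noise$read_noise_sd)
    }
    img
  })
}

# Normalise the many accepted plasmid-distribution specs to a sampler.
plasmid_sampler <- function(spec) {
  if (is.numeric(spec) && length(spec) == 1) {
    value <- as.integer(spec)
    return(function(n) rep(value, n))
  }
  if (is.numeric(spec)) {
    pool <- as.integer(spec)
    return(function(n) sample(pool, n, replace = TRUE))
  }
  if (is.list(spec) && !is.null(spec$kind)) {
    switch(spec$kind,
      point = function(n) rep(as.integer(spec$value), n),
      poisson = function(n) rpois(n, spec$mean),
      empirical = function(n) sample(as.integer(spec$counts), n, replace = TRUE),
      sim = function(n) {
        sim <- simulate_plasmid_population(
          N0 = spec$N0, a = spec$a %||% 1, K = spec$K %||% 5,
          pop_size = max(n, 2000L), generations = spec$generations %||% 20,
          seed = NULL)
        sample(sim$counts, n, replace = TRUE)
      },
      stop_pf("unknown plasmid distribution kind: ", spec$kind,
              class = "pf_bad_input")
    )
  } else {
    stop_pf("invalid plasmid distribution spec", class = "pf_bad_input")
  }
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Simulate a joint per-cell (plasmid, mRNA) population table
#'
#' Draws a plasmid copy number N per cell from the given distribution, then
#' an mRNA count m conditioned on N from the plasmid-borne promoter. Cells
#' with N = 0 always get m = 0. By default m | N is Poisson with mean
#' `mrna_per_plasmid * N`, with a fraction `zero_activity_prob` of
#' plasmid-bearing cells transcriptionally silent (m = 0), emulating the
#' zero-activity subpopulation seen in single-cell promoter measurements.
#' `mrna_model = "telegraph"` instead draws m from the stationary two-state
#' promoter model with per-copy transcription rate scaled by N.
#'
#' @param n_cells number of cells.
#' @param plasmid_dist a single number (point mass), a numeric vector
#'   (resampled empirically), or a list such as `list(kind = "poisson",
#'   mean = 9)`, `list(kind = "sim", N0 = 9, a = 1, K = 5)`.
#' @param mrna_per_plasmid mean mRNA per plasmid copy at steady state.
#' @param zero_activity_prob probability a plasmid-bearing cell is silent.
#' @param mrna_model `"poisson"` or `"telegraph"`.
#' @param telegraph list of rates for the telegraph option
#'   (`k_on`, `k_off`, `tau` in 1/s); `k_tx` per copy is derived so the
#'   stationary mean stays `mrna_per_plasmid * N`.
#' @param seed integer seed.
#' @return data.frame (cell_id, N, m).
#' @export
simulate_population_table <- function(n_cells, plasmid_dist = list(kind = "sim", N0 = 9),
                                      mrna_per_plasmid = 11.2,
                                      zero_activity_prob = 0.05,
                                      mrna_model = c("poisson", "telegraph"),
                                      telegraph = list(k_on = 0.02, k_off = 0.002,
                                                       tau = log(2) / 408),
                                      seed = NULL) {
  mrna_model <- match.arg(mrna_model)
  stopifnot(n_cells >= 1, mrna_per_plasmid >= 0,
            zero_activity_prob >= 0, zero_activity_prob <= 1)
  with_seed(seed, {
    N <- plasmid_sampler(plasmid_dist)(n_cells)
    m <- integer(n_cells)
    active <- runif(n_cells) >= zero_activity_prob
    pos <- which(N >= 1 & active)
    if (length(pos) > 0) {
      if (mrna_model == "poisson") {
        m[pos] <- rpois(length(pos), mrna_per_plasmid * N[pos])
      } else {
        f_on <- telegraph$k_on / (telegraph$k_on + telegraph$k_off)
        for (i in pos) {
          k_tx <- mrna_per_plasmid * N[i] * telegraph$tau / f_on
          m[i] <- telegraph_mrna(k_on = telegraph$k_on, k_off = telegraph$k_off,
                                 k_tx = k_tx, tau = telegraph$tau,
                                 n_cells = 1, seed = NULL)
        }
      }
    }
    data.frame(cell_id = seq_len(n_cells), N = as.integer(N), m = as.integer(m))
  })
}

#' Simulate a transcription-arrest (rifampicin) decay time course
#'
#' Per-cell transcript counts at each time point are Poisson with mean
#' `initial_mean * 2^(-t / half_life)`, the single-exponential decay expected
#' after transcription initiation is blocked.
#'
#' @param initial_mean mean transcript count per cell at t = 0.
#' @param half_life mRNA half-life in minutes.
#' @param timepoints sampling times in minutes after the arrest.
#' @param n_cells cells measured per time point.
#' @param seed integer seed.
#' @return data.frame (time_min, cell, count).
#' @export
simulate_decay_series <- function(initial_mean, half_life,
                                  timepoints = c(0, 4, 10, 20, 60),
                                  n_cells = 500, seed = NULL) {
  stopifnot(half_life > 0, all(timepoints >= 0), initial_mean >= 0, n_cells >= 1)
  with_seed(seed, {
    do.call(rbind, lapply(timepoints, function(t) {
      mu <- initial_mean * 2^(-t / half_life)
      data.frame(time_min = t, cell = seq_len(n_cells),
                 count = rpois(n_cells, mu))
    }))
  })
}
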