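# Image-analysis chain: registration, smoothing, seeding, Gaussian fitting,
# cell quantification.

test_that("registration recovers known integer shifts", {
  set.seed(1)
  ref <- matrix(runif(60 * 60), 60, 60)
  expect_equal(register_channels(ref, ref), c(dx = 0L, dy = 0L))
  # property: random shifts up to max_shift are recovered exactly
  for (case in 1:5) {
    dx <- sample(-4:4, 1); dy <- sample(-4:4, 1)
    moving <- matrix(median(ref), 60, 60)
    rx <- max(1, 1 - dx):min(60, 60 - dx)
    ry <- max(1, 1 - dy):min(60, 60 - dy)
    moving[ry, rx] <- ref[ry + dy, rx + dx]
    expect_equal(register_channels(ref, moving, max_shift = 5),
                 c(dx = dx, dy = dy))
    expect_equal(apply_shift(moving, c(dx, dy))[ry + dy, rx + dx],
                 ref[ry + dy, rx + dx])
  }
  expect_error(register_channels(matrix(1, 10, 10), matrix(1, 10, 10)),
               "degenerate")
})

test_that("smoothing preserves constants, mass and reduces variance", {
  flat <- matrix(3.7, 30, 30)
  expect_equal(smooth_image(flat), flat)
  # delta impulse: the response sums to the input mass
  delta <- matrix(0, 41, 41); delta[21, 21] <- 5
  expect_equal(sum(smooth_image(delta)), 5, tolerance = 1e-6)
  set.seed(2)
  noise <- matrix(rnorm(80 * 80), 80, 80)
  sm <- smooth_image(noise)
  expect_lt(var(as.vector(sm)), var(as.vector(noise)))
  expect_lt(abs(mean(sm) - mean(noise)), 1e-3 * sd(noise))
})

test_that("seeding finds rendered spots and nothing on flat cells", {
  mk <- make_cell_masks(1, c(64, 64), length_um = 3, width_um = 1,
                        rotation_sd = 0, seed = 5)
  nm0 <- noise_model(shot_noise = FALSE, read_noise_sd = 0)
  # flat interior
  img_flat <- render_channel(c(64, 64), data.frame(x = double(),
                                                   y = double(),
                                                   multiplicity = integer()),
                             nm0)
  seeds <- find_spot_seeds(smooth_image(img_flat), mk$mask, 1)
  expect_equal(nrow(seeds), 0L)
  # one spot: exactly one seed at the brightest smoothed pixel
  ctr <- round(c(mk$cells$x, mk$cells$y))
  sp <- data.frame(x = ctr[1], y = ctr[2], multiplicity = 1L)
  img1 <- render_channel(c(64, 64), sp, nm0)
  sm1 <- smooth_image(img1)
  s1 <- find_spot_seeds(sm1, mk$mask, 1)
  expect_equal(nrow(s1), 1L)
  expect_equal(c(s1$x, s1$y), ctr)
  # two equal spots 10 px apart -> two seeds
  sp2 <- data.frame(x = ctr[1] + c(-5, 5), y = ctr[2], multiplicity = 1L)
  s2 <- find_spot_seeds(smooth_image(render_channel(c(64, 64), sp2, nm0)),
                        mk$mask, 1)
  expect_equal(nrow(s2), 2L)
  expect_error(find_spot_seeds(sm1, mk$mask, 99), "not present")
})

test_that("spot fitting matches the closed-form Gaussian integral", {
  img <- render_single_spot(total = 2 * pi * 100 * 2 * 2, x0 = 16.4,
                            y0 = 15.7, sigma = 2, bg = 10)
  f <- fit_spot(img, c(16, 16), window = 7, psf_sigma = 2)
  expect_equal(f$status, "ok")
  expect_equal(f$integral, 2 * pi * 100 * 2 * 2, tolerance = 1e-3)
  expect_equal(c(f$x, f$y), c(16.4, 15.7), tolerance = 1e-3)
  # model identity holds to machine precision for every accepted fit
  expect_lt(abs(f$integral - 2 * pi * f$amplitude * f$sigma_x * f$sigma_y),
            1e-9 * f$integral)
  # flat background: amplitude indistinguishable from zero -> rejection
  set.seed(3)
  flat <- matrix(100 + rnorm(31 * 31, 0, 3), 31, 31)
  fr <- fit_spot(flat, c(16, 16))
  expect_equal(fr$status, "rejected")
})

test_that("fitted integrals increase with true multiplicity (noise-free)", {
  nm0 <- noise_model(shot_noise = FALSE, read_noise_sd = 0)
  ints <- vapply(1:5, function(mult) {
    img <- render_channel(c(31, 31), data.frame(x = 16, y = 16,
                                                multiplicity = mult), nm0)
    fit_spot(img, c(16, 16))$integral
  }, numeric(1))
  expect_true(all(diff(ints) > 0))
  expect_equal(ints, 1000 * (1:5), tolerance = 1e-3)
})

test_that("quantify_cell recovers spots, totals and geometry", {
  mk <- make_cell_masks(1, c(80, 80), length_um = 3.5, width_um = 1,
                        rotation_sd = 0, seed = 8)
  nm <- noise_model()   # realistic noise
  sp <- assign_spots(mk$mask, 3L, channel = "plasmid", mode = "singles",
                     seed = 9)
  img <- render_channel(c(80, 80), sp, nm, seed = 10)
  rec <- quantify_cell(list(plasmid = img), mk$mask, 1)
  expect_equal(nrow(rec$spots), 3L)
  expect_equal(sum(rec$spots$integral), 3 * 1000, tolerance = 0.1)
  expect_equal(rec$cell$volume_um3,
               rec$cell$area_um2 * rec$cell$width_um)

  # empty cell: no spots, total close to background * area
  img0 <- render_channel(c(80, 80),
                         data.frame(x = double(), y = double(),
                                    multiplicity = integer()),
                         nm, seed = 11)
  rec0 <- quantify_cell(list(plasmid = img0), mk$mask, 1)
  expect_equal(nrow(rec0$spots), 0L)
  expect_equal(rec0$cell$total_plasmid, 50 * rec0$cell$area_px,
               tolerance = 0.05)

  # rectangle geometry: 10 x 4 px at 0.1 um/px -> 0.16 um^3
  mkr <- make_cell_masks(1, c(64, 64), length_um = 1, width_um = 0.4,
                         pixel_size = 0.1, rotation_sd = 0,
                         shape = "rectangle", seed = 12)
  flat <- matrix(50, 64, 64)
  recr <- quantify_cell(list(ch = flat), mkr$mask, 1, pixel_size = 0.1)
  expect_equal(recr$cell$width_um, 0.4, tolerance = 1e-9)
  expect_equal(recr$cell$volume_um3, 0.16, tolerance = 1e-9)
})

test_that("threshold fallback segmentation labels bright blobs", {
  mk <- make_cell_masks(4, c(120, 120), seed = 14)
  img <- matrix(10, 120, 120)
  img[mk$mask > 0] <- 100
  lab <- segment_threshold(img)
  expect_equal(max(lab), 4L)
})
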