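# Readers/writers for the pipeline's exchange formats (TIFF images and label
# masks, per-cell/per-spot CSV tables, JSON summaries) and the end-to-end
# pipeline driver. CSV is the exchange format between stages so each stage is
# independently testable; label masks use 0 = background, k = cell k.

#' Read a fluorescence channel from a TIFF file
#'
#' Grayscale 8/16-bit TIFF; pixel values are returned as stored (integers).
#' @param path file path.
#' @return numeric matrix.
#' @export
read_channel_tiff <- function(path) {
  if (!file.exists(path)) {
    stop_pf("missing image file: ", path, class = "pf_io_error")
  }
  img <- tryCatch(tiff::readTIFF(path, as.is = TRUE),
                  error = function(e) {
                    stop_pf("not a readable TIFF: ", path, " (", conditionMessage(e),
                            ")", class = "pf_format_error")
                  })
  if (length(dim(img)) == 3) {
    if (dim(img)[3] != 1) {
      stop_pf("expected a single-sample grayscale TIFF: ", path,
              class = "pf_format_error")
    }
    img <- img[, , 1]
  }
  storage.mode(img) <- "double"
  img
}

#' Write a fluorescence channel as a 16-bit grayscale TIFF
#'
#' Values are clamped at 0 and rounded to integer photon counts
#' (0..65535).
#' @param image numeric matrix.
#' @param path output path.
#' @export
write_channel_tiff <- function(image, path) {
  assert_matrix_image(image)
  v <- round(pmax(image, 0))
  if (max(v) > 65535) {
    stop_pf("pixel values exceed the 16-bit range", class = "pf_io_error")
  }
  tiff::writeTIFF(v / 65535, path, bits.per.sample = 16, compression = "none")
  invisible(path)
}

#' Read a 16-bit label mask from a TIFF file
#' @param path file path.
#' @return integer matrix (0 = background).
#' @export
read_label_mask <- function(path) {
  m <- read_channel_tiff(path)
  storage.mode(m) <- "integer"
  m
}

#' Write a label mask as a 16-bit TIFF
#' @param mask integer matrix of labels.
#' @param path output path.
#' @export
write_label_mask <- function(mask, path) {
  if (max(mask) > 65535) {
    stop_pf("more than 65535 labels cannot be stored in a 16-bit mask",
            class = "pf_io_error")
  }
  write_channel_tiff(mask, path)
}

#' Write a table to CSV (round-trip safe)
#' @param records data.frame.
#' @param path output path.
#' @export
write_records <- function(records, path) {
  stopifnot(is.data.frame(records))
  write.csv(records, path, row.names = FALSE)
  invisible(path)
}

#' Read a table written by [write_records()]
#' @param path CSV path.
#' @return data.frame.
#' @export
read_records <- function(path) {
  if (!file.exists(path)) {
    stop_pf("missing table: ", path, class = "pf_io_error")
  }
  read.csv(path, stringsAsFactors = FALSE)
}

# Provenance block attached to every numeric output of a pipeline run.
provenance <- function(config) {
  cfg <- config[setdiff(names(config), "out_dir")]
  list(package = "promoterflux",
       version = as.character(utils::packageVersion("promoterflux")),
       seed = config$seed,
       config_hash = sum(utf8ToInt(paste(deparse(cfg), collapse = ""))),
       config = cfg)
}

#' Run the full measurement pipeline on one image set
#'
#' Executes register -> quantify -> calibrate -> count -> activity and writes
#' all per-stage artifacts (CSV tables, calibration JSON, summary JSON with a
#' provenance record) to `config$out_dir`. The first failing stage aborts
#' with an error naming that stage; artifacts from completed stages are kept.
#'
#' @param config list with elements:
#'   `images` (named list of channel TIFF paths; must include the channels
#'   named by `plasmid_channel` and `mrna_channel`), `mask` (label TIFF
#'   path), `pixel_size` (um/px), `plasmid_channel`, `mrna_channel`,
#'   `tau` (1/s) or `decay_series` (CSV with time_min, count),
#'   `seed`, `out_dir`, and optionally `smooth_radius`, `window`,
#'   `min_prominence`, `register` (logical), `n_subsample`.
#' @return invisibly, a list with the per-stage results and the summary.
#' @export
run_pipeline <- function(config) {
  stopifnot(is.list(config), !is.null(config$out_dir))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop_pf("stage '", name, "' failed: ", conditionMessage(e),
              class = "pf_stage_error")
    })
  }
  pch <- config$plasmid_channel %||% "plasmid"
  mch <- config$mrna_channel %||% "mrna"
  seed <- config$seed %||% 1L

  images <- stage("read", {
    mask <- read_label_mask(config$mask)
    imgs <- lapply(config$images, read_channel_tiff)
    list(mask = mask, channels = imgs)
  })

  if (isTRUE(config$register) && length(images$channels) > 1) {
    images$channels <- stage("register", {
      ref <- images$channels[[1]]
      c(images$channels[1], lapply(images$channels[-1], function(img) {
        apply_shift(img, register_channels(ref, img,
                                           config$max_shift %||% 5L))
      }))
    })
  }

  quant <- stage("quantify", {
    quantify_cells(images$channels, images$mask,
                   pixel_size = config$pixel_size %||% 0.1,
                   smooth_radius = config$smooth_radius %||% 5,
                   window = config$window %||% 7L,
                   min_prominence = config$min_prominence)
  })
  write_records(quant$cells, file.path(config$out_dir, "cells.csv"))
  write_records(quant$spots, file.path(config$out_dir, "spots.csv"))

  calib <- stage("calibrate", {
    lapply(setNames(c(pch, mch), c(pch, mch)), function(ch) {
      # a unit intensity calibrated on a dedicated low-copy sample may be
      # supplied in the config; otherwise calibrate from this dataset's spots
      if (!is.null(config$unit_intensity[[ch]])) {
        structure(list(unit_intensity = config$unit_intensity[[ch]],
                       peak_positions = numeric(), n_spots_used = 0L,
                       binwidth = NULL, method = "supplied"),
                  class = "calibration_result")
      } else {
        calibrate_unit_intensity(quant$spots$integral[quant$spots$channel == ch])
      }
    })
  })
  jsonlite::write_json(
    lapply(calib, function(cl) list(unit_intensity = cl$unit_intensity,
                                    peaks = cl$peak_positions,
                                    n_spots_used = cl$n_spots_used)),
    file.path(config$out_dir, "calibration.json"), auto_unbox = TRUE,
    digits = NA)

  counts <- stage("count", {
    all_ids <- sort(unique(quant$cells$cell_id))
    N <- counts_per_cell(quant$spots[quant$spots$channel == pch, ],
                         calib[[pch]]$unit_intensity, all_ids)
    m <- counts_per_cell(quant$spots[quant$spots$channel == mch, ],
                         calib[[mch]]$unit_intensity, all_ids)
    data.frame(cell_id = all_ids, N = N$count, m = m$count)
  })
  write_records(counts, file.path(config$out_dir, "counts.csv"))

  act <- stage("activity", {
    tau <- config$tau
    dec <- NULL
    if (is.null(tau)) {
      if (is.null(config$decay_series)) {
        stop_pf("need either tau or a decay_series table",
                class = "pf_bad_input")
      }
      dec <- decay_fit(read_records(config$decay_series), seed = seed)
      tau <- dec$tau
    }
    pop <- population_activity(counts, tau)
    list(tau = tau, decay = dec, pop = pop)
  })
  write_records(act$pop$records, file.path(config$out_dir, "activity.csv"))

  summary <- list(
    mean_J = act$pop$mean_J,
    sd_population = act$pop$sd_population,
    zero_activity_fraction = act$pop$zero_activity_fraction,
    plasmid_loss_fraction = act$pop$plasmid_loss_fraction,
    n_cells = nrow(counts),
    n_included = act$pop$n_included,
    tau = act$tau,
    half_life_min = if (!is.null(act$decay)) act$decay$half_life_min else log(2) / act$tau / 60,
    unit_intensity = lapply(calib, `[[`, "unit_intensity"),
    provenance = provenance(config))
  jsonlite::write_json(summary, file.path(config$out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(list(quant = quant, calibration = calib, counts = counts,
                 activity = act, summary = summary))
}

#' Generate a complete synthetic dataset on disk
#'
#' Renders a two-channel image set (plasmid + mRNA) with a label mask and
#' ground-truth tables for a seeded population, and writes everything under
#' `out_dir` (TIFF images, mask, ground-truth CSVs, config snapshot YAML).
#'
#' @param out_dir output directory.
#' @param n_cells number of cells.
#' @param image_shape image dimensions `c(rows, cols)`.
#' @param plasmid_dist,mrna_per_plasmid,zero_activity_prob see
#'   [simulate_population_table()].
#' @param noise a [noise_model()].
#' @param pixel_size um per pixel.
#' @param max_spots maximum spots per cell and channel (see
#'   [assign_spots()]); `1` makes each cell's molecules a single cluster,
#'   the regime of a calibration sample.
#' @param seed integer seed.
#' @return invisibly, the ground truth (cells, spots, population table).
#' @export
simulate_image_dataset <- function(out_dir, n_cells = 50,
                                   image_shape = c(512L, 512L),
                                   plasmid_dist = list(kind = "poisson", mean = 9),
                                   mrna_per_plasmid = 1.2,
                                   zero_activity_prob = 0.05,
                                   noise = noise_model(), pixel_size = 0.1,
                                   max_spots = 4L, seed = 1L) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  masks <- make_cell_masks(n_cells, image_shape, pixel_size = pixel_size,
                           seed = child_seed(seed, 1L))
  pop <- simulate_population_table(n_cells, plasmid_dist = plasmid_dist,
                                   mrna_per_plasmid = mrna_per_plasmid,
                                   zero_activity_prob = zero_activity_prob,
                                   seed = child_seed(seed, 2L))
  sp_p <- assign_spots(masks$mask, pop$N, channel = "plasmid",
                       max_spots = max_spots, seed = child_seed(seed, 3L))
  sp_m <- assign_spots(masks$mask, pop$m, channel = "mrna",
                       max_spots = max_spots, seed = child_seed(seed, 4L))
  img_p <- render_channel(image_shape, sp_p, noise, seed = child_seed(seed, 5L))
  img_m <- render_channel(image_shape, sp_m, noise, seed = child_seed(seed, 6L))
  write_label_mask(masks$mask, file.path(out_dir, "mask.tif"))
  write_channel_tiff(img_p, file.path(out_dir, "plasmid.tif"))
  write_channel_tiff(img_m, file.path(out_dir, "mrna.tif"))
  write_records(pop, file.path(out_dir, "truth_population.csv"))
  write_records(rbind(sp_p, sp_m), file.path(out_dir, "truth_spots.csv"))
  write_records(masks$cells, file.path(out_dir, "truth_cells.csv"))
  yaml::write_yaml(list(n_cells = n_cells, image_shape = image_shape,
                        pixel_size = pixel_size, seed = seed,
                        unit_intensity = noise$unit_intensity,
                        psf_sigma = noise$psf_sigma,
                        background = noise$background,
                        shot_noise = noise$shot_noise,
                        read_noise_sd = noise$read_noise_sd,
                        mrna_per_plasmid = mrna_per_plasmid,
                        zero_activity_prob = zero_activity_prob),
                   file.path(out_dir, "config.yaml"))
  invisible(list(cells = masks$cells, mask = masks$mask, population = pop,
                 spots = rbind(sp_p, sp_m)))
}
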