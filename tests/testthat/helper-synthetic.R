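# Shared synthetic protocols for end-to-end tests.

# Calibrate a channel's unit intensity from a dedicated calibration image
# set: cells carrying 1..4 molecules as a single cluster each (the regime of
# a low-copy calibration construct), rendered and quantified from scratch.
calibrate_on_synthetic_images <- function(dir, channel = "plasmid",
                                          n_cells = 400, seed = 1) {
  simulate_image_dataset(
    dir, n_cells = n_cells, image_shape = c(1600L, 1600L),
    plasmid_dist = list(kind = "empirical",
                        counts = rep(1:4, round(200 * 0.6^(0:3)))),
    mrna_per_plasmid = 1, zero_activity_prob = 0,
    max_spots = 1L, seed = seed)
  imgs <- list(read_channel_tiff(file.path(dir, paste0(channel, ".tif"))))
  names(imgs) <- channel
  q <- quantify_cells(imgs, read_label_mask(file.path(dir, "mask.tif")))
  calibrate_unit_intensity(q$spots$integral)$unit_intensity
}
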