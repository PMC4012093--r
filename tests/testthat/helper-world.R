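# Shared fixtures: all synthetic, built in code.

# deterministic noise-free, cardiac-free model ("quiet world")
quiet_model <- function(...) {
  lung_model_config(noise_sd = 0, cardiac_amplitude_ml = 0,
                    spiro_noise_sd = 0, ...)
}

# uniform-fill tomogram series: each ROI strip filled with one constant
uniform_frames <- function(n_frames = 3, ventral = 1, middle = 2, dorsal = 3,
                           excluded = 99, layout = roi_layout()) {
  arr <- array(0, dim = c(n_frames, layout$n_rows, layout$n_cols))
  fill <- c(ventral = ventral, middle = middle, dorsal = dorsal,
            excluded = excluded)
  for (nm in names(fill)) {
    r <- layout$ranges[[nm]]
    if (r[2] > r[1]) arr[, (r[1] + 1):r[2], ] <- fill[[nm]]
  }
  pixel_frame_series(arr, fs = 13)
}

# brute-force per-pixel ROI summation oracle (independent of the rowSums path)
brute_force_roi_sums <- function(frames, layout) {
  d <- dim(frames$frames)
  z <- matrix(0, d[1], 4, dimnames = list(NULL, c("global", "ventral",
                                                  "middle", "dorsal")))
  for (t in seq_len(d[1])) {
    for (r in seq_len(d[2])) {
      row0 <- r - 1L
      roi <- NA_character_
      for (nm in c("ventral", "middle", "dorsal")) {
        rg <- layout$ranges[[nm]]
        if (row0 >= rg[1] && row0 < rg[2]) roi <- nm
      }
      if (is.na(roi)) next
      for (c in seq_len(d[3])) {
        z[t, roi] <- z[t, roi] + frames$frames[t, r, c]
        z[t, "global"] <- z[t, "global"] + frames$frames[t, r, c]
      }
    }
  }
  z
}

# build a regional impedance series directly from sub-ROI curves
make_impedance <- function(ventral, middle, dorsal, fs, t0 = 0) {
  series <- cbind(global = ventral + middle + dorsal, ventral = ventral,
                  middle = middle, dorsal = dorsal)
  eitflow:::new_regional_series(series, fs, t0, "regional_impedance_series")
}

make_volume <- function(ventral, middle, dorsal, fs, t0 = 0, v_t = 1,
                        z_t = 1) {
  series <- cbind(global = ventral + middle + dorsal, ventral = ventral,
                  middle = middle, dorsal = dorsal)
  eitflow:::new_regional_series(series, fs, t0, "regional_volume_series",
                                extra = list(calibration = list(v_t = v_t,
                                                                z_t = z_t)))
}

make_flow <- function(global, fs, t0) {
  series <- cbind(global = global, ventral = global / 3, middle = global / 3,
                  dorsal = global / 3)
  eitflow:::new_regional_series(series, fs, t0, "regional_flow_series")
}

manual_seg <- function(cycles, fs, expected = 7.5, t0 = 0,
                       n_samples = max(cycles$end)) {
  structure(list(cycles = cycles, expected_duration = expected, fs = fs,
                 t0 = t0, n_samples = n_samples),
            class = "breath_segmentation")
}
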