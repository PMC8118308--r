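# shared fixtures: standard axes, reference libraries and small scenes

ch_axis <- function() wavenumber_axis(2825, 3075, 5)
fp_axis <- function() wavenumber_axis(1600, 1800, 2)

all_species <- c("CHOLESTEROL_MONOHYDRATE", "CHOLESTERYL_OLEATE",
                 "CHOLESTERYL_LINOLEATE", "PROTEIN")

# reference spectrum plus white noise at a given peak SNR
noisy_reference <- function(species, axis, snr = 20) {
  s <- synth_reference_spectrum(species, axis)
  sd <- max(s$intensities) / snr
  spectrum(s$wavenumbers_cm1,
           s$intensities + stats::rnorm(length(s$intensities), 0, sd),
           s$label)
}

# independent maximum-Feret oracle: brute force over all pixel pairs
feret_px_oracle <- function(px) {
  if (nrow(px) == 1L) return(1)
  max(stats::dist(px)) + 1
}

# small noiseless needle field used by several tests
small_field <- function(n = 10L, crossings = 0L, noise_sd = 0, seed = 3L,
                        shape = c(192L, 192L), length_um = 10) {
  generate_needle_field(needle_field_params(
    image_shape = shape, n_needles = n,
    length_um = list(family = "FIXED", value = length_um),
    noise_sd = noise_sd, n_forced_crossing_pairs = crossings, seed = seed))
}
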