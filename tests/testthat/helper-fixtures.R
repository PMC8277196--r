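# Small, fast study-condition variants shared across tests: a 45-um field
# holding a 40-um cell keeps single-cell fixtures quick while preserving the
# default calibration (0.15 um/px) and stack geometry (15 slices at 1 um).

small_acq <- function(noise_model = "none", ...) {
  acquisition_params(image_size_px = c(300, 300), noise_model = noise_model,
                     ...)
}

small_cell <- function(truth_spec = puncta_spec(n = c(10, 5, 1)), seed = 7,
                       noise_model = "none", ...) {
  generate_cell(truth_spec, small_acq(noise_model = noise_model), seed = seed,
                cell_diameter_um = 40, nucleus_diameter_um = 12, ...)
}

# threshold at half the post-top-hat amplitude (FWHM convention): with the
# generator's constant peak intensity this sits near 120 of 255
half_max_params <- function(...) pipeline_params(threshold = 120, ...)
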