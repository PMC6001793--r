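# Shared synthetic fixtures. All data are generated in code from closed
# forms; seeds are fixed wherever noise is involved.

# a 16-step gradient list reaching e^-3-ish attenuation for D ~ 5e-10 m^2/s
default_encoding <- function(n = 16, gmax = 0.55, gmin = 0.02, spacing = "equal_g2") {
  g <- if (spacing == "equal_g2") sqrt(seq(gmin^2, gmax^2, length.out = n))
       else seq(gmin, gmax, length.out = n)
  diffusion_encoding(g)
}

# two-component mixture with overlapping spectra, 60:40 by integral,
# D = 5e-10 / 1e-10 m^2/s
mixture_lines <- function() {
  c(list(line_spec(-2.0, 0.36, 3, D = 5e-10, component_id = 1),
         line_spec(0.5, 0.24, 3, D = 5e-10, component_id = 1)),
    list(line_spec(0.8, 0.25, 3, D = 1e-10, component_id = 2),
         line_spec(2.5, 0.15, 3, D = 1e-10, component_id = 2)))
}

mixture_set <- function(noise_sigma = 0, seed = NULL, n_points = 2048) {
  make_diffusion_set(mixture_lines(), n_increments = 16, gmax = 0.55, gmin = 0.02,
                     spacing = "equal_g2", n_points = n_points, dwell = 2e-4,
                     noise_sigma = noise_sigma, seed = seed)
}

# measured full width at half height of the tallest peak in a window
measure_fwhm <- function(spec, window_ppm = NULL) {
  track_peak(spec, window_ppm = window_ppm)$fwhm_hz
}

grid_step_hz <- function(spec) abs(spec$axis_hz[1] - spec$axis_hz[2])
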