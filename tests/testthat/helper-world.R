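# Shared small synthetic fixtures.

# quiet 2-degree world at coarse resolution, deterministic climate
quiet_world <- function(resolution = 6, n_stations = 60, seed = 1, ...) {
  world_config(bbox = c(100, 102, 35, 37), resolution = resolution,
               n_stations = n_stations, seed = seed,
               noise_sd_temp = 0, noise_sd_precip = 0, ...)
}

# small suitability grid from a matrix
suit_grid <- function(m, bbox = c(100, 100 + ncol(m) / 24,
                                  35, 35 + nrow(m) / 24)) {
  hydro_grid(m, bbox, resolution = 2.5, var = "suitability")
}
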