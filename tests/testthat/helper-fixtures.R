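# Shared fixtures, built in code. Small configurations keep the suite fast;
# the full-scale geometry (101 angles, 2048-sample IRs) is exercised where
# the check is about the geometry itself.

fix_cfg <- function(...) sim_config(...)

fix_small_cfg <- function(n_angles = 21, ir_length = 1536, ...) {
  sim_config(n_angles = n_angles, ir_length = ir_length, ...)
}

fix_flowers <- function(n_per_species = 2, seed = 2, catalog_seed = 1) {
  sample_flowers(make_catalog(seed = catalog_seed), n_per_species,
                 seed = seed)
}

# one flower with a given corolla depth (mm), for interference-comb checks
fix_flower_depth <- function(depth_mm) {
  fl <- fix_flowers(1)[1, , drop = FALSE]
  fl$inner_depth <- depth_mm
  fl
}

# analytic two-path transfer function |a1 + a2 e^{-2 pi i f tau}|^2 in dB,
# from the spike amplitudes/positions of a simulated IR (independent of the
# window/PSD/calibration pipeline under test)
two_path_ts_db <- function(ir, f, sample_rate = 5e5) {
  idx <- which(ir != 0)
  a <- ir[idx]
  if (length(idx) == 1) return(rep(20 * log10(abs(a)), length(f)))
  tau <- (idx[2] - idx[1]) / sample_rate
  10 * log10(Mod(a[1] + a[2] * exp(-2i * pi * f * tau))^2)
}

# dummy scan-set entry for chunking tests: geometry only, IR content unused
fix_chunk_entry <- function(n_angles = 101, planes = c("azimuth",
                                                       "elevation")) {
  pl <- lapply(planes, function(p) matrix(0, n_angles, 4))
  names(pl) <- planes
  list(flower_id = "F_01", species = "sp", syndrome = "bat",
       angles = seq(-90, 90, length.out = n_angles), planes = pl)
}
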