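# Shared fixtures: a well-separated set of mismatch loci spanning the
# R = -465..-545 scan window (spacings >= 8 turns), and a one-call
# simulate + reference + fit chain used by several test files.

acc_mismatches <- c(2455, 2500, 2560, 2610, 2655, 2700, 2760, 2800)

make_run <- function(noise = 0.035, seed = 3,
                     mismatches = acc_mismatches,
                     R_start = -465, R_stop = -545, ...) {
  p <- sim_params(noise_sd_slow = noise, seed = seed)
  tr <- simulate_protocol_run(p, mismatches, R_start = R_start,
                              R_stop = R_stop, ...)
  n0 <- estimate_N0(tr[tr$segment_id == 0, , drop = FALSE])
  ref <- fit_reference(simulate_reference_trace(p), N0 = n0$N0)
  list(params = p, trace = tr, n0 = n0, ref = ref,
       truth = attr(tr, "truth"))
}

# noiseless reference curve over the full bell, used as a near-exact
# stand-in for the generator truth
make_clean_ref <- function(seed = 2, N0 = 1200, step = 0.5) {
  p <- sim_params(noise_sd_slow = 0, seed = seed)
  fit_reference(simulate_reference_trace(p, R_max = 60, step = step),
                N0 = N0)
}

# synthetic blockage curve-segment on the generator truth
make_segment <- function(Ri, Ni, params, R_top_offset = 2, n = 26,
                         noise = 0) {
  R <- seq(round(Ri) + R_top_offset, by = -1, length.out = n)
  h <- ifelse(R > Ri, migration_height(R, params),
              blocked_height(R, Ri, Ni, params))
  data.frame(rotation_turns = R,
             height_um = pmax(h + rnorm(n, 0, noise), 0))
}
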