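#' Simulation parameters for synthetic tweezers traces
#'
#' Bundles the physical and instrumental parameters of the forward model.
#' Defaults describe the study conditions of the mapping experiments: a
#' 13.2-kb construct with an effective `N0` of about 1200 turns between the
#' anchoring points, a maximum extension `H0` of 2.76 um at zero rotation,
#' and a B-DNA helical repeat of 10.45 bp/turn.
#'
#' @param N0 Effective number of helical turns of the torsion-relaxed tether
#'   (turns, > 0).
#' @param H0 Maximum extension at zero rotation (um, > 0).
#' @param hr_dna Helical repeat of B-DNA (bp/turn); one bead turn advances
#'   the junction `hr_dna / 2` bases into each arm.
#' @param plecto_width Half-width at mid-height of the plectoneme formation
#'   curve, in relative winding units sigma (dimensionless, in (0, 1)). The
#'   default 0.025 puts the mid-height of the bell at about 30 turns for
#'   `N0 = 1200`, the tens-of-turns scale over which extension is lost to
#'   plectonemes at 0.2-0.4 pN.
#' @param noise_sd_slow,noise_sd_fast Gaussian height-measurement noise SD
#'   (um) in the slow and fast acquisition modes. The slow-mode default is
#'   calibrated so that the residual-resampling bootstrap SD of fitted
#'   blockage rotations on default runs falls in the 0.5-0.6-turn range;
#'   fast mode defaults to three times noisier.
#' @param skid_prob Per-rotation-step probability of a rotation skid, a
#'   persistent shift of the rotation reference caused by transient loss of
#'   one anchoring strand. Off by default.
#' @param skid_magnitude_range Two-element range (turns) from which a skid
#'   offset is drawn uniformly.
#' @param max_skids Maximum number of skid events per run (default one).
#' @param temperature Sample temperature (degrees C); phenomenological label.
#' @param force Traction force (pN); phenomenological label only — force
#'   enters the simulator through `H0`, `plecto_width` and the noise levels.
#' @param seed Optional RNG seed recorded with the simulated trace.
#'
#' @return An object of class `sim_params` (a validated list).
#' @examples
#' p <- sim_params()
#' p$N0
#' @export
sim_params <- function(N0 = 1200, H0 = 2.76, hr_dna = 10.45,
                       plecto_width = 0.025,
                       noise_sd_slow = 0.035,
                       noise_sd_fast = 3 * noise_sd_slow,
                       skid_prob = 0, skid_magnitude_range = c(1, 5),
                       max_skids = 1,
                       temperature = 37, force = 0.2, seed = NULL) {
  p <- list(N0 = N0, H0 = H0, hr_dna = hr_dna, plecto_width = plecto_width,
            noise_sd_slow = noise_sd_slow, noise_sd_fast = noise_sd_fast,
            skid_prob = skid_prob,
            skid_magnitude_range = skid_magnitude_range,
            max_skids = max_skids,
            temperature = temperature, force = force, seed = seed)
  validate_sim_params(p)
  class(p) <- "sim_params"
  p
}

validate_sim_params <- function(p) {
  bad <- character()
  chk <- function(cond, msg) if (!isTRUE(cond)) bad <<- c(bad, msg)
  chk(is.numeric(p$N0) && length(p$N0) == 1 && p$N0 > 0, "N0 must be > 0")
  chk(is.numeric(p$H0) && length(p$H0) == 1 && p$H0 > 0, "H0 must be > 0")
  chk(is.numeric(p$hr_dna) && p$hr_dna > 0, "hr_dna must be > 0")
  chk(is.numeric(p$plecto_width) && p$plecto_width > 0 && p$plecto_width < 1,
      "plecto_width must be in (0, 1)")
  chk(p$noise_sd_slow >= 0, "noise_sd_slow must be >= 0")
  chk(p$noise_sd_fast >= 0, "noise_sd_fast must be >= 0")
  chk(p$skid_prob >= 0 && p$skid_prob <= 1, "skid_prob must be in [0, 1]")
  chk(length(p$skid_magnitude_range) == 2 &&
        all(p$skid_magnitude_range >= 0) &&
        diff(p$skid_magnitude_range) >= 0,
      "skid_magnitude_range must be an increasing non-negative pair")
  if (length(bad)) {
    stop("invalid sim_params:\n  ", paste(bad, collapse = "\n  "),
         call. = FALSE)
  }
  invisible(p)
}

#' @export
print.sim_params <- function(x, ...) {
  cat("Tweezers simulation parameters\n")
  cat(sprintf("  N0 = %g turns, H0 = %g um, helical repeat = %g bp/turn\n",
              x$N0, x$H0, x$hr_dna))
  cat(sprintf("  plectoneme mid-height half-width = %g (sigma)\n",
              x$plecto_width))
  cat(sprintf("  noise SD: slow %g um, fast %g um\n",
              x$noise_sd_slow, x$noise_sd_fast))
  cat(sprintf("  skid: prob %g/step, magnitude [%g, %g] turns, max %d\n",
              x$skid_prob, x$skid_magnitude_range[1],
              x$skid_magnitude_range[2], as.integer(x$max_skids)))
  cat(sprintf("  temperature %g C, force %g pN\n", x$temperature, x$force))
  invisible(x)
}
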