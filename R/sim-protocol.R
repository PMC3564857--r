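#' Simulate a go-and-return mapping run
#'
#' Forward model of the measurement protocol used to explore a rotation
#' range for mismatch-induced migration blockages. The junction starts deep
#' (driven to `R_stop` under permissive, magnesium-free conditions, where
#' mismatches do not block), and the protocol then works its way back toward
#' `R_start`: the rotation is raised to a start value `R1` (retracting the
#' junction and resorbing mismatches), lowered in 1-turn steps in the noisy
#' fast mode to probe for a blockage, and — whenever a new blockage is met —
#' returned to `R1` for a quieter slow-mode re-acquisition of the whole
#' plectoneme curve-segment. `R1` is then moved up by `restart_step` turns
#' and the probe repeated until `R_start` is passed. Fast cycles take 2.5 s,
#' slow cycles 10 s; continuous raises run at 6 turns/s and are not
#' recorded.
#'
#' Heights come from [migration_height()] / [blocked_height()] driven by the
#' [step_hj()] ratchet, plus mode-dependent Gaussian noise. Optional
#' rotation-skid events add a persistent offset to the rotation reference
#' (the recorded rotation is the commanded one, so apexes shift in the
#' recorded frame).
#'
#' @param params A [sim_params()] object.
#' @param mismatches Base indices (from the construct center, ascending) of
#'   mismatch loci, e.g. the `base_index` column of a mismatch table from
#'   [find_differences()].
#' @param R_start,R_stop Rotation range scanned (turns); `R_start > R_stop`,
#'   exploration is toward more negative rotations.
#' @param fast_span Turns descended per fast-mode probe (default 14, in the
#'   12-15 range of the protocol).
#' @param slow_span Turns descended per slow-mode acquisition (default 25,
#'   in the 20-30 range).
#' @param restart_step Turns by which the descent start is raised between
#'   probes (default 2).
#' @return A `data.frame` of class `hj_trace` with columns `time_s`,
#'   `rotation_turns`, `height_um`, `mode`, `segment_id`, `buffer`
#'   (`segment_id` 0 marks the migration regime; positive ids index the
#'   blocking mismatch) and attributes `params`, `truth` (a table of the
#'   blocking mismatches with their true blocking rotations `Ri_true` and
#'   `Ni_true`), `skid_events`, and `seed`.
#' @examples
#' p <- sim_params(seed = 1)
#' tr <- simulate_protocol_run(p, mismatches = c(2500, 2600),
#'                             R_start = -465, R_stop = -510)
#' table(tr$segment_id)
#' @export
simulate_protocol_run <- function(params, mismatches, R_start, R_stop,
                                  fast_span = 14, slow_span = 25,
                                  restart_step = 2) {
  stopifnot(inherits(params, "sim_params"))
  if (!(R_start > R_stop)) {
    stop("R_start must exceed R_stop (exploration toward more negative R)",
         call. = FALSE)
  }
  mism <- sort(as.numeric(mismatches))
  if (!is.null(params$seed)) set.seed(params$seed)
  hr <- params$hr_dna
  noise <- c(fast = params$noise_sd_fast, slow = params$noise_sd_slow)
  cycle <- c(fast = 2.5, slow = 10)

  # junction driven to R_stop with migration unblocked (permissive buffer)
  state <- hj_state(junction_position = abs(R_stop) * hr / 2)
  R_cmd <- R_stop
  skid_offset <- 0
  n_skids <- 0L
  skid_events <- list()
  mol_prev <- R_stop
  t_now <- 0
  rows <- vector("list", 4096L)
  n_rows <- 0L

  height_at <- function(Rmol) {
    if (!is.na(state$blocked_at)) {
      Ri <- -2 * state$blocked_at / hr
      blocked_height(Rmol, Ri, params$N0 - abs(Ri), params)
    } else {
      migration_height(Rmol, params)
    }
  }

  step_to <- function(R_target, mode = "fast", record = TRUE) {
    if (!record) t_now <<- t_now + abs(R_target - R_cmd) / 6
    while (abs(R_target - R_cmd) > 1e-9) {
      d <- sign(R_target - R_cmd) * min(1, abs(R_target - R_cmd))
      R_cmd <<- R_cmd + d
      if (n_skids < params$max_skids && params$skid_prob > 0 &&
          runif(1) < params$skid_prob) {
        mag <- runif(1, params$skid_magnitude_range[1],
                     params$skid_magnitude_range[2])
        skid_offset <<- skid_offset + mag
        n_skids <<- n_skids + 1L
        skid_events[[n_skids]] <<- list(time_s = t_now, offset_turns = mag)
      }
      mol <- R_cmd + skid_offset
      state <<- step_hj(state, mol - mol_prev, mism, params)
      mol_prev <<- mol
      if (record) {
        t_now <<- t_now + cycle[[mode]]
        h <- height_at(mol) + rnorm(1, 0, noise[[mode]])
        seg <- if (is.na(state$blocked_at)) 0L
               else match(state$blocked_at, mism)
        n_rows <<- n_rows + 1L
        rows[[n_rows]] <<- list(time_s = t_now, rotation_turns = R_cmd,
                                height_um = max(h, 0), mode = mode,
                                segment_id = seg, buffer = "B")
      }
    }
  }

  R1 <- R_stop + fast_span
  last_block <- NA_real_
  seen <- numeric(0)
  repeat {
    step_to(R1, record = FALSE)               # retract / resorb
    step_to(R1 - fast_span, mode = "fast")    # probe descent
    nb <- state$blocked_at
    if (!is.na(nb) && !isTRUE(nb == last_block)) {
      step_to(R1, record = FALSE)
      step_to(R1 - slow_span, mode = "slow")  # detailed acquisition
      step_to(R1, record = FALSE)
      last_block <- nb
      seen <- c(seen, nb)
    }
    R1 <- R1 + restart_step
    if (R1 > R_start) break
  }

  tr <- do.call(rbind, lapply(rows[seq_len(n_rows)], as.data.frame))
  rownames(tr) <- NULL
  truth <- data.frame(base_index = mism,
                      Ri_true = -2 * mism / hr,
                      Ni_true = params$N0 - 2 * mism / hr,
                      segment_id = seq_along(mism),
                      detected = mism %in% seen)
  structure(tr, params = params, truth = truth,
            skid_events = skid_events, seed = params$seed,
            class = c("hj_trace", "data.frame"))
}

#' Simulate a plectoneme reference curve acquisition
#'
#' Slow stepwise rotation sweep around zero rotation with no junction
#' present: the extension follows `H0 * reference_shape(R / N0)` plus
#' measurement noise. This is the trace from which [fit_reference()] builds
#' the normalized mirror-symmetric reference curve. An `apex_offset` can
#' shift the curve to emulate a rotation skid accumulated before the
#' (re-)acquisition.
#'
#' @param params A [sim_params()] object.
#' @param R_max Sweep half-range in turns (default 60).
#' @param step Rotation step in turns (default 1).
#' @param mode Acquisition mode, `"slow"` (default) or `"fast"`.
#' @param apex_offset Rotation of the apex in the recorded frame (turns).
#' @return An `hj_trace` data frame (all `segment_id` 0).
#' @export
simulate_reference_trace <- function(params, R_max = 60, step = 1,
                                     mode = c("slow", "fast"),
                                     apex_offset = 0) {
  stopifnot(inherits(params, "sim_params"), R_max > 0, step > 0)
  mode <- match.arg(mode)
  if (!is.null(params$seed)) set.seed(params$seed + 1L)
  sd_h <- if (mode == "slow") params$noise_sd_slow else params$noise_sd_fast
  cyc <- if (mode == "slow") 10 else 2.5
  R <- seq(-R_max, R_max, by = step) + apex_offset
  h <- params$H0 * reference_shape((R - apex_offset) / params$N0,
                                   params$plecto_width) +
    rnorm(length(R), 0, sd_h)
  tr <- data.frame(time_s = cyc * seq_along(R), rotation_turns = R,
                   height_um = pmax(h, 0), mode = mode,
                   segment_id = 0L, buffer = "B")
  structure(tr, params = params, seed = params$seed,
            class = c("hj_trace", "data.frame"))
}

#' Simulate blockage-bypass waiting times
#'
#' I.i.d. exponential waiting times with mean `tau`, the model under which
#' bypass event histograms are fitted ([fit_exponential()]).
#'
#' @param n Number of events (>= 1).
#' @param tau Characteristic time in seconds (> 0).
#' @param seed Optional RNG seed.
#' @return Numeric vector of `n` positive waiting times (seconds).
#' @export
simulate_waiting_times <- function(n, tau, seed = NULL) {
  stopifnot(n >= 1, tau > 0)
  if (!is.null(seed)) set.seed(seed)
  rexp(n, rate = 1 / tau)
}
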