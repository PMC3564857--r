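#' Holliday-junction ratchet state
#'
#' Minimal state of the noiseless junction state machine: position of the
#' branch point (bases from the construct center), the mismatch currently
#' blocking (if any), and the turns stored as plectonemes beyond the block.
#'
#' @param junction_position Bases from the construct center (>= 0).
#' @param blocked_at Base index of the blocking mismatch, or `NA` when
#'   migrating freely.
#' @param plectoneme_turns Turns stored in plectonemes beyond the blockage
#'   (>= 0).
#' @return An object of class `hj_state`.
#' @export
hj_state <- function(junction_position = 0, blocked_at = NA_real_,
                     plectoneme_turns = 0) {
  stopifnot(junction_position >= 0, plectoneme_turns >= 0)
  structure(list(junction_position = junction_position,
                 blocked_at = blocked_at,
                 plectoneme_turns = plectoneme_turns),
            class = "hj_state")
}

#' @export
print.hj_state <- function(x, ...) {
  cat(sprintf("HJ at %.2f bases from center; %s; %.3f plectoneme turns\n",
              x$junction_position,
              if (is.na(x$blocked_at)) "migrating"
              else sprintf("blocked at base %.2f", x$blocked_at),
              x$plectoneme_turns))
  invisible(x)
}

#' Advance or retract the junction by a rotation increment
#'
#' Implements the mismatch ratchet. Negative increments (unwinding) advance
#' the branch point by `hr_dna / 2` bases per turn until the next mismatch
#' index is reached; once blocked, further negative turns accumulate as
#' plectonemes. Positive increments first unwind stored plectonemes, then
#' clear the block and retract the junction (resorbing mismatches) freely.
#' Turns are conserved exactly: applied turns = 2/hr_dna times the bases
#' migrated plus the change in stored plectoneme turns.
#'
#' @param state An [hj_state()].
#' @param delta_R Rotation increment in turns (negative = unwinding =
#'   advancing the junction).
#' @param mismatches Sorted ascending base indices (from the construct
#'   center) of mismatch loci.
#' @param params A [sim_params()] object (supplies `hr_dna`).
#' @return The updated `hj_state`.
#' @examples
#' p <- sim_params()
#' s <- step_hj(hj_state(), -2, numeric(0), p)
#' s$junction_position   # 10.45 bases: one helical repeat in each arm
#' @export
step_hj <- function(state, delta_R, mismatches, params) {
  stopifnot(inherits(state, "hj_state"), inherits(params, "sim_params"))
  if (is.unsorted(mismatches)) {
    stop("mismatch indices must be sorted ascending", call. = FALSE)
  }
  eps <- 1e-9
  hr <- params$hr_dna
  pos <- state$junction_position
  blocked <- state$blocked_at
  plect <- state$plectoneme_turns

  if (delta_R < 0) {                      # unwinding: advance
    t_avail <- -delta_R
    if (!is.na(blocked)) {
      plect <- plect + t_avail
    } else {
      ahead <- mismatches[mismatches >= pos - eps]
      if (!length(ahead)) {
        pos <- pos + t_avail * hr / 2
      } else {
        need <- (ahead[1] - pos) * 2 / hr  # turns to reach the mismatch
        if (t_avail < need - eps) {
          pos <- pos + t_avail * hr / 2
        } else {
          pos <- ahead[1]
          blocked <- ahead[1]
          plect <- max(0, t_avail - need)
        }
      }
    }
  } else if (delta_R > 0) {               # rewinding: retract
    t_avail <- delta_R
    used <- min(t_avail, plect)
    plect <- plect - used
    t_avail <- t_avail - used
    if (t_avail > eps) {
      blocked <- NA_real_
      pos <- max(0, pos - t_avail * hr / 2)
    }
  }
  hj_state(pos, blocked, plect)
}
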