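#' Merge expected blockages closer than the experimental resolution
#'
#' Neighboring mismatches whose expected blockage rotations differ by less
#' than `resolution` turns cannot be told apart by the go-and-return
#' protocol (a descent would have to start between them). Groups of
#' expected blockages within `resolution` of a neighbor (transitive
#' closure) are replaced by their middle member — the median base index,
#' taking the lower median for even groups — flagged as merged.
#'
#' @param table A `mismatch_table` with `expected_rotation` filled (see
#'   [expected_rotations()]).
#' @param resolution Merging resolution in turns (> 0; default 2, about 10
#'   bases).
#' @return The reduced table with logical column `merged` and `n_in_group`.
#' @export
merge_unresolvable <- function(table, resolution = 2) {
  stopifnot(resolution > 0, !is.null(table$expected_rotation))
  tab <- table[order(table$base_index), , drop = FALSE]
  n <- nrow(tab)
  if (n == 0) {
    tab$merged <- logical(0); tab$n_in_group <- integer(0)
    return(tab)
  }
  gap <- abs(diff(tab$expected_rotation))
  grp <- cumsum(c(1, gap >= resolution))
  keep <- vapply(split(seq_len(n), grp), function(ix) {
    ix[ceiling(length(ix) / 2)]   # lower median on even-sized groups
  }, integer(1))
  sizes <- as.integer(table(grp))
  out <- tab[keep, , drop = FALSE]
  out$merged <- sizes > 1
  out$n_in_group <- sizes
  rownames(out) <- NULL
  out
}

# Order-preserving 1-D assignment between fitted and expected rotations,
# minimizing total squared residual about a trial offset; unmatched entries
# on either side cost skip_cost^2.
assign_pairs <- function(fitted, expected, offset, skip_cost) {
  n <- length(fitted); m <- length(expected)
  s2 <- skip_cost^2
  D <- matrix(0, n + 1, m + 1)
  D[, 1] <- (0:n) * s2
  D[1, ] <- (0:m) * s2
  P <- matrix(0L, n + 1, m + 1)        # 1 pair, 2 skip fitted, 3 skip expected
  for (i in 1:n) for (j in 1:m) {
    pair <- D[i, j] + (fitted[i] - expected[j] - offset)^2
    sf <- D[i, j + 1] + s2
    se <- D[i + 1, j] + s2
    best <- which.min(c(pair, sf, se))
    D[i + 1, j + 1] <- c(pair, sf, se)[best]
    P[i + 1, j + 1] <- best
  }
  pairs <- matrix(0L, 0, 2)
  i <- n + 1L; j <- m + 1L
  while (i > 1L || j > 1L) {
    mv <- if (i == 1L) 3L else if (j == 1L) 2L else P[i, j]
    if (mv == 1L) { pairs <- rbind(c(i - 1L, j - 1L), pairs); i <- i - 1L; j <- j - 1L }
    else if (mv == 2L) i <- i - 1L
    else j <- j - 1L
  }
  list(cost = D[n + 1, m + 1], pairs = pairs)
}

#' Match fitted blockages to expected positions and calibrate
#'
#' Pairs the fitted blocking rotations `Ri` with the sequence-predicted
#' blockage rotations by an order-preserving dynamic-programming assignment
#' (minimizing total squared mismatch over a set of trial offsets, with
#' unmatchable entries skipped at cost `skip_cost` squared). On the matched
#' pairs a line of fixed slope 1, `y = A + x`, is fitted: the intercept `A`
#' is the mean residual, `sd_turns` the SD of the residuals about the line,
#' and `sd_bases = sd_turns * hr_dna / 2` its conversion to bases. A large
#' common offset (|A| above `skid_flag`) is flagged as a possible rotation
#' skid.
#'
#' @param fits A list of [fit_blockage()] results, or a numeric vector of
#'   fitted rotations.
#' @param expected A `mismatch_table` with `expected_rotation` (apply
#'   [merge_unresolvable()] first if appropriate), or a numeric vector.
#' @param hr_dna Helical repeat (bp/turn).
#' @param skip_cost Residual (turns) beyond which leaving an entry
#'   unmatched is cheaper than pairing it (default 3).
#' @param skid_flag Intercept magnitude (turns) flagged as a likely global
#'   rotation skid (default 1).
#' @return An object of class `hj_map`: a list with `pairs` (data frame of
#'   fitted rotation, expected rotation, base index, residual), `A`,
#'   `sd_turns`, `sd_bases`, `n_matched`, `unmatched_fitted`,
#'   `unmatched_expected`, and `skid_suspected`.
#' @examples
#' m <- match_and_calibrate(c(-470.05, -480.05), c(-470, -480))
#' m$A          # 0.05 intercept, forced analytically
#' m$sd_turns   # 0
#' @export
match_and_calibrate <- function(fits, expected, hr_dna = 10.45,
                                skip_cost = 3, skid_flag = 1) {
  fitted_R <- if (is.numeric(fits)) fits else
    vapply(fits, function(f) f$Ri, numeric(1))
  boot_sd <- if (is.numeric(fits)) rep(NA_real_, length(fits)) else
    vapply(fits, function(f) f$boot_sd, numeric(1))
  exp_R <- if (is.numeric(expected)) expected else expected$expected_rotation
  base_ix <- if (is.numeric(expected)) rep(NA_real_, length(expected)) else
    expected$base_index
  if (length(fitted_R) < 2) {
    stop("need at least 2 fitted blockages", call. = FALSE)
  }
  of <- order(fitted_R); oe <- order(exp_R)
  fitted_R <- fitted_R[of]; boot_sd <- boot_sd[of]
  exp_R <- exp_R[oe]; base_ix <- base_ix[oe]

  offsets <- unique(c(0, round(outer(fitted_R, exp_R, "-"), 2)))
  best <- NULL
  for (a0 in offsets) {
    cand <- assign_pairs(fitted_R, exp_R, a0, skip_cost)
    # mild offset regularization: among near-equal assignments prefer the
    # smaller common shift rather than a remote order-preserving match
    cand$cost <- cand$cost + 1e-4 * a0^2
    if (is.null(best) || cand$cost < best$cost) best <- cand
  }
  if (nrow(best$pairs) < 2) {
    stop("no order-preserving assignment covering at least 2 pairs",
         call. = FALSE)
  }
  fi <- best$pairs[, 1]; ei <- best$pairs[, 2]
  A <- mean(fitted_R[fi] - exp_R[ei])     # least squares with slope fixed at 1
  resid <- fitted_R[fi] - exp_R[ei] - A
  sd_turns <- if (length(resid) > 1) sd(resid) else 0
  pairs <- data.frame(fitted_Ri = fitted_R[fi],
                      expected_rotation = exp_R[ei],
                      base_index = base_ix[ei],
                      boot_sd = boot_sd[fi],
                      residual = resid)
  structure(list(pairs = pairs, A = A, sd_turns = sd_turns,
                 sd_bases = sd_turns * hr_dna / 2,
                 hr_dna = hr_dna, n_matched = nrow(pairs),
                 unmatched_fitted = fitted_R[-fi],
                 unmatched_expected = exp_R[-ei],
                 skid_suspected = abs(A) > skid_flag),
            class = "hj_map")
}

#' @export
print.hj_map <- function(x, ...) {
  cat(sprintf(
    "Blockage map: %d matched pairs, A = %+.3f turns, SD = %.3f turns (%.2f bases)\n",
    x$n_matched, x$A, x$sd_turns, x$sd_bases))
  if (length(x$unmatched_fitted)) {
    cat("  unmatched fitted rotations:",
        paste(sprintf("%.2f", x$unmatched_fitted), collapse = ", "), "\n")
  }
  if (length(x$unmatched_expected)) {
    cat("  unmatched expected rotations:",
        paste(sprintf("%.2f", x$unmatched_expected), collapse = ", "), "\n")
  }
  if (x$skid_suspected) {
    cat("  note: common offset exceeds 1 turn - possible rotation skid\n")
  }
  invisible(x)
}

#' @export
summary.hj_map <- function(object, ...) {
  print(object)
  cat("\n")
  print.data.frame(object$pairs, digits = 4)
  invisible(object)
}

#' @export
plot.hj_map <- function(x, ...) {
  plot(x$pairs$expected_rotation, x$pairs$fitted_Ri,
       xlab = "expected rotation (turns)", ylab = "fitted Ri (turns)", ...)
  abline(x$A, 1, col = 2)
  legend("topleft", bty = "n",
         legend = sprintf("y = %.3f + x, SD = %.2f turns", x$A, x$sd_turns))
  invisible(x)
}

#' Widest blockage-free rotation interval of a construct
#'
#' The largest gap between consecutive expected blockage rotations is a
#' robust fingerprint of a construct (a fixed-span region with no mismatch
#' surrounded by closely spaced ones identifies the molecule even when the
#' absolute rotation reference has skidded).
#'
#' @param expected A `mismatch_table` with `expected_rotation`, or a
#'   numeric vector of expected rotations (at least 2).
#' @return A list with `gap` (turns), `from`, `to` (interval endpoints,
#'   `from < to`).
#' @export
signature_gap <- function(expected) {
  r <- if (is.numeric(expected)) expected else expected$expected_rotation
  if (length(r) < 2) stop("need at least 2 expected blockages", call. = FALSE)
  r <- sort(r)
  d <- diff(r)
  i <- which.max(d)
  list(gap = d[i], from = r[i], to = r[i + 1])
}
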