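#' Detect plectoneme curve-segments in a mapping run
#'
#' Partitions a go-and-return trace into blockage curve-segments. Descents
#' (runs of decreasing rotation) are located; per-mode noise SDs are
#' estimated from second differences within descents; the migration line is
#' found by an iterative trimmed linear fit (blocked points lie below the
#' line and are trimmed away); and a descent carries a blockage when its
#' heights fall more than `k` noise SDs below the migration line for at
#' least three consecutive steps. Such a descent contributes its whole
#' curve-segment, cut just above the apex (the highest point lying below
#' the line). Curve-segments from different descents are merged when their
#' heights agree where they overlap in rotation (within `k` SD); one that
#' sits below the previous segment's interpolated prediction for three
#' consecutive points, or whose apex lies above the previous segment's
#' top, opens a new segment. Simulated traces carry ground-truth
#' `segment_id` labels against which the detector can be checked.
#'
#' @param trace An `hj_trace` data frame.
#' @param k Detection threshold in noise SDs (default 3).
#' @param min_points Minimum points for a reported segment (default 6).
#' @param min_span Minimum rotation span in turns (default 5).
#' @return A list of segment data frames (columns of `trace` plus
#'   `detected_segment`), ordered by apex rotation (most negative first),
#'   with attribute `noise_sd` (per-mode estimates).
#' @export
detect_segments <- function(trace, k = 3, min_points = 6, min_span = 5) {
  stopifnot(all(c("rotation_turns", "height_um", "mode") %in% names(trace)))
  R <- trace$rotation_turns
  h <- trace$height_um
  mode <- as.character(trace$mode)

  # descents: maximal runs of strictly decreasing rotation
  run <- cumsum(c(TRUE, diff(R) >= 0))
  descents <- split(seq_along(R), run)
  descents <- descents[vapply(descents, length, 1L) >= 3]

  # per-mode noise from second differences (kills the local linear trend)
  noise_sd <- vapply(c("fast", "slow"), function(m) {
    d2 <- unlist(lapply(descents, function(ix) {
      ix <- ix[mode[ix] == m]
      if (length(ix) >= 3) diff(h[ix], differences = 2) else numeric(0)
    }))
    if (length(d2) >= 5) stats::mad(d2) / sqrt(6) else NA_real_
  }, numeric(1))
  if (all(is.na(noise_sd))) noise_sd[] <- 0
  noise_sd[is.na(noise_sd)] <- max(noise_sd, na.rm = TRUE)
  # floor at 0.1% of the typical extension: keeps thresholds meaningful on
  # noiseless synthetic traces, where the trimmed line fit is only exact to
  # the level of its own leverage bias
  sd_pt <- pmax(noise_sd[mode], 1e-3 * median(h), 1e-9)

  # migration line by trimmed iteration: drop points > k SD below the fit
  keep <- rep(TRUE, length(R))
  for (it in 1:25) {
    fit <- lm(h[keep] ~ R[keep])
    pred <- coef(fit)[[1]] + coef(fit)[[2]] * R
    new_keep <- (h - pred) > -k * sd_pt
    if (identical(new_keep, keep)) break
    keep <- new_keep
    if (sum(keep) < 5) { keep <- rep(TRUE, length(R)); break }
  }
  pred_line <- coef(lm(h[keep] ~ R[keep]))[[1]] +
    coef(lm(h[keep] ~ R[keep]))[[2]] * R
  below <- pred_line - h     # positive where the point sits under the line

  # a descent carries a blockage when >= 3 consecutive points sit k SD
  # below the migration line; its curve-segment is the descent cut just
  # above the apex (the highest point lying below the line), so the
  # stringent top of the curve is retained while migration-regime points
  # further up (where the even reference curve no longer applies) are not
  tails <- list()
  for (ix in descents) {
    flag <- below[ix] > k * sd_pt[ix]
    sus <- which(flag & c(flag[-1], FALSE) & c(flag[-(1:2)], FALSE, FALSE))
    if (!length(sus)) next
    cand <- ix[below[ix] > 0]
    R_hat <- if (length(cand) >= 5) {
      estimate_apex(R[cand], h[cand])     # local quadratic, robust to noise
    } else {
      R[cand[which.max(h[cand])]]
    }
    tails[[length(tails) + 1L]] <- ix[R[ix] <= R_hat + 3]
  }
  if (!length(tails)) {
    return(structure(list(), noise_sd = noise_sd))
  }

  # merge tails into segments: compare each tail to the previous segment
  segs <- list(tails[[1]])
  for (tl in tails[-1]) {
    cur <- segs[[length(segs)]]
    o <- order(R[cur])
    prd <- approx(R[cur][o], h[cur][o], xout = R[tl], rule = 1,
                  ties = mean)$y
    comparable <- !is.na(prd)
    dev <- prd[comparable] - h[tl][comparable]
    sd_pool <- median(sd_pt[cur])    # the prediction is itself noisy
    thr <- k * sqrt(sd_pt[tl][comparable]^2 + sd_pool^2)
    lowrun <- dev > thr
    if (sum(comparable) >= 3) {
      new_seg <- any(lowrun & c(lowrun[-1], FALSE) &
                       c(lowrun[-(1:2)], FALSE, FALSE))
    } else {
      # too little overlap to compare heights: a genuinely new blockage
      # has its apex above the previous segment's top, whereas a deeper
      # re-descent of the same blockage extends it downward
      new_seg <- max(R[tl]) > max(R[cur]) + 1
    }
    if (new_seg) segs[[length(segs) + 1L]] <- tl
    else segs[[length(segs)]] <- c(cur, tl)
  }

  out <- lapply(seq_along(segs), function(i) {
    d <- trace[segs[[i]], , drop = FALSE]
    # the noisy fast mode only probes for blockages; when a slow-mode
    # re-acquisition exists it alone carries the curve-segment
    if (sum(d$mode == "slow") >= min_points) {
      d <- d[d$mode == "slow", , drop = FALSE]
    }
    d$detected_segment <- i
    d
  })
  ok <- vapply(out, function(d) {
    nrow(d) >= min_points && diff(range(d$rotation_turns)) >= min_span
  }, logical(1))
  structure(out[ok], noise_sd = noise_sd)
}

#' Weighted residuals of a blockage curve-segment against the reference
#'
#' For each point, the height is divided by `H0 * Ni / N0` to give the
#' relative height, the rotation is shifted by `Ri` and divided by `Ni` to
#' give the relative winding, and the residual relative to the reference
#' curve is multiplied by the weight `exp(3 * (hrel - 1))`, which makes the
#' fit stringent on the top of the curve and tolerant of deviations (e.g.
#' bead-proximity distortion) in the lower part. Points mapping outside the
#' reference domain are excluded and counted.
#'
#' @param segment Data frame with `rotation_turns` and `height_um`.
#' @param Ri Blocking rotation offset (turns).
#' @param Ni Effective turns of the shortened tether (> 0).
#' @param ref An `hj_refcurve`.
#' @return A list with `residuals` (weighted, included points only),
#'   `residuals_um` (the same expressed on the measurement scale, i.e.
#'   multiplied by `H0 * Ni / N0` — the form minimized by
#'   [fit_blockage()]), `raw` (unweighted), `weights`, `included` (logical
#'   over all points), and `n_excluded`.
#' @export
blockage_residuals <- function(segment, Ri, Ni, ref) {
  stopifnot(Ni > 0, inherits(ref, "hj_refcurve"))
  h <- segment$height_um
  R <- segment$rotation_turns
  hrel <- h / (ref$H0 * Ni / ref$N0)
  sig <- (R - Ri) / Ni
  pred <- predict(ref, sig)
  inc <- !is.na(pred) & abs(sig) <= 1
  w <- exp(3 * (hrel - 1))
  list(residuals = ((hrel - pred) * w)[inc],
       residuals_um = ((hrel - pred) * w * (ref$H0 * Ni / ref$N0))[inc],
       raw = (hrel - pred)[inc],
       weights = w[inc],
       included = inc,
       n_excluded = sum(!inc))
}

#' Fit the blocking rotation and effective turns of a curve-segment
#'
#' Estimates `(Ri, Ni)` for one plectoneme curve-segment by minimizing the
#' sum of squared weighted residuals ([blockage_residuals()]) with the
#' Levenberg-Marquardt algorithm. The initial guess is the rotation of the
#' segment's highest point for `Ri` and `N0 - |Ri|` for `Ni`; `Ni` is
#' bounded in `(0, N0]` and `Ri` within the segment's rotation span plus or
#' minus 5 turns. Convergence requires a relative parameter step below
#' 1e-8 within 200 iterations; non-convergence is flagged but parameters
#' are still reported.
#'
#' Because `N0` enters both the reference normalization and the residual
#' scaling, the fitted `Ri` is invariant (to better than 1e-2 turns) under
#' a change of `N0`, with `Ni` absorbing the rescaling.
#'
#' @param segment Data frame with `rotation_turns` and `height_um` (at
#'   least 6 usable points).
#' @param ref An `hj_refcurve`.
#' @param start Optional named vector `c(Ri = , Ni = )` overriding the
#'   default initial guess.
#' @return An object of class `hj_blockfit`: `Ri`, `Ni`, `converged`,
#'   `rss` (weighted residual sum of squares), `n_points`, `n_excluded`,
#'   `boot_sd`/`boot_bias`/`n_boot` (`NA`/0 until [bootstrap_fits()]),
#'   `segment_id`, plus the data and reference needed by its methods.
#' @examples
#' p <- sim_params(noise_sd_slow = 0, seed = 3)
#' ref <- fit_reference(simulate_reference_trace(p), N0 = p$N0)
#' R <- seq(-500, -480, by = 1)
#' seg <- data.frame(rotation_turns = R,
#'                   height_um = blocked_height(R, -480, 720, p))
#' coef(fit_blockage(seg, ref))
#' @export
fit_blockage <- function(segment, ref, start = NULL) {
  stopifnot(inherits(ref, "hj_refcurve"))
  R <- segment$rotation_turns
  h <- segment$height_um
  if (length(R) < 6) stop("segment has fewer than 6 points", call. = FALSE)
  if (is.null(start)) {
    Ri0 <- R[which.max(h)]
    start <- c(Ri = Ri0, Ni = min(max(ref$N0 - abs(Ri0), 1), ref$N0))
  }
  # minimized on the measurement (um) scale: the relative residuals carry a
  # noise scale proportional to 1/Ni, which on noisy data rewards inflating
  # Ni; multiplying by H0 * Ni / N0 removes that spurious gradient while
  # leaving the noiseless optimum unchanged
  fn <- function(par) {
    r <- blockage_residuals(segment, par[1], par[2], ref)
    out <- numeric(length(R))
    out[r$included] <- r$residuals_um
    out
  }
  lm_out <- minpack.lm::nls.lm(
    par = start, fn = fn,
    lower = c(min(R) - 5, 1e-3), upper = c(max(R) + 5, ref$N0),
    control = minpack.lm::nls.lm.control(
      maxiter = 200, ptol = 1e-8, ftol = 1e-12))
  Ri <- lm_out$par[[1]]; Ni <- lm_out$par[[2]]
  rs <- blockage_residuals(segment, Ri, Ni, ref)
  fitted_h <- rep(NA_real_, length(R))
  fitted_h[rs$included] <- (h[rs$included] / (ref$H0 * Ni / ref$N0) -
                              rs$raw) * (ref$H0 * Ni / ref$N0)
  structure(list(Ri = Ri, Ni = Ni,
                 converged = lm_out$info %in% 1:3,
                 info = lm_out$info, message = lm_out$message,
                 rss = sum(rs$residuals_um^2),
                 n_points = sum(rs$included), n_excluded = rs$n_excluded,
                 boot_sd = NA_real_, boot_bias = NA_real_, n_boot = 0L,
                 segment_id = if (!is.null(segment$detected_segment))
                   segment$detected_segment[1] else NA_integer_,
                 segment = segment, fitted = fitted_h,
                 included = rs$included, ref = ref),
            class = "hj_blockfit")
}

#' @export
print.hj_blockfit <- function(x, ...) {
  cat(sprintf(
    "Blockage curve-segment fit: Ri = %.3f turns, Ni = %.1f turns\n",
    x$Ri, x$Ni))
  cat(sprintf("  %d points (%d excluded), weighted RSS %.3g, %s\n",
              x$n_points, x$n_excluded, x$rss,
              if (x$converged) "converged" else "NOT converged"))
  if (x$n_boot > 0) {
    cat(sprintf("  bootstrap (%d reps): SD %.3f turns, bias %+.3f turns\n",
                x$n_boot, x$boot_sd, x$boot_bias))
  }
  invisible(x)
}

#' @export
coef.hj_blockfit <- function(object, ...) {
  c(Ri = object$Ri, Ni = object$Ni)
}

#' @export
residuals.hj_blockfit <- function(object, type = c("weighted", "raw"),
                                  ...) {
  type <- match.arg(type)
  r <- blockage_residuals(object$segment, object$Ri, object$Ni, object$ref)
  if (type == "weighted") r$residuals else r$raw
}

#' Predicted blockage-segment heights at given rotations
#' @param object An `hj_blockfit`.
#' @param rotation Rotations (turns) at which to evaluate the fitted curve.
#' @param ... Unused.
#' @return Heights in um (`NA` outside the reference domain).
#' @export
predict.hj_blockfit <- function(object, rotation = NULL, ...) {
  if (is.null(rotation)) rotation <- object$segment$rotation_turns
  ref <- object$ref
  ref$H0 * object$Ni / ref$N0 *
    predict(ref, (rotation - object$Ri) / object$Ni)
}

#' @export
plot.hj_blockfit <- function(x, ...) {
  R <- x$segment$rotation_turns
  plot(R, x$segment$height_um, xlab = "rotation (turns)",
       ylab = "height (um)", ...)
  Rg <- seq(min(R), max(R), length.out = 200)
  lines(Rg, predict(x, Rg), col = 2)
  abline(v = x$Ri, lty = 3)
  invisible(x)
}

#' Residual-resampling bootstrap of blockage fits
#'
#' Error estimation for the fitted blocking rotations. Un-weighted raw
#' residuals (data minus fit, in um) are pooled from all points in the
#' upper half of the curve-segments (fitted relative height at or above
#' `upper_half`) across all segments of the run. For each replicate,
#' simulated data are built as fitted curve plus residuals resampled with
#' replacement, refitted with the same weighted objective, and the SD and
#' mean shift of the replicate `Ri` values give `boot_sd` and `boot_bias`.
#'
#' @param fits A list of converged [fit_blockage()] results from one run
#'   (a single `hj_blockfit` is accepted).
#' @param n_boot Number of replicates (default 1000).
#' @param seed Optional RNG seed.
#' @param upper_half Relative-height threshold defining the residual pool
#'   (default 0.5).
#' @return The list of fits with `boot_sd`, `boot_bias`, `n_boot` filled.
#' @export
bootstrap_fits <- function(fits, n_boot = 1000, seed = NULL,
                           upper_half = 0.5) {
  if (inherits(fits, "hj_blockfit")) fits <- list(fits)
  stopifnot(all(vapply(fits, inherits, logical(1), "hj_blockfit")),
            n_boot >= 2)
  if (!all(vapply(fits, `[[`, logical(1), "converged"))) {
    stop("bootstrap requires converged fits", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)

  pool <- unlist(lapply(fits, function(f) {
    ref <- f$ref
    hrel_fit <- f$fitted / (ref$H0 * f$Ni / ref$N0)
    sel <- f$included & !is.na(hrel_fit) & hrel_fit >= upper_half
    f$segment$height_um[sel] - f$fitted[sel]
  }))
  if (length(pool) < 10) {
    stop("fewer than 10 pooled upper-half residuals", call. = FALSE)
  }

  for (i in seq_along(fits)) {
    f <- fits[[i]]
    sel <- f$included
    base <- f$fitted[sel]
    seg <- f$segment[sel, , drop = FALSE]
    Ri_rep <- numeric(n_boot)
    for (b in seq_len(n_boot)) {
      seg$height_um <- base + sample(pool, length(base), replace = TRUE)
      refit <- fit_blockage(seg, f$ref, start = c(Ri = f$Ri, Ni = f$Ni))
      Ri_rep[b] <- refit$Ri
    }
    fits[[i]]$boot_sd <- sd(Ri_rep)
    fits[[i]]$boot_bias <- mean(Ri_rep) - f$Ri
    fits[[i]]$n_boot <- as.integer(n_boot)
  }
  fits
}

#' Detect and fit all blockage curve-segments of a run
#'
#' Convenience wrapper: [detect_segments()], [fit_blockage()] on each
#' segment, and optionally [bootstrap_fits()].
#'
#' @param trace An `hj_trace` mapping run.
#' @param ref An `hj_refcurve`.
#' @param k Detection threshold (see [detect_segments()]).
#' @param n_boot Bootstrap replicates; 0 skips the bootstrap.
#' @param seed Optional RNG seed for the bootstrap.
#' @return A list of `hj_blockfit` objects (most negative apex first).
#' @export
fit_blockages <- function(trace, ref, k = 3, n_boot = 0, seed = NULL) {
  segs <- detect_segments(trace, k = k)
  fits <- lapply(segs, function(seg) {
    f <- fit_blockage(seg, ref)
    # refine the apex-side cut: the detector's quadratic apex guess can
    # leave migration-regime points above the blockage, where the even
    # reference curve does not apply; re-cut just above the fitted Ri
    for (pass in 1:2) {
      keep <- seg$rotation_turns <= f$Ri + 3
      if (all(keep) || sum(keep) < 6) break
      seg <- seg[keep, , drop = FALSE]
      f <- fit_blockage(seg, ref, start = coef(f))
    }
    f
  })
  if (n_boot > 0 && length(fits)) {
    fits <- bootstrap_fits(fits, n_boot = n_boot, seed = seed)
  }
  fits
}
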