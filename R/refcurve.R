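#' Estimate the effective tether turns N0 from the migration regime
#'
#' In the migrating-junction regime the extension falls linearly with
#' rotation; a least-squares line through (|R|, height) extrapolated to zero
#' height gives the effective number of helical turns `N0` between the
#' anchoring points.
#'
#' @param trace An `hj_trace` data frame, or any data frame with
#'   `rotation_turns` and `height_um` columns; pass only migration-regime
#'   points (e.g. `segment_id == 0` of a simulated run).
#' @return A list with `N0` (turns), `H0_intercept` (extrapolated height at
#'   zero rotation, um), `N0_se` (delta-method standard error), and `fit`
#'   (the underlying `lm`).
#' @examples
#' p <- sim_params()
#' d <- data.frame(rotation_turns = -(400:460),
#'                 height_um = migration_height(-(400:460), p))
#' estimate_N0(d)$N0   # 1200
#' @export
estimate_N0 <- function(trace) {
  stopifnot(all(c("rotation_turns", "height_um") %in% names(trace)))
  if (nrow(trace) < 5) {
    stop("need at least 5 migration-regime points", call. = FALSE)
  }
  absR <- abs(trace$rotation_turns)
  fit <- lm(trace$height_um ~ absR)
  a <- coef(fit)[[1]]; b <- coef(fit)[[2]]
  if (b >= 0) {
    stop("non-negative slope vs |R|: not a migration regime", call. = FALSE)
  }
  # vcov warns on noiseless (exactly collinear) input; the SE is then 0
  V <- suppressWarnings(stats::vcov(fit))
  N0 <- -a / b
  # delta method on N0 = -a/b
  g <- c(-1 / b, a / b^2)
  se <- sqrt(drop(t(g) %*% V %*% g))
  list(N0 = N0, H0_intercept = a, N0_se = se, fit = fit)
}

# Locate the apex of a bell-shaped trace by a local quadratic fit around the
# coarse maximum (the literal noisy maximum is biased by the noise).
estimate_apex <- function(R, h, window = 10) {
  i0 <- which.max(h)
  sel <- abs(R - R[i0]) <= window
  if (sum(sel) < 5) sel <- rep(TRUE, length(R))
  q <- lm(h[sel] ~ R[sel] + I(R[sel]^2))
  b <- coef(q)
  if (!is.finite(b[[3]]) || b[[3]] >= 0) return(R[i0])
  apex <- -b[[2]] / (2 * b[[3]])
  # keep the estimate inside the searched window
  min(max(apex, R[i0] - window), R[i0] + window)
}

#' Fit the normalized mirror-symmetric reference curve
#'
#' Builds the segmented cubic-spline reference curve from a plectoneme
#' formation trace: heights are divided by `H0`, rotations (relative to the
#' apex, which defines zero rotation) by `N0`, the data are folded to
#' `|sigma|`, and a least-squares piecewise cubic with `n_pieces` uniform
#' knot intervals and a clamped (zero) derivative at `sigma = 0` is fitted,
#' then reflected to negative `sigma`. Evenness is therefore exact by
#' construction. The apex rotation is located by a local quadratic fit and
#' reported as `R_zero_offset`; if a second (end-of-run) reference trace is
#' supplied, the shift between the two apexes is reported as a rotation-skid
#' offset.
#'
#' @param ref_trace An `hj_trace` (or data frame with `rotation_turns`,
#'   `height_um`) spanning both signs of rotation about the apex.
#' @param N0 Effective tether turns (e.g. from [estimate_N0()]).
#' @param H0 Maximum extension (um); estimated from the apex quadratic fit
#'   when `NULL`.
#' @param n_pieces Number of spline pieces over the folded domain
#'   (default 8).
#' @param end_trace Optional re-acquired reference trace; its apex shift
#'   relative to `ref_trace` is reported as `skid_offset` (turns).
#' @return An object of class `hj_refcurve`: a list with `H0`, `N0`,
#'   `R_zero_offset`, `knots` (augmented knot vector in `|sigma|`),
#'   `coef` (B-spline coefficients), `n_pieces`, `sigma_max` (domain bound),
#'   and `skid_offset`. Evaluate it with [predict()][predict.hj_refcurve].
#' @examples
#' p <- sim_params(noise_sd_slow = 0, seed = 2)
#' ref <- fit_reference(simulate_reference_trace(p), N0 = p$N0)
#' predict(ref, 0)   # 1 within fit tolerance
#' @export
fit_reference <- function(ref_trace, N0, H0 = NULL, n_pieces = 8,
                          end_trace = NULL) {
  stopifnot(all(c("rotation_turns", "height_um") %in% names(ref_trace)),
            N0 > 0, n_pieces >= 1)
  R <- ref_trace$rotation_turns
  h <- ref_trace$height_um
  if (nrow(ref_trace) < 2 * n_pieces + 4) {
    stop("fewer points than 2*n_pieces + 4", call. = FALSE)
  }
  R0 <- estimate_apex(R, h)
  if (min(R) > R0 || max(R) < R0) {
    stop("reference trace must span both signs of rotation about the apex",
         call. = FALSE)
  }
  if (is.null(H0)) {
    near <- abs(R - R0) <= max(5, diff(range(R)) / 10)
    H0 <- max(stats::fitted(lm(h[near] ~ R[near] + I(R[near]^2))))
  }
  stopifnot(H0 > 0)

  s <- abs(R - R0) / N0            # folded relative winding
  y <- h / H0
  s_max <- max(s)
  breaks <- seq(0, s_max, length.out = n_pieces + 1)
  knots <- c(rep(0, 3), breaks, rep(s_max, 3))
  B <- splines::splineDesign(knots, s, ord = 4)
  d0 <- splines::splineDesign(knots, 0, ord = 4, derivs = 1)[1, ]
  # null-space reparametrization enforcing f'(0) = 0
  Z <- qr.Q(qr(matrix(d0, ncol = 1)), complete = TRUE)[, -1, drop = FALSE]
  fit <- lm.fit(B %*% Z, y)
  cf <- drop(Z %*% fit$coefficients)

  skid <- NULL
  if (!is.null(end_trace)) {
    R0_end <- estimate_apex(end_trace$rotation_turns, end_trace$height_um)
    skid <- R0_end - R0
  }
  structure(list(H0 = H0, N0 = N0, R_zero_offset = R0, knots = knots,
                 coef = cf, n_pieces = n_pieces, sigma_max = s_max,
                 skid_offset = skid),
            class = "hj_refcurve")
}

#' Evaluate a fitted reference curve
#'
#' @param object An `hj_refcurve` from [fit_reference()].
#' @param sigma Relative winding values; the curve is even, so `|sigma|` is
#'   used.
#' @param ... Unused.
#' @return Relative heights; `NA` outside the fitted domain
#'   `[-sigma_max, sigma_max]` (callers exclude such points rather than
#'   extrapolate).
#' @export
predict.hj_refcurve <- function(object, sigma, ...) {
  s <- abs(sigma)
  out <- rep(NA_real_, length(s))
  ok <- s <= object$sigma_max * (1 + 1e-8)
  if (any(ok)) {
    B <- splines::splineDesign(object$knots, pmin(s[ok], object$sigma_max),
                               ord = 4)
    out[ok] <- drop(B %*% object$coef)
  }
  out
}

#' @export
print.hj_refcurve <- function(x, ...) {
  cat("Normalized plectoneme reference curve (segmented cubic spline)\n")
  cat(sprintf("  H0 = %.3f um, N0 = %.1f turns, apex at R = %.2f turns\n",
              x$H0, x$N0, x$R_zero_offset))
  cat(sprintf("  %d pieces over |sigma| <= %.4f; value at 0: %.4f\n",
              x$n_pieces, x$sigma_max, predict(x, 0)))
  if (!is.null(x$skid_offset)) {
    cat(sprintf("  apex shift vs end-of-run reference: %.2f turns\n",
                x$skid_offset))
  }
  invisible(x)
}

#' @export
plot.hj_refcurve <- function(x, ...) {
  s <- seq(-x$sigma_max, x$sigma_max, length.out = 400)
  plot(s, predict(x, s), type = "l", xlab = "relative winding sigma",
       ylab = "relative height", ...)
  invisible(x)
}

#' Serialize / restore a reference curve
#'
#' The curve is written as JSON (knots, coefficients, `H0`, `N0`, apex
#' offset, domain bound) so a fitted reference can be reused across runs.
#'
#' @param ref An `hj_refcurve`.
#' @param path Output / input file path.
#' @return `read_refcurve` returns the restored `hj_refcurve`;
#'   `write_refcurve` returns `path` invisibly.
#' @export
write_refcurve <- function(ref, path) {
  stopifnot(inherits(ref, "hj_refcurve"))
  obj <- unclass(ref)
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE,
                       null = "null")
  invisible(path)
}

#' @rdname write_refcurve
#' @export
read_refcurve <- function(path) {
  obj <- jsonlite::fromJSON(path)
  need <- c("H0", "N0", "R_zero_offset", "knots", "coef", "n_pieces",
            "sigma_max")
  miss <- setdiff(need, names(obj))
  if (length(miss)) {
    stop("reference-curve file missing fields: ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  obj$knots <- as.numeric(obj$knots)
  obj$coef <- as.numeric(obj$coef)
  if (is.null(obj$skid_offset)) obj["skid_offset"] <- list(NULL)
  structure(obj[c(need, "skid_offset")], class = "hj_refcurve")
}
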