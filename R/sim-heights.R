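#' Plectoneme formation curve of the forward model
#'
#' Generator truth for the bell-shaped rotation-extension curve near zero
#' rotation: relative height as a smooth, even, unimodal function of the
#' relative winding sigma, equal to 1 at sigma = 0 and reaching 0 at
#' |sigma| = 1. The family is a power of a half-cosine,
#' `cos(pi |sigma| / 2) ^ p`, with the exponent calibrated so the curve
#' crosses 1/2 at `|sigma| = plecto_width`. The inference-side spline fit
#' ([fit_reference()]) must recover this shape from data; nothing downstream
#' assumes the functional form.
#'
#' @param sigma Relative winding (rotation divided by `N0`); any numeric
#'   vector.
#' @param plecto_width Half-width at mid-height (see [sim_params()]).
#' @return Relative heights in `[0, 1]`, 0 for `|sigma| >= 1`.
#' @examples
#' reference_shape(0)                      # 1
#' reference_shape(0.025)                  # 0.5 at the default width
#' @export
reference_shape <- function(sigma, plecto_width = 0.025) {
  stopifnot(is.numeric(sigma), plecto_width > 0, plecto_width < 1)
  p <- log(0.5) / log(cos(pi * plecto_width / 2))
  s <- abs(sigma)
  out <- numeric(length(s))
  inside <- s < 1
  out[inside] <- cos(pi * s[inside] / 2)^p
  out
}

#' Extension of a freely migrating Holliday junction
#'
#' In the migration regime the junction absorbs the applied turns and the
#' tether shortens linearly: `h = H0 * (1 - |R| / N0)`. The zero-height
#' intercept at `|R| = N0` is what [estimate_N0()] inverts.
#'
#' @param R Rotation (turns, signed); must satisfy `|R| <= N0`.
#' @param params A [sim_params()] object.
#' @return Height in um.
#' @export
migration_height <- function(R, params) {
  stopifnot(inherits(params, "sim_params"))
  if (any(abs(R) > params$N0)) {
    stop("migration_height: |R| exceeds N0 (", params$N0, " turns)",
         call. = FALSE)
  }
  params$H0 * (1 - abs(R) / params$N0)
}

#' Extension of a blocked junction forming plectonemes
#'
#' Once branch migration is blocked at rotation offset `Ri`, further
#' unwinding is stored as plectonemes in the shortened tether of `Ni`
#' effective turns, and the extension traces a rescaled, shifted copy of the
#' plectoneme formation curve:
#' `h = H0 * (Ni / N0) * reference_shape((R - Ri) / Ni)`.
#' With `Ni = N0 - |Ri|` the apex lies exactly on the migration line, so
#' apexes of successive blockage segments are collinear.
#'
#' @param R Rotation (turns); physically meaningful on the advancing side
#'   (`R <= Ri` for negative unwinding), although the curve itself is even
#'   about `Ri`.
#' @param Ri Blocking rotation offset (turns).
#' @param Ni Effective turns of the shortened tether, in `(0, N0]`.
#' @param params A [sim_params()] object.
#' @return Height in um.
#' @export
blocked_height <- function(R, Ri, Ni, params) {
  stopifnot(inherits(params, "sim_params"))
  if (Ni <= 0 || Ni > params$N0) {
    stop("blocked_height: Ni must be in (0, N0]", call. = FALSE)
  }
  params$H0 * (Ni / params$N0) *
    reference_shape((R - Ri) / Ni, params$plecto_width)
}
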