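#' Fit an exponential waiting-time distribution
#'
#' Characteristic time of mismatch-bypass events. `method = "mle"` uses the
#' exponential maximum-likelihood estimate (the sample mean) with an exact
#' confidence interval from the gamma (chi-squared) distribution of the
#' mean; `method = "histogram"` reproduces a count-based analysis: events
#' are binned (Freedman-Diaconis bin width) and `a * exp(-t / tau)` is
#' fitted to counts versus bin centers by nonlinear least squares.
#'
#' @param times Positive waiting times in seconds (at least 5 events), or a
#'   list with elements `times` and optional `temperature`.
#' @param method `"mle"` (default) or `"histogram"`.
#' @param conf_level Confidence level for the MLE interval (default 0.95).
#' @return A list with `tau` (s), `ci` (two-sided interval; `NA` for the
#'   histogram method when the fit provides none), `n`, `method`, and
#'   `temperature` if supplied.
#' @examples
#' wt <- simulate_waiting_times(200, tau = 19, seed = 1)
#' fit_exponential(wt)$tau
#' @export
fit_exponential <- function(times, method = c("mle", "histogram"),
                            conf_level = 0.95) {
  temperature <- NULL
  if (is.list(times)) {
    temperature <- times$temperature
    times <- times$times
  }
  method <- match.arg(method)
  if (any(times <= 0)) stop("non-positive waiting time", call. = FALSE)
  n <- length(times)
  if (n < 5) stop("need at least 5 events", call. = FALSE)

  if (method == "mle") {
    tau <- mean(times)
    alpha <- 1 - conf_level
    # 2 n tau_hat / tau ~ chi-squared with 2n df
    ci <- 2 * n * tau / qchisq(c(1 - alpha / 2, alpha / 2), df = 2 * n)
  } else {
    bw <- 2 * stats::IQR(times) / n^(1 / 3)
    if (bw <= 0) bw <- diff(range(times)) / ceiling(sqrt(n))
    if (bw <= 0) {                       # degenerate: all times equal
      return(list(tau = times[1], ci = c(NA_real_, NA_real_), n = n,
                  method = method, temperature = temperature))
    }
    breaks <- seq(0, max(times) + bw, by = bw)
    cnt <- table(cut(times, breaks))
    mid <- breaks[-length(breaks)] + bw / 2
    d <- data.frame(t = mid, y = as.numeric(cnt))
    fit <- nls(y ~ a * exp(-t / tau), data = d,
               start = list(a = max(d$y), tau = mean(times)))
    tau <- coef(fit)[["tau"]]
    ci <- tryCatch(suppressMessages(stats::confint(fit, "tau",
                                                   level = conf_level)),
                   error = function(e) c(NA_real_, NA_real_))
    ci <- as.numeric(ci)
  }
  list(tau = tau, ci = ci, n = n, method = method,
       temperature = temperature)
}

#' Arrhenius activation enthalpy from two characteristic times
#'
#' Assuming the bypass rate follows the Arrhenius law, two characteristic
#' times at two temperatures give the activation enthalpy:
#' `Ea / kb = ln(tau1 / tau2) / (1/T1 - 1/T2)` with temperatures in kelvin.
#' The result is reported in units of `kb * T` at a reference temperature
#' (300 K by default) and in kJ/mol.
#'
#' @param tau1,tau2 Characteristic times (s, > 0).
#' @param T1,T2 Temperatures in degrees C (converted internally; pass
#'   kelvin with `celsius = FALSE`).
#' @param reference_T Reference absolute temperature for the `kbT` units
#'   (K, default 300).
#' @param celsius Whether `T1`, `T2` are in degrees C (default TRUE).
#' @return An object of class `arrhenius_result`: `tau_by_T` (named
#'   tau values), `Ea_kbT`, `Ea_kJ_mol`, `reference_T`.
#' @examples
#' arrhenius_enthalpy(19, 30, 3, 37)   # about 80 kbT, about 200 kJ/mol
#' @export
arrhenius_enthalpy <- function(tau1, T1, tau2, T2, reference_T = 300,
                               celsius = TRUE) {
  stopifnot(tau1 > 0, tau2 > 0, reference_T > 0)
  K1 <- if (celsius) T1 + 273.15 else T1
  K2 <- if (celsius) T2 + 273.15 else T2
  if (abs(K1 - K2) < 1e-12) {
    stop("temperatures must differ", call. = FALSE)
  }
  Ea_over_kb <- log(tau1 / tau2) / (1 / K1 - 1 / K2)   # kelvin
  structure(list(tau_by_T = setNames(c(tau1, tau2), c(K1, K2)),
                 Ea_kbT = Ea_over_kb / reference_T,
                 Ea_kJ_mol = Ea_over_kb * .R_gas / 1000,
                 reference_T = reference_T),
            class = "arrhenius_result")
}

#' @export
print.arrhenius_result <- function(x, ...) {
  cat(sprintf(
    "Arrhenius activation enthalpy: %.1f kbT (at %g K) = %.0f kJ/mol\n",
    x$Ea_kbT, x$reference_T, x$Ea_kJ_mol))
  cat("  tau(K):",
      paste(sprintf("%s K: %g s", names(x$tau_by_T), x$tau_by_T),
            collapse = "; "), "\n")
  invisible(x)
}

#' Characteristic time at a new temperature under the Arrhenius law
#'
#' Inverse of [arrhenius_enthalpy()]: scales a characteristic time from a
#' known temperature to another given the activation enthalpy. Used by the
#' simulator to link waiting-time sets across temperatures.
#'
#' @param tau_ref Characteristic time (s) at `T_ref`.
#' @param T_ref,T_new Temperatures (degrees C unless `celsius = FALSE`).
#' @param Ea_kbT Activation enthalpy in `kb * reference_T` units.
#' @param reference_T Reference absolute temperature (K, default 300).
#' @param celsius Whether temperatures are in degrees C.
#' @return The characteristic time at `T_new` (s).
#' @export
arrhenius_tau <- function(tau_ref, T_ref, T_new, Ea_kbT,
                          reference_T = 300, celsius = TRUE) {
  Kr <- if (celsius) T_ref + 273.15 else T_ref
  Kn <- if (celsius) T_new + 273.15 else T_new
  tau_ref * exp(Ea_kbT * reference_T * (1 / Kn - 1 / Kr))
}

#' Tether length with the junction positioned at a locus
#'
#' When the junction sits at a locus `b` bases from the construct center,
#' `2 b` bases reside in the two lateral arms of the junction and the
#' bead-tethering length is `total_bp - 2 b`. The contour length uses a
#' configurable helical rise (default 0.30 nm/bp, matching an 8.4-kb tether
#' to about 2.5 um; the canonical 0.34 nm/bp is selectable).
#'
#' @param total_bp Total construct length (bp).
#' @param locus_bp Locus distance from the construct center (bp).
#' @param rise_per_bp Helical rise (nm/bp, default 0.30).
#' @return A list with `tether_bp` and `tether_nm`.
#' @examples
#' tether_length(13200, 2386)   # about 8.4 kb, about 2.5 um
#' @export
tether_length <- function(total_bp, locus_bp, rise_per_bp = 0.30) {
  stopifnot(total_bp > 0, locus_bp >= 0, rise_per_bp > 0)
  bp <- total_bp - 2 * locus_bp
  if (bp <= 0) stop("locus beyond the construct half-length", call. = FALSE)
  list(tether_bp = bp, tether_nm = bp * rise_per_bp)
}

#' Linear twist-elasticity torque estimate
#'
#' Torque stored by `delta_R` turns applied beyond a blockage in a tether
#' of contour length `L1`, under linear twist elasticity:
#' `gamma = kbT * 2 * pi * |delta_R| * C / L1`. When the estimate exceeds
#' the critical torque `gamma0_critical` (about 10 pN nm, the onset of a
#' structural transition of unwound DNA) it is flagged as beyond-critical:
#' the linear-elasticity value is then not reliable. The plectoneme-regime
#' torque scale (`gamma_plecto`, about 3 pN nm at 0.2 pN) is carried as
#' context.
#'
#' @param delta_R Turns applied beyond the blockage (sign ignored).
#' @param C Twist persistence length (nm, default 95 — the midpoint of the
#'   90-100 nm range).
#' @param L1 Tether contour length (nm, > 0), e.g.
#'   `tether_length(...)$tether_nm`.
#' @param kbT Thermal energy (pN nm, default 4.14 at 300 K).
#' @param gamma0_critical Critical torque (pN nm, default 10).
#' @param gamma_plecto Plectoneme-regime torque scale (pN nm, default 3).
#' @return A list with `gamma` (pN nm), `beyond_critical` (logical), and
#'   the parameters used.
#' @examples
#' torque_estimate(20, L1 = 2500)   # about 20 pN nm, beyond-critical
#' @export
torque_estimate <- function(delta_R, C = 95, L1, kbT = .kbT_300,
                            gamma0_critical = 10, gamma_plecto = 3) {
  if (!(L1 > 0)) stop("L1 must be positive", call. = FALSE)
  stopifnot(C > 0, kbT > 0)
  gamma <- kbT * 2 * pi * abs(delta_R) * C / L1
  list(gamma = gamma, beyond_critical = gamma > gamma0_critical,
       gamma0_critical = gamma0_critical, gamma_plecto = gamma_plecto,
       kbT = kbT, C = C, L1 = L1, delta_R = delta_R)
}
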