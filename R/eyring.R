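# Exchange-rate and activation analysis.  The fitted decay rate of the
# transfer kinetics is R = k_d + R2: dissociation of the transient complex
# plus transverse relaxation of the hydride coherence.  Subtracting an
# assumed R2 gives k_d(T), lifetimes 1/k_d, and - via the Eyring equation
# ln(k_d/T) = ln(kB/h) + dS/R_gas - dH/(R_gas*T) - activation parameters.

#' Dissociation rates and lifetimes from fitted decay rates
#'
#' Decomposes `R(T) = k_d(T) + R2`: `k_d = R - R2` and
#' `lifetime = 1/k_d`.  Standard errors are propagated linearly
#' (`se(k_d) = se(R)`, `se(lifetime) = se(R)/k_d^2`).
#'
#' @param rates data frame with columns `temperature_K`, `R_per_s` and
#'   optionally `se`, or a named numeric vector `c("256" = 3.16, ...)`.
#' @param R2_per_s assumed hydride transverse relaxation rate in 1/s;
#'   the default 1 is the typical order of magnitude for hydride protons.
#'   May be a single value or one per temperature.
#' @return Data frame with columns `temperature_K`, `k_d_per_s`,
#'   `lifetime_s` and (if SEs supplied) `se_k_d`, `se_lifetime`.
#' @export
#' @examples
#' dissociation_rates(c("267" = 7.05))   # k_d = 6.05, lifetime ~ 0.165 s
dissociation_rates <- function(rates, R2_per_s = 1.0) {
  if (is.numeric(rates) && !is.null(names(rates)))
    rates <- data.frame(temperature_K = as.numeric(names(rates)),
                        R_per_s = unname(rates))
  stopifnot(all(c("temperature_K", "R_per_s") %in% names(rates)))
  r2 <- rep_len(R2_per_s, nrow(rates))
  bad <- rates$R_per_s <= r2
  if (any(bad))
    stop("R <= R2 at temperature(s) ",
         paste(rates$temperature_K[bad], collapse = ", "),
         " K: dissociation rate would be non-positive")
  kd <- rates$R_per_s - r2
  out <- data.frame(temperature_K = rates$temperature_K,
                    k_d_per_s = kd, lifetime_s = 1 / kd)
  if ("se" %in% names(rates)) {
    out$se_k_d <- rates$se
    out$se_lifetime <- rates$se / kd^2
  }
  out
}

#' Eyring rate at a temperature
#'
#' Forward Eyring equation
#' `k(T) = (kB*T/h) * exp(-dH/(R_gas*T) + dS/R_gas)`; used to generate
#' rates for round-trip checks of [eyring_fit()].
#'
#' @param temperature_K temperature(s) in kelvin.
#' @param dH_J_per_mol activation enthalpy in J/mol.
#' @param dS_J_per_mol_K activation entropy in J/(mol K).
#' @return Rate(s) in 1/s.
#' @export
eyring_rate <- function(temperature_K, dH_J_per_mol, dS_J_per_mol_K) {
  (.kB * temperature_K / .h_planck) *
    exp(-dH_J_per_mol / (.R_gas * temperature_K) +
        dS_J_per_mol_K / .R_gas)
}

#' Eyring regression of dissociation rates
#'
#' Linear regression of `ln(k_d/T)` on `1/T`:
#' slope `= -dH/R_gas`, intercept `= ln(kB/h) + dS/R_gas` with CODATA
#' constants.  Unweighted by default; supplying `se` uses inverse-variance
#' weights on the log scale (`se(ln k) = se(k)/k`).
#'
#' @param kd data frame with columns `temperature_K`, `k_d_per_s` and
#'   optionally `se_k_d` (as returned by [dissociation_rates()]), or a
#'   named numeric vector `c("256" = 2.16, ...)`.
#' @param weighted use inverse-variance weights when SEs are available.
#' @return An object of class `eyring_result`: `dH_J_per_mol`,
#'   `dS_J_per_mol_K`, `se_dH`, `se_dS`, `k_d` (input table augmented with
#'   fitted rates), `lifetimes`, and `fit` (the underlying `lm`).
#' @export
#' @examples
#' kd <- eyring_rate(c(256, 261, 267), 43400, -64.39)
#' eyring_fit(stats::setNames(kd, c(256, 261, 267)))  # recovers 43.4/-64.39
eyring_fit <- function(kd, weighted = TRUE) {
  if (is.numeric(kd) && !is.null(names(kd)))
    kd <- data.frame(temperature_K = as.numeric(names(kd)),
                     k_d_per_s = unname(kd))
  stopifnot(all(c("temperature_K", "k_d_per_s") %in% names(kd)))
  if (nrow(kd) < 2 || anyDuplicated(kd$temperature_K))
    stop("need at least 2 distinct temperatures")
  if (any(kd$k_d_per_s <= 0))
    stop("all dissociation rates must be positive")
  x <- 1 / kd$temperature_K
  y <- log(kd$k_d_per_s / kd$temperature_K)
  w <- NULL
  if (weighted && "se_k_d" %in% names(kd) &&
      all(is.finite(kd$se_k_d)) && all(kd$se_k_d > 0))
    w <- (kd$k_d_per_s / kd$se_k_d)^2
  fit <- if (is.null(w)) stats::lm(y ~ x) else stats::lm(y ~ x, weights = w)
  co <- stats::coef(fit)
  se <- if (nrow(kd) > 2)
    suppressWarnings(sqrt(diag(stats::vcov(fit)))) else c(NA, NA)
  dH <- -co[[2]] * .R_gas
  dS <- (co[[1]] - log(.kB / .h_planck)) * .R_gas
  kd$k_d_fit <- exp(stats::fitted(fit)) * kd$temperature_K
  structure(list(dH_J_per_mol = dH, dS_J_per_mol_K = dS,
                 se_dH = unname(se[2]) * .R_gas,
                 se_dS = unname(se[1]) * .R_gas,
                 k_d = kd,
                 lifetimes = data.frame(temperature_K = kd$temperature_K,
                                        lifetime_s = 1 / kd$k_d_per_s),
                 fit = fit),
            class = "eyring_result")
}

#' @export
print.eyring_result <- function(x, ...) {
  cat(sprintf(
    "<eyring_result> dH = %.2f kJ/mol, dS = %.2f J/(mol K)\n",
    x$dH_J_per_mol / 1000, x$dS_J_per_mol_K))
  if (is.finite(x$se_dH))
    cat(sprintf("  se(dH) = %.2f kJ/mol, se(dS) = %.2f J/(mol K)\n",
                x$se_dH / 1000, x$se_dS))
  print(x$k_d, row.names = FALSE)
  invisible(x)
}

#' Optimal transfer delay for a coupling
#'
#' Undamped (`R = 0`): the sine maximum `1/(4*J)`.  With decay the signal
#' `sin(2*pi*J*tau)*exp(-2*tau*R)` peaks earlier, at the stationary point
#' `tan(2*pi*J*tau) = pi*J/R`, i.e. `tau = atan(pi*J/R)/(2*pi*J)`.
#'
#' @param J_hz coupling in Hz, `> 0`.
#' @param R_per_s effective decay rate in 1/s; 0 selects the undamped
#'   maximum.
#' @return Optimal delay in seconds.
#' @export
#' @examples
#' optimal_tau(6.55)          # 0.0382 s -> the 38 ms delay
#' optimal_tau(2.69, 1.91)    # 0.0798 s
optimal_tau <- function(J_hz, R_per_s = 0) {
  if (J_hz <= 0) stop("J must be positive")
  stopifnot(R_per_s >= 0)
  if (R_per_s == 0) 1 / (4 * J_hz)
  else atan(pi * J_hz / R_per_s) / (2 * pi * J_hz)
}
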