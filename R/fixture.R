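# Packaged parameter set for the two SABRE-active Ir-pyruvate complexes:
# hydride and carbon chemical shifts, the hydride-hydride coupling, the
# measured |J(1H-13C)| per transfer channel (with and without selective 1H
# decoupling during detection) and the effective decay rate R at the three
# measurement temperatures.  These numbers parameterize the synthetic-data
# generator and all worked examples.

.complex_params <- list(
  list(
    complex_id = 1L,
    shifts_ppm = c(Ha = -29.10, Hb = -27.20, C1 = 168.54, C2 = 206.59),
    j_hh_hz = -10.48, j_hh_se = 0.02,
    channels = data.frame(
      proton = rep(c("Ha", "Hb", "Ha", "Hb"), 2),
      carbon = rep(c("C1", "C1", "C2", "C2"), 2),
      mode   = rep(c("coupled", "decoupled"), each = 4),
      j_hz   = c(0.55, 0.014, 0.93, 0,     # "not observable" channel -> 0
                 0.53, 0.006, 0.99, 0),
      se_hz  = c(0.02, 0.00, 0.08, NA,
                 0.02, 0.00, 0.016, NA)
    ),
    rates = data.frame(
      temperature_K = rep(c(256, 261, 267), 2),
      mode = rep(c("coupled", "decoupled"), each = 3),
      R_per_s = c(3.16, 4.19, 7.05, 2.96, 4.06, 6.73),
      se = c(0.03, 0.04, 0.07, 0.03, 0.04, 0.07)
    )
  ),
  list(
    complex_id = 2L,
    shifts_ppm = c(Ha = -14.97, Hb = -24.08, C1 = 165.15, C2 = 196.86),
    j_hh_hz = -6.55, j_hh_se = 0.01,
    channels = data.frame(
      proton = rep(c("Ha", "Hb", "Ha", "Hb"), 2),
      carbon = rep(c("C1", "C1", "C2", "C2"), 2),
      mode   = rep(c("coupled", "decoupled"), each = 4),
      j_hz   = c(0.32, 0.25, 0.41, 2.69,
                 0.21, 0.025, 0.45, 2.69),
      se_hz  = c(0.03, 0.03, 0.02, 0.002,
                 0.04, 0.33, 0.02, 0.035)
    ),
    rates = data.frame(
      temperature_K = rep(c(256, 261, 267), 2),
      mode = rep(c("coupled", "decoupled"), each = 3),
      R_per_s = c(1.36, 1.56, 1.91, 1.47, 1.58, 1.96),
      se = c(0.05, 0.05, 0.05, 0.06, 0.06, 0.05)
    )
  )
)

#' Packaged parameters of the Ir-pyruvate complexes
#'
#' Returns the measured parameter set for complexes 1 and 2: chemical
#' shifts of the two hydrides (Ha, Hb) and the two pyruvate carbons
#' (C1 carboxylate, C2 ketone), the hydride-hydride coupling, the
#' proton-to-carbon coupling magnitude of each transfer channel (zero for
#' the channel in which no polarization was observed), and the effective
#' decay rate R at 256, 261 and 267 K.  Couplings and rates exist in two
#' detection modes: `"coupled"` (plain carbon read-out) and `"decoupled"`
#' (selective 1H decoupling of the methyl protons during acquisition).
#'
#' @return A list of two objects of class `complex_fixture`, indexable by
#'   complex id.
#' @export
#' @examples
#' fx <- complex_parameters()
#' channel_j(fx[[2]], "Hb", "C2")     # 2.69 Hz
#' fixture_rate(fx[[1]], 267)         # 7.05 1/s
complex_parameters <- function() {
  lapply(.complex_params, function(x) structure(x, class = "complex_fixture"))
}

#' @export
print.complex_fixture <- function(x, ...) {
  cat(sprintf("<complex_fixture> complex [%d], J_HH = %.2f Hz\n",
              x$complex_id, x$j_hh_hz))
  print(x$channels[x$channels$mode == "coupled",
                   c("proton", "carbon", "j_hz")], row.names = FALSE)
  invisible(x)
}

#' Coupling magnitude of one transfer channel
#'
#' @param fixture one element of [complex_parameters()].
#' @param proton,carbon channel labels (`"Ha"`/`"Hb"`, `"C1"`/`"C2"`).
#' @param mode `"coupled"` or `"decoupled"`.
#' @return |J| in Hz (0 for the unobservable channel).
#' @export
channel_j <- function(fixture, proton, carbon, mode = "coupled") {
  ch <- fixture$channels
  row <- ch$proton == proton & ch$carbon == carbon & ch$mode == mode
  if (!any(row)) stop("no such channel: ", proton, "-", carbon)
  ch$j_hz[row]
}

#' Effective decay rate at a temperature
#'
#' @param fixture one element of [complex_parameters()].
#' @param temperature_K one of 256, 261, 267.
#' @param mode `"coupled"` or `"decoupled"`.
#' @return R in 1/s.
#' @export
fixture_rate <- function(fixture, temperature_K, mode = "coupled") {
  r <- fixture$rates
  row <- r$temperature_K == temperature_K & r$mode == mode
  if (!any(row)) stop("no rate at ", temperature_K, " K")
  r$R_per_s[row]
}

#' Three-spin system for one transfer channel of a complex
#'
#' Builds the (Ha, Hb, carbon) spin system used to simulate PASADENA and
#' SEPP-SPINEPT for one complex: shifts from the fixture, the
#' hydride-hydride coupling with its sign, and the channel couplings as
#' magnitudes (the transfer sequences carry no sign information).
#'
#' @param fixture one element of [complex_parameters()].
#' @param carbon `"C1"` or `"C2"`; the 13C spin included in the system.
#' @param field_proton_mhz proton Larmor frequency in MHz.
#' @param mode detection mode for the channel couplings.
#' @return A [spin_system()] with spins `Ha`, `Hb` and the chosen carbon.
#' @export
fixture_spin_system <- function(fixture, carbon = "C2",
                                field_proton_mhz = 400.0,
                                mode = "coupled") {
  stopifnot(carbon %in% c("C1", "C2"))
  spins <- data.frame(
    label = c("Ha", "Hb", carbon),
    isotope = c("H1", "H1", "C13"),
    shift_ppm = c(fixture$shifts_ppm[["Ha"]], fixture$shifts_ppm[["Hb"]],
                  fixture$shifts_ppm[[carbon]])
  )
  jm <- matrix(0, 3, 3, dimnames = list(spins$label, spins$label))
  jm["Ha", "Hb"] <- jm["Hb", "Ha"] <- fixture$j_hh_hz
  jm["Ha", carbon] <- jm[carbon, "Ha"] <- channel_j(fixture, "Ha", carbon, mode)
  jm["Hb", carbon] <- jm[carbon, "Hb"] <- channel_j(fixture, "Hb", carbon, mode)
  spin_system(spins, jm, field_proton_mhz = field_proton_mhz)
}
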