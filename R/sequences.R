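# Pulse-sequence layer: PASADENA read-out, SEPP tau1 kinetics and the
# selective INEPT transfer SEPP-SPINEPT, plus the closed-form amplitude law
# the density-matrix results are tested against.

# tau - 180(targets) - tau echo.  Offsets and couplings to unpulsed spins
# refocus; the mutual J of two pulsed spins evolves for the full 2*tau.
# Damping (if any) acts for the total 2*tau, i.e. exp(-2*tau*rate).
run_echo <- function(state, system, H, tau, targets, damping_rate = 0) {
  state <- evolve(state, H, tau, damping_rate)
  state <- apply_pulse(state, system,
                       pulse_event(targets, 180, 0, duration_s = 0))
  evolve(state, H, tau, damping_rate)
}

#' Simulated PASADENA spectrum of a hydride pair
#'
#' Prepares the parahydrogen-derived two-spin order `Iz(a)Iz(b)`, applies a
#' single hard proton pulse and acquires the 1H spectrum.  The result shows
#' the signature of PASADENA: one antiphase doublet at each hydride shift,
#' split by `|J_ab|`.  The default 45-degree flip maximizes the observable
#' antiphase amplitude (proportional to `sin(flip)*cos(flip)`); at 90
#' degrees the signal vanishes.
#'
#' @param system a [spin_system()] containing the two hydride protons.
#' @param hydride_a,hydride_b labels of the hydride 1H spins.
#' @param flip_deg read-pulse flip angle in degrees.
#' @param npoints,dwell_s,lb_hz acquisition settings, see [acquire()]; by
#'   default the window is sized to the hydride offsets and the digital
#'   resolution kept near 0.03 Hz so sub-Hz splittings stay resolvable.
#' @param decouple labels decoupled during acquisition (e.g. the 13C spin,
#'   mirroring a 1H with 13C-decoupling read-out, so each hydride shows a
#'   clean antiphase doublet split only by the hydride-hydride J).
#' @return An `nmr_spectrum`.
#' @export
#' @examples
#' sys <- spin_system(
#'   data.frame(label = c("Ha", "Hb"), isotope = "H1",
#'              shift_ppm = c(-29.10, -27.20)),
#'   matrix(c(0, -10.48, -10.48, 0), 2, 2))
#' sp <- pasadena_spectrum(sys, "Ha", "Hb", npoints = 2^15, dwell_s = 1/2048)
pasadena_spectrum <- function(system, hydride_a, hydride_b, flip_deg = 45,
                              npoints = NULL, dwell_s = NULL,
                              lb_hz = 0.5, decouple = NULL) {
  if (is.null(dwell_s)) {
    off <- offsets_hz(system)
    h <- system$spins$isotope == "H1"
    span <- 2 * (max(abs(off[h])) + max(abs(system$j_matrix)) + 20)
    dwell_s <- 1 / 2^ceiling(log2(span))
  }
  if (is.null(npoints))
    npoints <- 2^ceiling(log2(1 / (0.03125 * dwell_s)))
  state <- initial_ph2_order(system, hydride_a, hydride_b)
  hydrogens <- system$spins$label[system$spins$isotope == "H1"]
  # read pulse about +y: the antiphase terms it creates are then x-phase,
  # so after zero-order phasing both doublets appear purely absorptive
  state <- apply_pulse(state, system,
                       pulse_event(hydrogens, flip_deg, 90,
                                   duration_s = 0, selective = FALSE))
  acquire(state, system, "H1", npoints = npoints, dwell_s = dwell_s,
          lb_hz = lb_hz, decouple = decouple)
}

#' SEPP tau1 kinetics of a hydride pair
#'
#' Selective excitation of spin S followed by a `tau1 - 180(I,S) - tau1`
#' echo converts the hydride two-spin order into in-phase S magnetization
#' with amplitude `sin(2*pi*J_IS*tau1)`; scanning tau1 therefore maps the
#' proton-proton coupling.  With a nonzero damping rate the amplitude is
#' additionally scaled by `exp(-2*tau1*rate)`.
#'
#' @param system a [spin_system()].
#' @param I_label,S_label hydride 1H labels; S is the selectively excited
#'   spin whose in-phase amplitude is reported.
#' @param tau1_grid nonnegative, increasing vector of tau1 values (s).
#' @param damping_rate uniform decay rate in 1/s applied during the echo.
#' @param coupling_mode Hamiltonian mode, see [build_hamiltonian()].
#' @return Numeric vector of amplitudes (relative to the initial two-spin
#'   order), one per tau1.
#' @export
sepp_kinetics <- function(system, I_label, S_label, tau1_grid,
                          damping_rate = 0, coupling_mode = "weak") {
  if (any(tau1_grid < 0) || is.unsorted(tau1_grid))
    stop("tau1_grid must be nonnegative and increasing")
  H <- build_hamiltonian(system, coupling_mode)
  vapply(tau1_grid, function(tau1) {
    state <- initial_ph2_order(system, I_label, S_label)
    state <- apply_pulse(state, system,
                         pulse_event(S_label, 90, 0, duration_s = 0))
    state <- run_echo(state, system, H, tau1, c(I_label, S_label),
                      damping_rate)
    # in-phase Sx carries the sin(2 pi J tau1) term; normalize by the
    # initial IzSz coefficient (= 1/2 in the 2*IzSz basis)
    2 * do.call(op_coefficient,
                c(list(state, system), stats::setNames(list("x"), S_label)))
  }, numeric(1))
}

#' Specify a SEPP-SPINEPT experiment
#'
#' @param I_label,S_label hydride 1H labels; S is the selectively excited
#'   proton whose coupling to the carbon (`J_SF`) is probed.
#' @param F_label 13C label.
#' @param tau1_s,tau2_s echo half-delays in seconds (total J evolution per
#'   echo is twice the delay).
#' @param damping_rate effective decay rate R (1/s) applied during the tau2
#'   block, matching the kinetic fit model `exp(-2*tau2*R)`.
#' @param damp_tau1 also damp the tau1 block (for sensitivity studies; the
#'   default absorbs tau1-block losses into the fitted amplitude, since
#'   tau1 is fixed within any one kinetics series).
#' @param decouple_methyl decouple all non-hydride protons during
#'   acquisition.
#' @return An object of class `sepp_spinept_spec`.
#' @export
sepp_spinept_spec <- function(I_label, S_label, F_label,
                              tau1_s, tau2_s, damping_rate = 0,
                              damp_tau1 = FALSE, decouple_methyl = FALSE) {
  stopifnot(tau1_s >= 0, tau2_s >= 0, damping_rate >= 0)
  if (identical(I_label, S_label)) stop("I and S must differ")
  structure(list(I_label = I_label, S_label = S_label, F_label = F_label,
                 tau1_s = tau1_s, tau2_s = tau2_s,
                 damping_rate = damping_rate,
                 damp_tau1 = isTRUE(damp_tau1),
                 decouple_methyl = isTRUE(decouple_methyl)),
            class = "sepp_spinept_spec")
}

#' Run the SEPP-SPINEPT transfer sequence
#'
#' Starting from hydride two-spin order `Iz(I)Iz(S)`, executes the
#' selective transfer chain
#' `90(S) - tau1-180(I,S)-tau1 - tau2-180(S,F)-tau2 - 90(S) + 90(F)`.
#' All pulses are ideal selective rotations; each echo refocuses offsets
#' and couplings to passive spins while the marked pair's J evolves for the
#' full `2*tau`.  The carbon-observable outcome is the antiphase term
#' `2*Sz*Fy` with coefficient
#' `sin(2*pi*J_IS*tau1) * sin(2*pi*J_SF*tau2) * exp(-2*tau2*R)`
#' (normalized to the initial two-spin order), the signal model used for
#' all kinetic fits.  The reported amplitude is signed; experimental
#' read-outs determine only its magnitude.
#'
#' @param spec a [sepp_spinept_spec()].
#' @param system a [spin_system()] containing I, S (1H) and F (13C).
#' @param coupling_mode Hamiltonian mode; `"weak"` (default) reproduces the
#'   closed-form amplitude exactly, `"full"` adds strong-coupling
#'   corrections of order `(J_IS/offset-difference)^2`.
#' @param acquire_spectrum also acquire the 13C spectrum of the final
#'   state (antiphase doublet split by `J_SF`).
#' @param npoints,dwell_s,lb_hz acquisition settings when
#'   `acquire_spectrum = TRUE`.
#' @return A list of class `sequence_result`: `final_state`, `amplitude`,
#'   and optionally `spectrum`.
#' @export
sepp_spinept <- function(spec, system, coupling_mode = "weak",
                         acquire_spectrum = FALSE, npoints = 2^14,
                         dwell_s = 0.05, lb_hz = 0.2) {
  stopifnot(inherits(spec, "sepp_spinept_spec"))
  ii <- spin_index(system, spec$I_label)
  is <- spin_index(system, spec$S_label)
  if (!all(system$spins$isotope[c(ii, is)] == "H1"))
    stop("I and S must be 1H spins")
  if (system$spins$isotope[spin_index(system, spec$F_label)] != "C13")
    stop("F must be a 13C spin")
  H <- build_hamiltonian(system, coupling_mode)
  r1 <- if (spec$damp_tau1) spec$damping_rate else 0
  state <- initial_ph2_order(system, spec$I_label, spec$S_label)
  state <- apply_pulse(state, system,
                       pulse_event(spec$S_label, 90, 0, duration_s = 0))
  state <- run_echo(state, system, H, spec$tau1_s,
                    c(spec$I_label, spec$S_label), r1)
  state <- run_echo(state, system, H, spec$tau2_s,
                    c(spec$S_label, spec$F_label), spec$damping_rate)
  state <- apply_pulse(state, system,
                       pulse_event(spec$S_label, 90, 0, duration_s = 0))
  state <- apply_pulse(state, system,
                       pulse_event(spec$F_label, 90, 180, duration_s = 0))
  amp <- 2 * do.call(op_coefficient,
                     c(list(state, system),
                       stats::setNames(list("z", "y"),
                                       c(spec$S_label, spec$F_label))))
  out <- list(final_state = state, amplitude = amp)
  if (acquire_spectrum) {
    decouple <- NULL
    if (spec$decouple_methyl) {
      decouple <- setdiff(
        system$spins$label[system$spins$isotope == "H1"],
        c(spec$I_label, spec$S_label))
      if (length(decouple) == 0) decouple <- NULL
    }
    # the observable is the y-phase antiphase term 2 Sz Fy: a 90-degree
    # receiver phase renders the doublet absorptive
    out$spectrum <- acquire(state, system, "C13", npoints = npoints,
                            dwell_s = dwell_s, lb_hz = lb_hz,
                            coupling_mode = coupling_mode,
                            decouple = decouple, phase_deg = 90)
  }
  class(out) <- "sequence_result"
  out
}

#' @export
print.sequence_result <- function(x, ...) {
  cat(sprintf("<sequence_result> carbon antiphase amplitude = %.6f\n",
              x$amplitude))
  invisible(x)
}

#' Closed-form SEPP-SPINEPT amplitude
#'
#' The analytic amplitude law of the selective transfer:
#' `sin(2*pi*J_IS*tau1) * sin(2*pi*J_SF*tau2) * exp(-2*tau2*R)`.
#' This is both the oracle for the density-matrix sequence and the signal
#' model fitted to measured kinetics.
#'
#' @param J_IS_hz,J_SF_hz couplings in Hz.
#' @param tau1_s,tau2_s echo half-delays in seconds.
#' @param R_per_s effective decay rate in 1/s, `>= 0`.
#' @return Amplitude (signed; magnitude `<= 1`).
#' @export
closed_form_amplitude <- function(J_IS_hz, J_SF_hz, tau1_s, tau2_s,
                                  R_per_s = 0) {
  stopifnot(R_per_s >= 0)
  sin(2 * pi * J_IS_hz * tau1_s) * sin(2 * pi * J_SF_hz * tau2_s) *
    exp(-2 * tau2_s * R_per_s)
}
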