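# exp(-i * theta * G) for Hermitian G, via eigendecomposition.  System sizes
# are <= 4 spins (16 x 16), so dense eigen is both exact and cheap.
unitary_from_generator <- function(G, theta = 1) {
  e <- eigen(G, symmetric = TRUE)
  v <- e$vectors
  v %*% (exp(-1i * theta * e$values) * Conj(t(v)))
}

sandwich <- function(U, m) U %*% m %*% Conj(t(U))

#' Rotating-frame NMR Hamiltonian
#'
#' Builds `H = sum_i 2*pi*offset_i*Iz_i + sum_{i<j} 2*pi*J_ij*(Ii . Ij)` in
#' `"full"` mode, or with the coupling truncated to `2*pi*J_ij*Iz_i*Iz_j` in
#' `"weak"` mode.  Weak coupling is the operative regime for the hydride
#' pairs studied here (offset differences of hundreds of Hz against
#' couplings of a few Hz) and makes the closed-form sequence amplitudes
#' exact.
#'
#' @param system a [spin_system()].
#' @param coupling_mode `"full"` or `"weak"`.
#' @return Hermitian complex matrix in angular-frequency units (rad/s).
#' @export
build_hamiltonian <- function(system, coupling_mode = c("full", "weak")) {
  coupling_mode <- match.arg(coupling_mode)
  n <- n_spins(system)
  off <- offsets_hz(system)
  d <- 2^n
  H <- matrix(0 + 0i, d, d)
  for (i in seq_len(n))
    H <- H + 2 * pi * off[i] * spin_op(n, i, "z")
  J <- system$j_matrix
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (j <= i || J[i, j] == 0) next
    zz <- spin_op(n, i, "z") %*% spin_op(n, j, "z")
    if (coupling_mode == "full") {
      H <- H + 2 * pi * J[i, j] *
        (spin_op(n, i, "x") %*% spin_op(n, j, "x") +
         spin_op(n, i, "y") %*% spin_op(n, j, "y") + zz)
    } else {
      H <- H + 2 * pi * J[i, j] * zz
    }
  }
  H
}

#' Describe an RF pulse
#'
#' Pulses are ideal (zero-duration) rotations restricted to the target
#' spins; `duration_s` is retained only to validate the frequency
#' selectivity assumption (a selective pulse of duration `Delta` cannot
#' distinguish same-isotope spins closer than about `2/Delta` in offset).
#'
#' @param targets character vector of target spin labels.
#' @param flip_deg flip angle in degrees, in (-360, 360].
#' @param phase_deg RF phase in degrees; 0 = x, 90 = y.
#' @param duration_s nominal pulse duration in seconds (default 10 ms, the
#'   selective-pulse length used in the reference measurements).
#' @param selective whether the pulse is frequency-selective.
#' @return An object of class `pulse_event`.
#' @export
pulse_event <- function(targets, flip_deg, phase_deg = 0,
                        duration_s = 0.010, selective = TRUE) {
  stopifnot(is.character(targets), length(targets) >= 1,
            is.numeric(flip_deg), is.numeric(phase_deg),
            duration_s >= 0)
  if (flip_deg <= -360 || flip_deg > 360)
    stop("flip_deg must lie in (-360, 360]")
  structure(list(targets = targets, flip_deg = flip_deg,
                 phase_deg = phase_deg, duration_s = duration_s,
                 selective = isTRUE(selective)),
            class = "pulse_event")
}

#' Apply an RF pulse to a state
#'
#' Rotates the target spins by the flip angle about the axis set by the
#' phase (phase 0 = +x); non-target spins are untouched exactly.  The
#' rotation convention is `90x: Iz -> -Iy` (propagator `exp(-i*theta*Ix)`).
#' A warning (not an error) is raised when a selective pulse with finite
#' duration targets one of two same-isotope spins whose offset difference
#' is below `2/duration_s` - the ideal-selectivity assumption is then
#' violated in practice even though the simulation remains exact.
#'
#' @param state a [quantum_state()].
#' @param system the matching [spin_system()].
#' @param pulse a [pulse_event()].
#' @return The rotated [quantum_state()].
#' @export
apply_pulse <- function(state, system, pulse) {
  n <- n_spins(system)
  if (nrow(state$matrix) != 2^n)
    stop("state dimension does not match system")
  idx <- spin_index(system, pulse$targets)
  if (pulse$selective && pulse$duration_s > 0) {
    off <- offsets_hz(system)
    iso <- system$spins$isotope
    for (i in idx) {
      others <- setdiff(which(iso == iso[i]), idx)
      close <- others[abs(off[others] - off[i]) < 2 / pulse$duration_s]
      if (length(close) > 0)
        warning(sprintf(
          "selective pulse on '%s': spin(s) %s within 2/duration (%.1f Hz); selectivity assumption violated",
          system$spins$label[i],
          paste(system$spins$label[close], collapse = ","),
          2 / pulse$duration_s))
    }
  }
  phi <- pulse$phase_deg * pi / 180
  G <- Reduce(`+`, lapply(idx, function(i)
    cos(phi) * spin_op(n, i, "x") + sin(phi) * spin_op(n, i, "y")))
  U <- unitary_from_generator(G, pulse$flip_deg * pi / 180)
  quantum_state(sandwich(U, state$matrix), system)
}

#' Free evolution under a Hamiltonian
#'
#' Unitary propagation `rho -> U rho U'` with `U = exp(-i*H*t)`.  If
#' `damping_rate` is given, all (non-identity) components are additionally
#' scaled by `exp(-damping_rate * t)`: a uniform exponential loss that
#' implements the effective decay `R = k_d + R2` of a transient complex
#' without a full relaxation superoperator.
#'
#' @param state a [quantum_state()].
#' @param hamiltonian Hermitian matrix from [build_hamiltonian()].
#' @param t evolution time in seconds, `>= 0`.
#' @param damping_rate uniform decay rate in 1/s (default 0).
#' @return The evolved [quantum_state()].
#' @export
evolve <- function(state, hamiltonian, t, damping_rate = 0) {
  if (t < 0) stop("evolution time must be >= 0")
  if (t == 0 && damping_rate == 0) return(state)
  U <- unitary_from_generator(hamiltonian, t)
  m <- sandwich(U, state$matrix)
  if (damping_rate > 0) m <- m * exp(-damping_rate * t)
  # deviation density is traceless, so uniform scaling touches no identity part
  structure(list(matrix = m, labels = state$labels), class = "quantum_state")
}
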