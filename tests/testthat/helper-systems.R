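# Builders shared across the suite.  All fixtures are constructed in code;
# nothing is read from disk.

# Bare hydride pair (1H, 1H) at the given shifts/coupling.
two_proton_system <- function(shift_a = -29.10, shift_b = -27.20,
                              j_hh = -10.48, field = 400) {
  spin_system(
    data.frame(label = c("Ha", "Hb"), isotope = "H1",
               shift_ppm = c(shift_a, shift_b)),
    matrix(c(0, j_hh, j_hh, 0), 2, 2),
    field_proton_mhz = field)
}

# Three-spin (1H, 1H, 13C) transfer system with well-separated offsets.
# offset_scale multiplies the hydride shift separation, to probe the
# weak-coupling limit.
his_system <- function(j_is = -10.48, j_sf = 0.93, j_if = 0,
                       offset_scale = 1, field = 400) {
  mid <- -28.15
  half <- 0.95 * offset_scale
  spins <- data.frame(label = c("Ha", "Hb", "C"),
                      isotope = c("H1", "H1", "C13"),
                      shift_ppm = c(mid - half, mid + half, 206.59))
  jm <- matrix(0, 3, 3, dimnames = list(spins$label, spins$label))
  jm["Ha", "Hb"] <- jm["Hb", "Ha"] <- j_is
  jm["Hb", "C"] <- jm["C", "Hb"] <- j_sf
  jm["Ha", "C"] <- jm["C", "Ha"] <- j_if
  spin_system(spins, jm, field_proton_mhz = field)
}

# Random Hermitian traceless state for property tests.
random_state <- function(system, seed) {
  set.seed(seed)
  d <- 2^nrow(system$spins)
  m <- matrix(stats::rnorm(d * d), d, d) +
    1i * matrix(stats::rnorm(d * d), d, d)
  m <- (m + Conj(t(m))) / 2
  m <- m - diag(Re(sum(diag(m))) / d, d)
  quantum_state(m, system)
}

state_matrix <- function(state) state$matrix
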