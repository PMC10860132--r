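# Operator algebra, Hamiltonians, pulses, evolution and detection.

test_that("weak-coupling Hamiltonian matches explicit diagonal construction", {
  # single on-resonance spin: zero operator
  one <- spin_system(data.frame(label = "S", isotope = "H1", shift_ppm = 0),
                     matrix(0, 1, 1), carrier_ppm = c(H1 = 0))
  expect_lt(max(Mod(build_hamiltonian(one, "weak"))), 1e-12)

  # two spins, offsets +/-380 Hz, J = -10.48: oracle is the diagonal
  # 2*pi*(nu1*m1 + nu2*m2 + J*m1*m2) over m = +/-1/2 in basis order
  # (aa, ab, ba, bb)
  sys <- two_proton_system()
  off <- offsets_hz(sys)
  expect_equal(unname(off[2] - off[1]), 760, tolerance = 1e-12)
  J <- -10.48
  m <- c(0.5, -0.5)
  diag_oracle <- 2 * pi * as.vector(vapply(m, function(m1)
    vapply(m, function(m2) off[[1]] * m1 + off[[2]] * m2 + J * m1 * m2,
           numeric(1)), numeric(2)))
  H <- build_hamiltonian(sys, "weak")
  expect_lt(max(Mod(H - diag(diag_oracle))), 1e-9)
  expect_equal(sort(Re(eigen(H)$values)), sort(diag_oracle),
               tolerance = 1e-12)

  # full mode stays Hermitian, unknown mode errors
  Hf <- build_hamiltonian(sys, "full")
  expect_lt(max(Mod(Hf - Conj(t(Hf)))), 1e-12)
  expect_error(build_hamiltonian(sys, "strong"))
})

test_that("parahydrogen two-spin order has the product-operator form", {
  sys <- two_proton_system()
  st <- initial_ph2_order(sys, "Ha", "Hb")
  expect_lt(max(Mod(state_matrix(st) - diag(c(1, -1, -1, 1) / 4))), 1e-14)

  # extra carbon: same operator tensored with identity, still traceless
  sys3 <- his_system()
  st3 <- initial_ph2_order(sys3, "Ha", "Hb")
  expect_lt(max(Mod(state_matrix(st3) -
                    diag(c(1, -1, -1, 1) / 4) %x% diag(2))), 1e-14)
  expect_lt(Mod(sum(diag(state_matrix(st3)))), 1e-14)

  # IzIz expectation is maximal among rotated two-spin-order directions
  base <- op_coefficient(st, sys, Ha = "z", Hb = "z")
  for (ang in c(20, 45, 90, 133)) {
    rot <- apply_pulse(st, sys, pulse_event("Ha", ang, 30, duration_s = 0))
    expect_lte(op_coefficient(rot, sys, Ha = "z", Hb = "z"), base + 1e-12)
  }

  expect_error(initial_ph2_order(sys, "Ha", "Hx"), "unknown")
  expect_error(initial_ph2_order(his_system(), "Ha", "C"), "1H")
  expect_error(initial_ph2_order(sys, "Ha", "Ha"), "distinct")
})

test_that("pulses follow the rotation convention and respect selectivity", {
  sys <- two_proton_system()
  # 90x on Iz -> -Iy
  n <- 2
  iz <- diag(c(0.5, -0.5))
  iy <- matrix(c(0, 0.5i, -0.5i, 0), 2, 2)
  st <- quantum_state(iz %x% diag(2), sys)
  rot <- apply_pulse(st, sys, pulse_event("Ha", 90, 0, duration_s = 0))
  expect_lt(max(Mod(state_matrix(rot) + iy %x% diag(2))), 1e-12)

  # selective 90 on Hb of IzSz: Ha untouched, Hb z -> -y
  st2 <- initial_ph2_order(sys, "Ha", "Hb")
  rot2 <- apply_pulse(st2, sys, pulse_event("Hb", 90, 0, duration_s = 0))
  expect_lt(max(Mod(state_matrix(rot2) + iz %x% iy)), 1e-12)

  # nonselective 45: antiphase products IySz / IzSy appear with magnitude
  # sin45*cos45 = 0.5 (op_coefficient reports against the normalized
  # 2*IySz basis, i.e. half the bare-product coefficient)
  rot3 <- apply_pulse(st2, sys, pulse_event(c("Ha", "Hb"), 45, 0,
                                            duration_s = 0,
                                            selective = FALSE))
  expect_equal(2 * abs(op_coefficient(rot3, sys, Ha = "y", Hb = "z")), 0.5,
               tolerance = 1e-12)
  expect_equal(2 * abs(op_coefficient(rot3, sys, Ha = "z", Hb = "y")), 0.5,
               tolerance = 1e-12)

  # 360 degrees is the identity
  full <- apply_pulse(st2, sys, pulse_event("Ha", 360, 45, duration_s = 0))
  expect_lt(max(Mod(state_matrix(full) - state_matrix(st2))), 1e-12)

  # selectivity warning: same-isotope neighbor within 2/duration
  close_sys <- two_proton_system(shift_a = -28.2, shift_b = -28.0)  # 80 Hz
  stc <- initial_ph2_order(close_sys, "Ha", "Hb")
  expect_warning(
    apply_pulse(stc, close_sys,
                pulse_event("Ha", 90, 0, duration_s = 0.010)),
    "selectivity")
  # well-separated spins: silent
  expect_silent(
    apply_pulse(st2, sys, pulse_event("Ha", 90, 0, duration_s = 0.010)))
})

test_that("free evolution reproduces product-operator rules and is unitary", {
  # weak J only: Sx -> Sx cos(pi J t) + 2SyIz sin(pi J t)
  sys <- spin_system(
    data.frame(label = c("I", "S"), isotope = "H1", shift_ppm = c(0, 0)),
    matrix(c(0, 8, 8, 0), 2, 2), carrier_ppm = c(H1 = 0))
  H <- build_hamiltonian(sys, "weak")
  sx <- matrix(c(0, 0.5, 0.5, 0), 2, 2)
  st <- quantum_state(diag(2) %x% sx, sys)   # Sx
  for (t in c(0.011, 1 / 32)) {
    ev <- evolve(st, H, t)
    expect_equal(op_coefficient(ev, sys, S = "x"), cos(pi * 8 * t),
                 tolerance = 1e-10)
    expect_equal(op_coefficient(ev, sys, S = "y", I = "z"),
                 sin(pi * 8 * t), tolerance = 1e-10)
  }
  # at t = 1/(2J): purely antiphase
  ev2 <- evolve(st, H, 1 / 16)
  expect_lt(abs(op_coefficient(ev2, sys, S = "x")), 1e-10)

  # t = 0 returns the identical state
  expect_identical(evolve(st, H, 0), st)
  expect_error(evolve(st, H, -1), ">= 0")

  # purity conserved over many random undamped evolutions
  sysr <- two_proton_system()
  Hr <- build_hamiltonian(sysr, "full")
  str <- random_state(sysr, 11)
  p0 <- purity(str)
  set.seed(12)
  for (k in 1:200) str <- evolve(str, Hr, stats::runif(1, 0, 0.05))
  expect_equal(purity(str), p0, tolerance = 1e-10)

  # hermiticity and zero trace preserved throughout
  m <- state_matrix(str)
  expect_lt(max(Mod(m - Conj(t(m)))), 1e-12)
  expect_lt(Mod(sum(diag(m))), 1e-12)

  # damping scales all components
  dmp <- evolve(st, H, 0.1, damping_rate = 3)
  expect_equal(state_matrix(dmp),
               state_matrix(evolve(st, H, 0.1)) * exp(-0.3),
               tolerance = 1e-12)
})

test_that("acquisition gives phased absorptive spectra with correct splittings", {
  one <- spin_system(data.frame(label = "S", isotope = "H1", shift_ppm = 0),
                     matrix(0, 1, 1), carrier_ppm = c(H1 = 0))
  sx1 <- matrix(c(0, 0.5, 0.5, 0), 2, 2)
  st1 <- quantum_state(sx1, one)
  sp1 <- acquire(st1, one, "H1", npoints = 2^12, dwell_s = 1 / 128,
                 lb_hz = 0.5)
  expect_equal(sp1$freq_hz[which.max(sp1$intensity)], 0, tolerance = 0.05)
  expect_gt(max(sp1$intensity), 0)
  # absorptive: no large negative lobe
  expect_lt(abs(min(sp1$intensity)), 0.02 * max(sp1$intensity))
  # in-phase singlet has no sign change -> splitting is undefined
  expect_error(peak_splitting(sp1), "sign change")

  # antiphase 2SxIz with J = 10.48 on a weakly coupled pair (shift
  # difference 400 Hz >> J): extrema separation within 1%
  wsys <- function(j) spin_system(
    data.frame(label = c("I", "S"), isotope = "H1", shift_ppm = c(1, 0)),
    matrix(c(0, j, j, 0), 2, 2), carrier_ppm = c(H1 = 0))
  sx <- matrix(c(0, 0.5, 0.5, 0), 2, 2)
  iz <- diag(c(0.5, -0.5))
  sys <- wsys(10.48)
  st <- quantum_state(2 * iz %x% sx, sys)   # 2 Iz Sx, S on resonance
  sp <- acquire(st, sys, "H1", npoints = 2^15, dwell_s = 1 / 1024,
                lb_hz = 0.5)
  expect_equal(peak_splitting(sp, c(-25, 25)), 10.48,
               tolerance = 0.01 * 10.48)
  # antiphase symmetry: integral vanishes
  expect_lt(abs(sum(sp$intensity)), 1e-8 * max(abs(sp$intensity)))

  # splitting stable in lb once lb <= J/10 (6.55 Hz pair)
  sys2 <- wsys(6.55)
  st2 <- quantum_state(2 * iz %x% sx, sys2)
  sp_fine <- lapply(c(0.1, 0.2, 0.5), function(lb)
    peak_splitting(acquire(st2, sys2, "H1", npoints = 2^16,
                           dwell_s = 1 / 1024, lb_hz = lb), c(-25, 25)))
  expect_equal(sp_fine[[1]], 6.55, tolerance = 0.07)
  expect_equal(sp_fine[[2]], 6.55, tolerance = 0.07)
  expect_lt(abs(sp_fine[[1]] - sp_fine[[2]]) / 6.55, 0.01)

  # guards
  expect_error(acquire(st, sys, "H1", npoints = 1000, dwell_s = 1e-3),
               "power of two")
  big <- two_proton_system()   # offsets +/- 380 Hz
  stb <- initial_ph2_order(big, "Ha", "Hb")
  expect_error(acquire(stb, big, "H1", npoints = 2^10, dwell_s = 1 / 256),
               "Nyquist")
})

test_that("weak and full Hamiltonians agree where shifts dominate couplings", {
  tau1 <- 0.02; tau2 <- 0.15
  spec <- sepp_spinept_spec("Ha", "Hb", "C", tau1_s = tau1, tau2_s = tau2)
  # hydride regime (offset difference / J ~ 73): corrections ~1e-4
  aw <- sepp_spinept(spec, his_system(offset_scale = 1), "weak")$amplitude
  af <- sepp_spinept(spec, his_system(offset_scale = 1), "full")$amplitude
  expect_lt(abs(aw - af), 1e-3)
  # x10 offsets (ratio ~725): corrections fall below 1e-6
  aw10 <- sepp_spinept(spec, his_system(offset_scale = 10), "weak")$amplitude
  af10 <- sepp_spinept(spec, his_system(offset_scale = 10), "full")$amplitude
  expect_lt(abs(aw10 - af10), 1e-6)
})
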