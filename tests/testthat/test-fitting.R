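# Damped-sinusoid estimation, single and global.

test_that("noiseless data are recovered exactly and J = 0 is flagged", {
  d <- generate_dataset(J_hz = 2.69, R_per_s = 1.91, sigma = 0, seed = 1)
  f <- fit_single(d)
  expect_true(f$converged)
  expect_true(f$identifiable)
  expect_equal(unname(coef(f)[["J"]]), 2.69, tolerance = 1e-9)
  expect_equal(unname(coef(f)[["R"]]), 1.91, tolerance = 1e-9)
  expect_equal(unname(coef(f)[["A"]]), 1, tolerance = 1e-9)
  # optimality: residual rms at the optimum cannot exceed the truth's
  expect_lte(f$residual_rms, 1e-10)

  # J = 0, sigma = 0: signal identically zero, A and J trade off freely
  dz <- generate_dataset(J_hz = 0, R_per_s = 1.91, sigma = 0, seed = 1)
  fz <- fit_single(dz)
  expect_false(fz$identifiable)

  # J = 0 with noise: no significant oscillation either
  dn <- generate_dataset(J_hz = 0, R_per_s = 7.05, sigma = 0.02, seed = 3)
  fn <- fit_single(dn)
  expect_false(fn$identifiable)

  expect_error(fit_single(list(tau2_s = 1:3, signal = 1:3)), "6 points")
})

test_that("fitting is invariant under the sign of the generating J", {
  # model parity: (A, J) and (-A, -J) describe the same curve, so negating
  # the data (= flipping J with the matching noise) changes nothing but
  # the sign of A
  for (s in 1:5) {
    dp <- generate_dataset(J_hz = 2.69, R_per_s = 1.91, sigma = 0.02,
                           seed = 40 + s)
    dm <- dp
    dm$signal <- -dp$signal
    fp <- fit_single(dp); fm <- fit_single(dm)
    expect_equal(coef(fp)[["J"]], coef(fm)[["J"]], tolerance = 1e-6)
    expect_equal(fp$residual_rms, fm$residual_rms, tolerance = 1e-8)
    expect_equal(coef(fp)[["A"]], -coef(fm)[["A"]], tolerance = 1e-6)
  }
  # and noiseless generation with either sign recovers the same magnitude
  fp0 <- fit_single(generate_dataset(J_hz = 2.69, R_per_s = 1.91,
                                     sigma = 0, seed = 1))
  fm0 <- fit_single(generate_dataset(J_hz = -2.69, R_per_s = 1.91,
                                     sigma = 0, seed = 1))
  expect_equal(coef(fp0)[["J"]], coef(fm0)[["J"]], tolerance = 1e-9)
})

test_that("replicate means recover the generating parameters", {
  fits <- lapply(1:20, function(s)
    fit_single(generate_dataset(J_hz = 2.69, R_per_s = 1.91, sigma = 0.02,
                                seed = s)))
  js <- vapply(fits, function(f) coef(f)[["J"]], numeric(1))
  rs <- vapply(fits, function(f) coef(f)[["R"]], numeric(1))
  expect_lt(abs(mean(js) - 2.69), 3 * stats::sd(js) / sqrt(20))
  expect_lt(abs(mean(rs) - 1.91), 3 * stats::sd(rs) / sqrt(20))
})

test_that("initializer lands near the truth and flags flat input", {
  d <- generate_dataset(J_hz = 6.55, R_per_s = 1.91, sigma = 0, seed = 1)
  init <- estimate_init(d)
  expect_lt(abs(init[["J"]] - 6.55) / 6.55, 0.2)
  flat <- list(tau2_s = seq(0, 0.6, length.out = 30),
               signal = rep(0, 30))
  expect_equal(estimate_init(flat)[["J"]], 0)
})

test_that("multi-start reaches the optimum a dense start grid finds", {
  worse <- 0
  for (s in 1:15) {
    d <- generate_dataset(J_hz = 6.55, R_per_s = 1.91, sigma = 0.02,
                          seed = 200 + s)
    f <- fit_single(d)
    brute <- min(vapply(seq(0.2, 13, length.out = 25), function(j0)
      fit_single(d, init = c(A = 1, J = j0, R = 2))$sse, numeric(1)))
    if (f$sse > brute + 1e-8) worse <- worse + 1
  }
  expect_lte(worse, 1)
})

test_that("global fit ties parameters and degenerates to single fits", {
  fx <- complex_parameters()
  # three noiseless temperatures sharing J: exact joint recovery
  ds <- lapply(c(256, 261, 267), function(T)
    generate_dataset(J_hz = 0.93, R_per_s = fixture_rate(fx[[1]], T),
                     sigma = 0, seed = 1, complex_id = 1L, proton = "Ha",
                     carbon = "C2", temperature_K = T))
  g <- fit_global(ds)
  expect_true(g$converged)
  expect_equal(g$j_report$J_hz, 0.93, tolerance = 1e-8)
  expect_equal(sort(g$r_report$R_per_s), c(3.16, 4.19, 7.05),
               tolerance = 1e-7)

  # one dataset per group reproduces the single fit
  d1 <- generate_dataset(J_hz = 2.69, R_per_s = 1.91, sigma = 0.02,
                         seed = 7, complex_id = 2L, proton = "Hb",
                         carbon = "C2", temperature_K = 267)
  g1 <- fit_global(list(d1))
  f1 <- fit_single(d1)
  expect_equal(g1$j_report$J_hz, unname(coef(f1)[["J"]]), tolerance = 1e-8)
  expect_equal(g1$r_report$R_per_s, unname(coef(f1)[["R"]]),
               tolerance = 1e-8)

  # a group whose every dataset is zero-signal is unidentifiable
  dz <- lapply(c(256, 267), function(T)
    generate_dataset(J_hz = 0, R_per_s = fixture_rate(fx[[1]], T),
                     sigma = 0.02, seed = T, complex_id = 1L,
                     proton = "Hb", carbon = "C2", temperature_K = T))
  gz <- fit_global(dz)
  expect_false(gz$j_report$identifiable)
})

test_that("sharing across temperatures pools information", {
  fx <- complex_parameters()
  wins <- 0
  for (s in 1:20) {
    ds <- lapply(c(256, 261, 267), function(T)
      generate_dataset(J_hz = 2.69, R_per_s = fixture_rate(fx[[2]], T),
                       sigma = 0.02, seed = s * 10 + T, complex_id = 2L,
                       proton = "Hb", carbon = "C2", temperature_K = T))
    g <- fit_global(ds)
    singles <- vapply(ds, function(d) fit_single(d)$se[["J"]], numeric(1))
    if (is.finite(g$j_report$se) && all(is.finite(singles)) &&
        g$j_report$se < min(singles))
      wins <- wins + 1
  }
  expect_gte(wins, 18)
})

test_that("global-fit bias and interval coverage behave across the fixture", {
  fx <- complex_parameters()
  channels <- list(c(1, "Ha", "C1"), c(1, "Ha", "C2"),
                   c(2, "Ha", "C1"), c(2, "Hb", "C1"),
                   c(2, "Ha", "C2"), c(2, "Hb", "C2"))
  n_rep <- 20
  bias <- numeric(0); hits <- 0; finite <- 0; total <- 0
  for (ch in channels) {
    cid <- as.integer(ch[1])
    J <- channel_j(fx[[cid]], ch[2], ch[3])
    rel <- numeric(n_rep)
    for (i in 1:n_rep) {
      ds <- lapply(c(256, 261, 267), function(T)
        generate_dataset(J_hz = J, R_per_s = fixture_rate(fx[[cid]], T),
                         sigma = 0.02, seed = i * 7 + T,
                         complex_id = cid, proton = ch[2], carbon = ch[3],
                         temperature_K = T))
      g <- fit_global(ds)
      rel[i] <- (g$j_report$J_hz - J) / J
      total <- total + 1
      if (is.finite(g$j_report$se)) {
        finite <- finite + 1
        if (abs(g$j_report$J_hz - J) <= 2 * g$j_report$se) hits <- hits + 1
      }
    }
    bias <- c(bias, stats::median(rel))
  }
  # across-channel median relative bias under 2%
  expect_lt(stats::median(abs(bias)), 0.02)
  # pooled 2-SE coverage near nominal; a small fraction of sub-Hz
  # replicates may collapse onto the A*J ridge (non-finite SE)
  expect_gte(finite / total, 0.85)
  expect_gte(hits / finite, 0.88)
  expect_lte(hits / finite, 0.995)
})
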