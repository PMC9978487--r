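# Worked hand-arithmetic oracles for each process equation, then the
# conservation/monotonicity property suite.

test_that("temperature factor matches hand arithmetic and rejects bad Q10", {
  expect_equal(temperature_factor(10, 2.95), 1)
  expect_equal(temperature_factor(20, 2.95), 2.95)
  expect_equal(temperature_factor(0, 2), 0.5)
  expect_error(temperature_factor(10, 0), "Q10")
  # strictly increasing in T for Q10 > 1
  Ts <- seq(-2, 30, by = 0.5)
  expect_true(all(diff(temperature_factor(Ts, 2.95)) > 0))
})

test_that("biomass partition closes exactly and handles degenerate substrate", {
  st <- partition_biomass(10, 100, 100)
  expect_equal(st$B_DOC, 5)
  expect_equal(st$B_POC, 5)

  st <- partition_biomass(30, 2350, 323)          # low-latitude stock magnitudes
  expect_equal(st$phi_DOC, 2350 / 2673, tolerance = 1e-12)
  expect_equal(st$B_DOC, 26.37, tolerance = 1e-3)
  expect_equal(st$B_POC, 3.625, tolerance = 1e-3)

  st <- partition_biomass(7, 5, 0)
  expect_equal(st$phi_DOC, 1)
  expect_equal(st$B_POC, 0)

  expect_warning(st <- partition_biomass(4, 0, 0), "phi_DOC")
  expect_equal(st$phi_DOC, 0)
  expect_equal(st$B_POC, 4)

  # exact closure on random inputs
  rf <- random_forcings(200)
  st <- partition_biomass(rf$B, rf$DOC, rf$POC)
  expect_identical(st$B_DOC + st$B_POC, st$B)
})

test_that("DOC uptake: half-saturation, saturation limit, worked example", {
  p <- bact_params(mu_max = 2)
  st <- partition_biomass(1, 10, 0)   # B_DOC = 1
  # half-saturation at DOC = X_DOC, T = T_ref
  st2 <- partition_biomass(1, p$X_DOC, 0)
  f <- env_forcing(T_c = 10, DOC = p$X_DOC, POC = 0, z = 10)
  expect_equal(uptake_doc(st2, f, p), 0.5 * p$mu_max * st2$B_DOC)
  # saturation: DOC >= 100 * X_DOC within 1e-4 of mu_max * f_T * B_DOC
  f <- env_forcing(T_c = 17, DOC = 100 * p$X_DOC, POC = 0, z = 10)
  fT <- temperature_factor(17, p$Q10_B)
  expect_equal(uptake_doc(st, f, p), p$mu_max * fT * st$B_DOC,
               tolerance = 1e-4)
  # hand example: mu_max=2, T=20, DOC=2*X -> 2 * 2.95 * 8/9
  f <- env_forcing(T_c = 20, DOC = 2 * p$X_DOC, POC = 0, z = 10)
  expect_equal(uptake_doc(st, f, p), 2 * 2.95 * 8 / 9 * st$B_DOC,
               tolerance = 1e-12)
})

test_that("POC uptake: depth factor, Contois half-saturation, zero limits", {
  p <- bact_params()
  st <- partition_biomass(2, 0, 10)   # all attached
  # depth factor 1 at z = z0 and clamped above z0 (incl. z = 0)
  for (z in c(0, 10, p$z0)) {
    f <- env_forcing(T_c = 10, DOC = 0, POC = 10, z = z)
    r <- bact_rates(st, f, p)
    expect_equal(r$f_depth, 1)
  }
  # (z/z0)^b at depth: z = 2 z0, b = -1 -> 0.5
  p2 <- bact_params(b_exp = -1)
  f <- env_forcing(T_c = 10, DOC = 0, POC = 10, z = 2 * p2$z0)
  expect_equal(bact_rates(st, f, p2)$f_depth, 0.5)
  # Contois half-saturation: POC = X_POC * B_POC -> factor 0.5
  f <- env_forcing(T_c = 10, DOC = 0, POC = p$X_POC * st$B_POC, z = 10)
  expect_equal(bact_rates(st, f, p)$f_POC, 0.5)
  expect_equal(uptake_poc(st, f, p), 0.5 * p$mu_max * st$B_POC)
  # zero when B_POC = 0 or POC = 0
  st0 <- partition_biomass(2, 10, 0)
  expect_equal(uptake_poc(st0, f, p), 0)
  f0 <- env_forcing(T_c = 10, DOC = 0, POC = 0, z = 10)
  expect_equal(uptake_poc(st, f0, p), 0)
})

test_that("respiration: oxic limit, oxygen half-saturation, both modes", {
  p <- bact_params(b_B = 0.01, gamma_a = 0.5)
  st <- partition_biomass(50, 1, 0)
  f <- env_forcing(T_c = 10, DOC = 1, POC = 0, DO = 1e4, z = 10)
  r <- respiration(st, f, p, BCD = 10)
  expect_equal(r$R, 0.01 * 50 + 0.5 * 10, tolerance = 1e-6) # 5.5, BGE 0.45
  f <- env_forcing(T_c = 10, DOC = 1, POC = 0, DO = p$h_o, z = 10)
  expect_equal(respiration(st, f, p, 10)$f_O, 0.5)
  # low-oxygen reading adds respiration at LOW oxygen; printed formula at high
  f_anoxic <- env_forcing(T_c = 10, DOC = 1, POC = 0, DO = 0, z = 10)
  R_low <- respiration(st, f_anoxic, p, 10)$R
  expect_equal(R_low, 0.01 * 50 + (0.5 + p$gamma_o) * 10)
  p_printed <- bact_params(oxygen_mode = "as_printed")
  expect_equal(respiration(st, f_anoxic, p_printed, 10)$R, 0.01 * 50 + 0.5 * 10)
  # floor: R >= b_B * f_T * B always
  rf <- random_forcings(100)
  for (i in seq_len(10)) {
    sti <- partition_biomass(rf$B[i], rf$DOC[i], rf$POC[i])
    fi <- mk_forcing(rf$T_c[i], rf$DOC[i], rf$POC[i], rf$DO[i], rf$Z[i],
                     rf$P[i], rf$z[i])
    expect_gte(respiration(sti, fi, bact_params(), rf$B[i])$R,
               0.01 * temperature_factor(rf$T_c[i], 2.95) * rf$B[i] - 1e-12)
  }
})

test_that("grazing: no prey, half-saturation of total uptake, worked example", {
  p <- bact_params()
  f <- mk_forcing()
  st0 <- partition_biomass(0, 10, 1)
  expect_equal(grazing(st0, f, p)$G, 0)
  # single prey, F_c = h_ZF -> G = 0.5 * r_Z0 * f_T_Z * Z
  p2 <- bact_params(mu_Z = 0.1, h_ZF = 2, delta_ZB = 1)
  # solve e*B = 2 with e = B/(B+0.1): B^2/(B+0.1) = 2 -> B = (2+sqrt(4.8))/2
  Bhs <- (2 + sqrt(4 + 4 * 0.2)) / 2
  sths <- partition_biomass(Bhs, 1, 0)
  fhs <- env_forcing(T_c = 10, DOC = 1, POC = 0, Z = 1.3, P = 0, z = 10)
  expect_equal(grazing(sths, fhs, p2)$G, 0.5 * p2$r_Z0 * 1.3, tolerance = 1e-10)
  # hand example: r_Z0=2, mu_Z=1, B=1, h_ZF=0.5, Z=1 -> G = 1
  p3 <- bact_params(r_Z0 = 2, mu_Z = 1, h_ZF = 0.5, delta_ZB = 1)
  st3 <- partition_biomass(1, 1, 0)
  f3 <- env_forcing(T_c = 10, DOC = 1, POC = 0, Z = 1, P = 0, z = 10)
  gr <- grazing(st3, f3, p3)
  expect_equal(gr$e_ZB, 0.5)
  expect_equal(gr$F_c, 0.5)
  expect_equal(gr$G, 1)
  # bound G <= r_Z0 * f_T_Z * Z on random inputs
  rf <- random_forcings(500)
  st <- partition_biomass(rf$B, rf$DOC + 1e-6, rf$POC)
  fr <- env_forcing(T_c = rf$T_c, DOC = rf$DOC + 1e-6, POC = rf$POC,
                    DO = rf$DO, Z = rf$Z, P = rf$P, z = rf$z)
  G <- grazing(st, fr, p)$G
  expect_true(all(G <= p$r_Z0 * temperature_factor(rf$T_c, p$Q10_Z) * rf$Z + 1e-12))
})

test_that("mortality is linear in biomass with Q10 scaling", {
  p <- bact_params(d_B = 0.05)
  f <- mk_forcing(T_c = 10)
  expect_equal(mortality(partition_biomass(0, 1, 0), f, p), 0)
  expect_equal(mortality(partition_biomass(40, 1, 0), f, p), 2)
  # f_T = 2 via Q10 = 2 at T = 20
  p2 <- bact_params(d_B = 0.05, Q10_B = 2)
  f2 <- mk_forcing(T_c = 20)
  expect_equal(mortality(partition_biomass(40, 1, 0), f2, p2), 4)
})

test_that("rate diagnostics satisfy conservation identities on random inputs", {
  p <- bact_params()
  rf <- random_forcings(2000)
  st <- partition_biomass(rf$B, rf$DOC, rf$POC)
  f <- env_forcing(T_c = rf$T_c, DOC = rf$DOC, POC = rf$POC, DO = rf$DO,
                   Z = rf$Z, P = rf$P, z = rf$z)
  r <- bact_rates(st, f, p)
  expect_rel_equal(r$BCD, r$BCD_DOC + r$BCD_POC)
  expect_rel_equal(r$BP, r$BCD - r$R)
  expect_rel_equal(r$dBdt, r$BP - r$G - r$M)
  ok <- r$BCD > 0
  expect_rel_equal(r$BGE[ok], (r$BP / r$BCD)[ok])
  expect_true(all(is.na(r$BGE[!ok])))
  expect_rel_equal(r$BP_DOC + r$BP_POC, r$BP, tol = 1e-9)
  for (fac in c("f_DOC", "f_POC", "f_depth", "f_O", "e_ZB", "e_ZP"))
    expect_true(all(r[[fac]] >= 0 & r[[fac]] <= 1), info = fac)
  # saturation bound
  fT <- temperature_factor(rf$T_c, p$Q10_B)
  expect_true(all(r$BCD_DOC <= p$mu_max * fT * st$B_DOC + 1e-12))
  # zero biomass -> all rates zero
  r0 <- bact_rates(partition_biomass(0, 5, 5), mk_forcing(), p)
  expect_equal(r0$dBdt, 0)
  expect_equal(r0$BCD + r0$R + r0$G + r0$M, 0)
})

test_that("BCD_DOC is monotone in DOC and T; grazing monotone in Z", {
  p <- bact_params()
  B <- 1
  up <- sapply(seq(0, 50, by = 1), function(doc) {
    st <- partition_biomass(B, doc, 5)
    uptake_doc(st, env_forcing(T_c = 12, DOC = doc, POC = 5, z = 10), p)
  })
  expect_true(all(diff(up) >= -1e-14))
  up_t <- sapply(seq(-2, 30, by = 1), function(tt) {
    st <- partition_biomass(B, 20, 5)
    uptake_doc(st, env_forcing(T_c = tt, DOC = 20, POC = 5, z = 10), p)
  })
  expect_true(all(diff(up_t) > 0))
  g_z <- sapply(seq(0, 3, by = 0.1), function(zz) {
    st <- partition_biomass(B, 20, 5)
    grazing(st, env_forcing(T_c = 12, DOC = 20, POC = 5, Z = zz, P = 1, z = 10), p)$G
  })
  expect_true(all(diff(g_z) >= 0))
})

test_that("integrator reaches steady state, grows without sinks, refines with dt", {
  p <- bact_params()
  f <- mk_forcing()
  out <- bact_integrate(0.5, f, p, mode = "to_steady")
  expect_true(out$converged)
  r <- out$rates
  expect_lt(abs(r$BP - r$G - r$M), 1e-6 * max(out$B, 1e-8) + 1e-12)
  # steady-state BGE identity (oxygen term ~ 0 at DO = 250 but included)
  fT <- temperature_factor(f$T_c, p$Q10_B)
  expect_equal(r$BGE,
               1 - p$gamma_a - p$gamma_o * (1 - r$f_O) -
                 p$b_B * fT * out$B / r$BCD,
               tolerance = 1e-6)
  # no sinks: strictly increasing biomass
  p_ns <- bact_params(d_B = 0)
  f_ns <- mk_forcing(Z = 0)
  tr <- bact_integrate(0.1, f_ns, p_ns, dt = 0.1, mode = "transient",
                       n_steps = 50)
  expect_true(all(diff(tr$trajectory$B) > 0))
  # halving dt moves the converged state by < 0.1% relative
  out2 <- bact_integrate(0.5, f, p, dt = 0.05, mode = "to_steady")
  expect_lt(abs(out2$B - out$B) / out$B, 1e-3)
  # vectorised steady mode matches scalar solves
  fv <- mk_forcing(T_c = c(5, 15), DOC = c(10, 30))
  ov <- bact_integrate(c(0.5, 0.5), fv, p, mode = "to_steady")
  o1 <- bact_integrate(0.5, mk_forcing(T_c = 5, DOC = 10), p, mode = "to_steady")
  expect_equal(ov$B[1], o1$B, tolerance = 1e-4)
})
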