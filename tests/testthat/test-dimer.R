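test_that("scaled couplings obey the anchoring identities", {
  g <- open_sandwich_dimer()
  st <- electronic_states()
  J <- scaled_couplings(g[[1]], g[[2]], st, J_QyQy = 83)
  expect_equal(J["Qy", "Qy"], 83)
  # f = 1 and identical geometry factor: the anchor value itself
  st1 <- electronic_states(c("Qy", "Qx"), f_QxQy = 1)
  g0 <- open_sandwich_dimer(rotations = c(Qy = 0, Qx = 0, By = 0, Bx = 0))
  # with Qx rotated onto the Qy direction, zeta ratio is 1
  gsame <- open_sandwich_dimer(rotations = c(Qy = 0, Qx = -90, By = 0, Bx = 0),
                               skew = 0)
  Jsame <- scaled_couplings(gsame[[1]], gsame[[2]], st1, J_QyQy = 83)
  expect_equal(abs(Jsame["Qx", "Qx"]), 83, tolerance = 1e-9)
  # amplitude ratios enter as the square root of the dipole-strength ratios
  stf <- electronic_states(c("Qy", "Qx"), f_QxQy = 1)
  Jf1 <- scaled_couplings(g[[1]], g[[2]], stf, J_QyQy = 83)
  Jf01 <- scaled_couplings(g[[1]], g[[2]],
                           electronic_states(c("Qy", "Qx"), f_QxQy = 0.1),
                           J_QyQy = 83)
  expect_equal(Jf01["Qx", "Qy"], sqrt(0.1) * Jf1["Qx", "Qy"], tolerance = 1e-12)
  expect_equal(Jf01["Qx", "Qx"], 0.1 * Jf1["Qx", "Qx"], tolerance = 1e-12)
})

test_that("dimer with all couplings zero is the union of the two monomers", {
  p <- minimal_vibronic_params()
  g <- open_sandwich_dimer()
  ma <- assemble_monomer(p, g[[1]])
  mb <- assemble_monomer(p, g[[2]])
  J0 <- scaled_couplings(g[[1]], g[[2]], p$states, J_QyQy = 0)
  d <- assemble_dimer(ma, mb, couplings = J0)
  expect_equal(sort(exciton_states(d)$energies),
               sort(c(exciton_states(ma)$energies,
                      exciton_states(mb)$energies)), tolerance = 1e-10)
})

test_that("two coupled 2-level monomers split by exactly 2J", {
  cfg <- default_config("wscp")
  d <- build_system(cfg, "dimer", "electronic")
  dec <- exciton_states(d)
  expect_equal(dec$energies, c(-83, 83))
  expect_close(abs(dec$A), matrix(1 / sqrt(2), 2, 2), 1e-12)
})

test_that("OPA coupling elements carry Franck-Condon amplitude products", {
  S <- 0.25
  p <- monomer_params(states = electronic_states("Qy"),
                      modes = mode_catalog(1000, S),
                      vc = vc_mode(1500, 0, max_quanta = 0))
  g <- open_sandwich_dimer()
  ma <- assemble_monomer(p, g[[1]]); mb <- assemble_monomer(p, g[[2]])
  J <- matrix(83, 1, 1, dimnames = list("Qy", "Qy"))
  d <- assemble_dimer(ma, mb, couplings = J)
  b <- d$basis
  i00 <- which(b$pigment == 1 & b$mode_quanta == 0)
  j00 <- which(b$pigment == 2 & b$mode_quanta == 0)
  j01 <- which(b$pigment == 2 & b$mode_quanta == 1)
  # 0-0 <-> 0-1 element is sqrt(S) times the 0-0 <-> 0-0 element
  expect_equal(d$H[i00, j01] / d$H[i00, j00], sqrt(S), tolerance = 1e-12)
  expect_equal(d$H[i00, j00], 83 * exp(-S), tolerance = 1e-12)
  # vibronic-coupling-mode quanta do not couple excitonically (undisplaced)
  pv <- monomer_params(states = electronic_states("Qy"),
                       modes = mode_catalog(numeric(), numeric()),
                       vc = vc_mode(1500, 0, max_quanta = 2))
  dv <- assemble_dimer(assemble_monomer(pv, g[[1]]),
                       assemble_monomer(pv, g[[2]]), couplings = J)
  bv <- dv$basis
  iv <- which(bv$pigment == 1 & bv$n_vc == 1)
  expect_true(all(dv$H[iv, bv$pigment == 2] == 0))
})

test_that("zero-zero coupling mask removes vibrationally excited couplings", {
  cfg <- default_config("wscp")
  d_all <- build_system(cfg, "dimer", "vibronic")
  d_00 <- build_system(cfg, "dimer", "zero_zero")
  b <- d_00$basis
  n1 <- sum(b$pigment == 1)
  V <- d_00$H[seq_len(n1), -seq_len(n1)]
  excited <- b$mode_quanta[b$pigment == 1] > 0 | b$n_vc[b$pigment == 1] > 0
  expect_true(all(V[excited, ] == 0))
  V_all <- d_all$H[seq_len(n1), -seq_len(n1)]
  expect_true(any(V_all[b$mode_quanta[b$pigment == 1] > 0, ] != 0))
  expect_error(assemble_dimer(d_all$monomers[[1]], d_all$monomers[[2]],
                              coupling_mask = "bogus"), "unknown coupling mask")
})

test_that("magnetic dipoles are R x mu with the expected symmetries", {
  g <- default_pigment_geometry()  # centered at the origin
  mu <- rbind(c(0, 1, 0), c(1, 0, 0))
  expect_equal(magnetic_dipoles(g, mu), matrix(0, 2, 3))
  g2 <- pigment_geometry(center = c(0, 0, 5))
  expect_equal(magnetic_dipoles(g2, rbind(c(0, 1, 0))),
               rbind(c(-5, 0, 0)))
})

test_that("rotational strengths form a closed exciton couplet", {
  # degenerate homodimer with non-parallel mu at +/- R/2: the two exciton
  # states carry equal and opposite rotational strength (textbook couplet)
  p <- electronic_params()
  ga <- pigment_geometry(center = c(-5, 0, 0), base_y = c(0, 1, 0),
                         rotations = c(Qy = 0))
  gb <- pigment_geometry(center = c(5, 0, 0), base_y = c(0, 1, -0.4),
                         rotations = c(Qy = 0))
  ma <- assemble_monomer(p, ga); mb <- assemble_monomer(p, gb)
  J <- matrix(50, 1, 1, dimnames = list("Qy", "Qy"))
  dec <- exciton_states(assemble_dimer(ma, mb, couplings = J))
  expect_equal(dec$rot[1], -dec$rot[2], tolerance = 1e-12)
  expect_equal(sum(dec$rot), 0, tolerance = 1e-12)
})

test_that("rotational strengths are origin independent and sum to zero", {
  cfg <- default_config("wscp")
  d <- build_system(cfg, "dimer", "vibronic")
  dec <- exciton_states(d)
  expect_equal(sum(dec$rot), 0, tolerance = 1e-9 * sum(abs(dec$rot)))
  # translate every center by a common vector: identical rotational strengths
  shift <- c(3.2, -7.7, 12.1)
  g <- open_sandwich_dimer()
  g1 <- g[[1]]; g1$center <- g1$center + shift
  g2 <- g[[2]]; g2$center <- g2$center + shift
  p <- config_monomer_params(cfg, c("Qy", "Qx"))
  J <- scaled_couplings(g1, g2, p$states)
  dec2 <- exciton_states(assemble_dimer(assemble_monomer(p, g1),
                                        assemble_monomer(p, g2),
                                        couplings = J))
  expect_close(dec$rot, dec2$rot, 1e-8 * max(abs(dec$rot)))
})

test_that("gamma weights are pigment participation measures", {
  d <- wscp_dimer("vibronic")
  dec <- exciton_states(d)
  expect_true(all(diag(dec$gamma) > 0.5 - 1e-12 & diag(dec$gamma) <= 1 + 1e-12))
  expect_true(isSymmetric(dec$gamma, tol = 1e-10))
  # independent check on one entry: sum_a <alpha|P_a|beta>^2
  A <- dec$A
  p1 <- dec$pigment == 1
  s12 <- sum(A[p1, 1] * A[p1, 2])^2 + sum(A[!p1, 1] * A[!p1, 2])^2
  expect_equal(dec$gamma[1, 2], s12, tolerance = 1e-12)
  # identity Hamiltonian: A = identity, local dipoles unchanged
  p <- electronic_params()
  m <- assemble_monomer(p)
  deci <- exciton_states(m)
  expect_equal(deci$A, matrix(1))
  expect_equal(deci$mu_exc, m$mu)
})
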