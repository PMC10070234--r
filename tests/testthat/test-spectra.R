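test_that("one-sided FFT of a damped exponential is a Lorentzian", {
  grid <- spectrum_grid(n_t = 4096, dt_fs = 1)
  w0 <- 500; tau <- 60  # fs
  cc <- 2.99792458e-5
  Ct <- exp(-2i * pi * cc * w0 * grid$t_fs - grid$t_fs / tau)
  s <- fourier_spectrum(Ct, grid, "abs")
  # closed form: Re{ int_0^inf e^{2i pi c (w - w0) t - t/tau} dt } in fs units
  hwhm <- 1 / (2 * pi * cc * tau)
  lor <- tau / (1 + ((grid$freq - w0) / hwhm)^2)
  sel <- abs(grid$freq - w0) < 2000
  expect_close(s[sel], lor[sel], 0.01 * tau)
  expect_equal(grid$freq[which.max(s)], w0, tolerance = grid$freq[2] - grid$freq[1])
})

test_that("Parseval identity: spectrum integrates to C(0)/(2c)", {
  m <- assemble_monomer(minimal_vibronic_params())
  bath <- bath_params()
  grid <- coarse_grid()
  dec <- exciton_states(m)
  ls <- lifetimes(dec, bath)
  cf <- correlation_functions(dec, ls, grid)
  sp <- fourier_spectrum(cf$C_abs, grid, "abs")
  integral <- sum(sp) * (grid$freq[2] - grid$freq[1])
  expect_equal(integral, Re(cf$C_abs[1]) / (2 * 2.99792458e-5),
               tolerance = 1e-3 * abs(integral))
})

test_that("single bright state with no bath structure gives one line at its energy", {
  p <- electronic_params()
  m <- assemble_monomer(p)
  b <- bath_params(s1 = 1e-9, s2 = 1e-9, tau_max_fs = 150)
  sp <- homogeneous_spectrum(m, b, coarse_grid())
  expect_equal(sp$freq[which.max(sp$absorption)], 0,
               tolerance = sp$freq[2] - sp$freq[1] + 1e-9)
  # CD of a single localized state is identically zero
  expect_equal(max(abs(sp$cd)), 0, tolerance = 1e-12)
})

test_that("CD spectrum of an exciton couplet integrates to zero", {
  p <- electronic_params()
  ga <- pigment_geometry(center = c(-5, 0, 0), rotations = c(Qy = 0))
  gb <- pigment_geometry(center = c(5, 0, 0), base_y = c(0.3, 1, -0.5),
                         rotations = c(Qy = 0))
  d <- assemble_dimer(assemble_monomer(p, ga), assemble_monomer(p, gb),
                      couplings = matrix(80, 1, 1, dimnames = list("Qy", "Qy")))
  sp <- suppressWarnings(homogeneous_spectrum(d, bath_params(), coarse_grid()))
  expect_lt(abs(spectrum_integral(sp, "cd")),
            1e-3 * spectrum_integral(sp, "abs_cd"))
  expect_gt(spectrum_integral(sp, "abs_cd"), 0)
})

test_that("total absorption is invariant under coupling masks and disorder", {
  # same state content throughout (full model incl. B states); only the
  # excitonic couplings and the site energies change
  cfg <- default_config("wscp")
  cfg$grid <- list(n_t = 2048, dt_fs = 1)
  grid <- config_grid(cfg)
  bath <- config_bath(cfg)
  variants <- list(
    suppressWarnings(homogeneous_spectrum(build_system(cfg, "dimer", "full"),
                                          bath, grid)),
    suppressWarnings(homogeneous_spectrum(build_system(cfg, "dimer", "zero_zero"),
                                          bath, grid)),
    suppressWarnings(disorder_average(build_system(cfg, "dimer", "full"),
                     disorder_model(n_samples = 25, seed = 7), bath, grid)))
  areas <- vapply(variants, spectrum_integral, numeric(1), what = "absorption")
  expect_lt(max(abs(areas - areas[1])) / areas[1], 0.005)
})

test_that("CD vanishes identically when all couplings are zero", {
  cfg <- default_config("wscp")
  cfg$coupling$J_QyQy <- 0
  cfg$grid <- list(n_t = 1024, dt_fs = 2)
  sp <- homogeneous_spectrum(build_system(cfg, "dimer", "vibronic"),
                             config_bath(cfg), config_grid(cfg))
  expect_equal(max(abs(sp$cd)), 0, tolerance = 1e-10 * max(sp$absorption))
})

test_that("disorder with zero FWHM reproduces the homogeneous spectrum", {
  cfg <- default_config("wscp")
  sys <- build_system(cfg, "dimer", "qx")
  grid <- coarse_grid()
  bath <- config_bath(cfg)
  hom <- suppressWarnings(homogeneous_spectrum(sys, bath, grid))
  dis <- suppressWarnings(disorder_average(
    sys, disorder_model(fwhm = c(Qy = 0, Qx = 0), n_samples = 3, seed = 1),
    bath, grid))
  expect_close(hom$absorption, dis$absorption, 1e-10 * max(hom$absorption))
  expect_close(hom$cd, dis$cd, 1e-10 * max(abs(hom$cd)))
})

test_that("pure site disorder of one line reproduces the Gaussian FWHM", {
  # single electronic state, (near) zero homogeneous broadening, FWHM 240
  p <- electronic_params()
  m <- assemble_monomer(p)
  # negligible Lorentzian width (tau cap at 100 ps); the ensemble-averaged
  # correlation function is damped by the disorder Gaussian itself
  b <- bath_params(s1 = 1e-9, s2 = 1e-9, tau_max_fs = 1e5)
  grid <- spectrum_grid(n_t = 2048, dt_fs = 2)
  dis <- disorder_model(fwhm = c(Qy = 240), n_samples = 5000, seed = 42)
  # finite-sample noise leaves a ~1/sqrt(N) floor in the averaged
  # correlation function; the truncated-tail warning is expected here
  sp <- suppressWarnings(disorder_average(m, dis, b, grid))
  half <- max(sp$absorption) / 2
  above <- range(sp$freq[sp$absorption > half])
  fw <- diff(above) + (sp$freq[2] - sp$freq[1])
  expect_equal(fw, 240, tolerance = 12)
  # the Gaussian top is flat on the grid scale; Monte-Carlo noise can move
  # the argmax by a couple of bins
  expect_lt(abs(sp$freq[which.max(sp$absorption)]), 25)
  # Monte-Carlo noise decays as 1/sqrt(N): the spread between independent
  # runs at N = 4000 is ~4x smaller than at N = 250
  run <- function(n, seed) {
    suppressWarnings(disorder_average(
      m, disorder_model(fwhm = c(Qy = 240), n_samples = n, seed = seed),
      b, grid))$absorption
  }
  e250 <- sqrt(mean((run(250, 1) - run(250, 2))^2))
  e4000 <- sqrt(mean((run(4000, 3) - run(4000, 4))^2))
  expect_gt(e250 / e4000, 2)
})

test_that("identical config and seed give byte-identical spectra", {
  cfg <- default_config("wscp")
  sys <- build_system(cfg, "dimer", "qx")
  grid <- coarse_grid()
  bath <- config_bath(cfg)
  dis <- disorder_model(n_samples = 5, seed = 99)
  s1 <- disorder_average(sys, dis, bath, grid)
  s2 <- disorder_average(sys, dis, bath, grid)
  expect_identical(s1$absorption, s2$absorption)
  expect_identical(s1$cd, s2$cd)
  s3 <- disorder_average(sys, disorder_model(n_samples = 5, seed = 100),
                         bath, grid)
  expect_false(identical(s1$absorption, s3$absorption))
})

test_that("monomer spectrum from the dimer code with J = 0 equals twice the monomer", {
  cfg <- default_config("wscp")
  p <- config_monomer_params(cfg, c("Qy", "Qx"))
  g <- open_sandwich_dimer()
  ma <- assemble_monomer(p, g[[1]]); mb <- assemble_monomer(p, g[[2]])
  J0 <- scaled_couplings(g[[1]], g[[2]], p$states, J_QyQy = 0)
  d <- assemble_dimer(ma, mb, couplings = J0)
  grid <- coarse_grid(); bath <- config_bath(cfg)
  sd <- homogeneous_spectrum(d, bath, grid)
  sa <- homogeneous_spectrum(ma, bath, grid)
  sb <- homogeneous_spectrum(mb, bath, grid)
  expect_close(sd$absorption, sa$absorption + sb$absorption,
               1e-10 * max(sd$absorption))
  expect_equal(max(abs(sd$cd)), 0, tolerance = 1e-10 * max(sd$absorption))
})

test_that("spectrum results print, convert and integrate", {
  m <- assemble_monomer(electronic_params())
  sp <- homogeneous_spectrum(m, bath_params(), coarse_grid())
  df <- as.data.frame(sp)
  expect_named(df, c("wavenumber", "absorption", "cd"))
  expect_output(print(sp), "homogeneous")
  path <- withr::local_tempfile(fileext = ".tsv")
  write_spectrum(sp, path)
  back <- utils::read.table(path, header = TRUE, sep = "\t", check.names = FALSE)
  expect_equal(back[["absorption"]], sp$absorption, tolerance = 1e-6)
  expect_true(file.exists(paste0(path, ".json")))
})

test_that("site-energy disorder localizes the sideband exciton states", {
  # the mechanism behind the loss of high-energy CD: the excitonic
  # couplings of vibrationally excited transitions are Franck-Condon
  # suppressed to a few cm^-1, so static disorder localizes those states
  # and their rotational strengths collapse realization by realization
  cfg <- default_config("wscp")
  sys <- build_system(cfg, "dimer", "vibronic")
  bath <- config_bath(cfg)
  sideband_rot <- function(dec) {
    dom <- apply(dec$A^2, 2, which.max)
    b <- dec$basis
    is00 <- b$electronic[dom] == "Qy" & b$n_vc[dom] == 0 & b$mode_quanta[dom] == 0
    sum(abs(dec$rot[!is00]))
  }
  hom <- sideband_rot(exciton_states(sys))
  set.seed(31)
  pig <- sys$basis$pigment
  sig <- c(Qy = 72.2, Qx = 144.4)  # sigma for FWHM 170 / 340
  per_real <- replicate(20, {
    sh <- matrix(rnorm(4, 0, rep(sig, each = 2)), 2, 2,
                 dimnames = list(NULL, names(sig)))
    H <- sys$H
    diag(H) <- diag(H) + sh[cbind(pig, match(sys$basis$electronic,
                                             colnames(sh)))]
    sideband_rot(vibronicCD:::decompose_system(H, sys$mu, sys$m, pig,
                                               sys$basis))
  })
  expect_lt(mean(per_real), hom / 2)
})
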