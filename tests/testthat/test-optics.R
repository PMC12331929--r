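test_that("heated focal profile has the calibrated FWHMs and scaling", {
  o <- optics_config(na = 0.4, wavelength_nm = 1300)
  ff <- focal_field(o, pitch_um = 0.1)
  heated <- ff$intensity^o$n_photon
  ix0 <- which(ff$offsets_um$x == 0)
  iz0 <- which(ff$offsets_um$z == 0)
  lat <- heated[, ix0, iz0]
  ax <- heated[ix0, ix0, ]
  expect_equal(profile_fwhm(ff$offsets_um$x, lat), 2.2, tolerance = 0.01)
  expect_equal(profile_fwhm(ff$offsets_um$z, ax), 30, tolerance = 0.01)
  expect_equal(max(ff$intensity), 1)
  # NA scaling of the derived widths
  o8 <- optics_config(na = 0.8)
  expect_equal(o8$w_xy_um, 1.1)
  expect_equal(o8$w_z_um, 7.5)
})

test_that("airy lateral option matches the Gaussian heated FWHM", {
  o <- optics_config(lateral_profile = "airy")
  ff <- focal_field(o, pitch_um = 0.05)
  heated <- ff$intensity^3
  ix0 <- which(ff$offsets_um$x == 0)
  iz0 <- which(ff$offsets_um$z == 0)
  expect_equal(profile_fwhm(ff$offsets_um$x, heated[, ix0, iz0]), 2.2,
               tolerance = 0.02)
})

test_that("heated-volume integral matches the closed-form Gaussian value", {
  o <- optics_config()
  ff <- focal_field(o, pitch_um = 0.2,
                    extent_um = c(5 * o$w_xy_um, 5 * o$w_xy_um, 5 * o$w_z_um))
  num <- sum(ff$intensity^3) * ff$pitch_um^3
  closed <- (pi / (4 * log(2)))^1.5 * o$w_xy_um^2 * o$w_z_um
  expect_lt(abs(num - closed) / closed, 0.005)
})

test_that("too-coarse focal sampling is rejected", {
  expect_error(focal_field(optics_config(), pitch_um = 1), "coarse")
})

test_that("depth transmission follows Beer-Lambert exactly", {
  expect_equal(depth_transmission(0, 123), 1)
  expect_equal(depth_transmission(250, 250), exp(-1))
  expect_equal(depth_transmission(2700, 50), 3.5e-24, tolerance = 0.01)
  # multiplicative over path segments, monotone decreasing
  z1 <- 130; z2 <- 412
  expect_equal(depth_transmission(z1 + z2, 250),
               depth_transmission(z1, 250) * depth_transmission(z2, 250))
  z <- seq(0, 1000, by = 50)
  expect_true(all(diff(depth_transmission(z, 250)) < 0))
  expect_error(depth_transmission(-1, 50), ">= 0")
})

test_that("absorbed heat matches a brute-force per-voxel oracle", {
  ph <- phantom(array(stats::runif(6 * 6 * 8, 0, 12), c(6, 6, 8)),
                pitch_um = 1, medium = "brain")
  o <- optics_config(w_xy_um = 4, w_z_um = 8)  # wide focus, voxel-resolvable
  ch <- chromophore()
  ff <- focal_field(o, pitch_um = 1, extent_um = c(4, 4, 6))
  H <- absorbed_energy_density(ph, ff, o, ch, focus_um = c(3, 3, 4))
  # independent oracle: explicit loop over field voxels with its own formula
  pf <- peak_flux(o)
  eta <- 1 - ch$phi * o$wavelength_nm / (3 * ch$lambda_em_nm)
  H_oracle <- array(0, dim(ph$concentration))
  off <- ff$offsets_um
  for (i in seq_along(off$x)) for (j in seq_along(off$y))
    for (k in seq_along(off$z)) {
      ix <- round((3 + off$x[i]) / 1 + 0.5)
      iy <- round((3 + off$y[j]) / 1 + 0.5)
      iz <- round((4 + off$z[k]) / 1 + 0.5)
      if (ix < 1 || ix > 6 || iy < 1 || iy > 6 || iz < 1 || iz > 8) next
      Tz <- exp(-((iz - 0.5) * 1) / ph$medium$L_I_um)
      H_oracle[ix, iy, iz] <-
        ph$concentration[ix, iy, iz] * 6.02214076e23 * ch$sigma_n *
        (pf$flux * Tz * ff$intensity[i, j, k])^3 *
        (o$pulse_width_fs * 1e-15) * eta * 3 * pf$E_photon
    }
  expect_equal(H, H_oracle, tolerance = 1e-12)
})

test_that("heat is linear in concentration and cubic in power", {
  o <- optics_config()
  ch <- chromophore()
  ff <- focal_field(o, pitch_um = 0.5, extent_um = c(4, 4, 8))
  mk <- function(c_mM) phantom(array(c_mM, c(16, 16, 24)), 0.5, "gel")
  H1 <- absorbed_energy_density(mk(3), ff, o, ch, focus_um = c(4, 4, 6))
  H2 <- absorbed_energy_density(mk(6), ff, o, ch, focus_um = c(4, 4, 6))
  expect_equal(H2, 2 * H1, tolerance = 1e-12)
  expect_true(all(absorbed_energy_density(mk(0), ff, o, ch) == 0))
  o2 <- o; o2$power_mw <- 2 * o$power_mw
  H8 <- absorbed_energy_density(mk(3), ff, o2, ch, focus_um = c(4, 4, 6))
  expect_equal(H8, 8 * H1, tolerance = 1e-12)
})

test_that("log signal vs log power slope equals the photon order", {
  powers <- c(6, 10, 16, 25)
  for (n_ph in c(2L, 3L)) {
    sig <- vapply(powers, function(p) {
      o <- optics_config(power_mw = p, n_photon = n_ph)
      ph <- uniform_slab(conc = 5, side_um = 40, depth_um = 60, pitch_um = 4)
      ff <- focal_field(o, pitch_um = 0.5)
      fluorescence_signal(ph, NULL, o, chromophore(), focus_um = c(20, 20, 30))
    }, numeric(1))
    fit <- fit_power_law(powers, sig)
    expect_equal(unname(fit$estimates[["exponent"]]), n_ph, tolerance = 1e-9)
  }
})

test_that("fluorescence vanishes with zero quantum yield and decays with the
           emission extinction length", {
  o <- optics_config()
  ph <- uniform_slab(conc = 5, side_um = 40, depth_um = 400, pitch_um = 4,
                     medium = "brain")
  expect_equal(
    fluorescence_signal(ph, NULL, o, chromophore(phi = 0),
                        focus_um = c(20, 20, 100)),
    0)
  # with excitation attenuation off, the depth ratio is the pure emission
  # escape factor exp(-z/L_em)
  med <- medium_preset("brain"); med$L_I_um <- 1e9
  ph2 <- phantom(ph$concentration, ph$pitch_um, med)
  s100 <- fluorescence_signal(ph2, NULL, o, chromophore(),
                              focus_um = c(20, 20, 100))
  s150 <- fluorescence_signal(ph2, NULL, o, chromophore(),
                              focus_um = c(20, 20, 150))
  expect_equal(s150 / s100, exp(-50 / 50), tolerance = 1e-6)
})

test_that("derived heat fraction is energy conserving (~0.952 at defaults)", {
  expect_equal(heat_fraction(chromophore(), optics_config()),
               1 - 0.05 * 1300 / (3 * 450), tolerance = 1e-12)
  expect_equal(heat_fraction(chromophore(), optics_config()), 0.9519,
               tolerance = 1e-3)
})
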