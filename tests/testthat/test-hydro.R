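two_layer_cast <- function(mld = 20, dz = 1, depth_max = 60,
                           s_top = 22, s_bot = 24) {
  z <- seq(0, depth_max, by = dz)
  data.frame(depth = z, sigma_theta = ifelse(z <= mld, s_top, s_bot))
}

test_that("buoyancy frequency matches finite-difference closed forms", {
  # uniform density: no stratification
  u <- data.frame(depth = 0:30, sigma_theta = 23)
  expect_true(all(buoyancy_frequency(u)$n2 == 0))
  # a step at 20 m gives a single spike at the interface midpoint
  tl <- two_layer_cast()
  bv <- buoyancy_frequency(tl)
  spike <- which(bv$n2 > 0)
  expect_length(spike, 1)
  expect_equal(bv$depth[spike], 20.5)
  expect_equal(bv$n2[spike], (9.81 / 1025) * 2 / 1)
  # linear profile: constant N2 equal to (g/rho0) * slope
  lin <- data.frame(depth = seq(0, 100, 5),
                    sigma_theta = 21 + 0.03 * seq(0, 100, 5))
  n2 <- buoyancy_frequency(lin)$n2
  expect_equal(n2, rep((9.81 / 1025) * 0.03, length(n2)),
               tolerance = 1e-12)
  expect_error(buoyancy_frequency(u[1:2, ]))
  expect_error(buoyancy_frequency(data.frame(depth = c(0, 5, 5),
                                             sigma_theta = 1:3)),
               "increasing")
})

test_that("mixed-layer depth takes the primary buoyancy maximum", {
  expect_equal(mixed_layer_depth(buoyancy_frequency(two_layer_cast())),
               20.5)
  # monotone N2: deepest midpoint wins
  expect_equal(mixed_layer_depth(seq(0.001, 0.01, length.out = 10),
                                 seq(5, 50, 5)), 50)
  # constant positive N2: shallowest midpoint by the tie rule
  expect_equal(mixed_layer_depth(rep(0.004, 5), c(5, 10, 15, 20, 25)), 5)
  expect_warning(m <- mixed_layer_depth(rep(0, 4), 1:4), "undefined")
  expect_true(is.na(m))
})

test_that("cline depths follow the surface-exceedance and interpolation rules", {
  expect_equal(cline_depth(c(0, 10, 20), c(1.5, 2, 3), 1), 0)
  expect_equal(cline_depth(c(10, 20), c(0.5, 1.5), 1), 15)
  expect_true(is.na(cline_depth(c(0, 50), c(0.2, 0.8), 1)))
  # a zero threshold is met at the surface of any non-negative profile
  expect_equal(cline_depth(c(0, 10), c(0, 5), 0), 0)
  # first crossing wins even if the profile later dips
  expect_equal(cline_depth(c(0, 10, 20, 30), c(0, 2, 0.5, 2), 1), 5)
})

test_that("the nitrate availability index reproduces all three branches", {
  rich <- data.frame(depth = c(0, 50), nox = c(2.4, 8))
  expect_equal(nai(rich), 2.4)
  mid <- data.frame(depth = c(0, 40, 60), nox = c(0.2, 1.0, 3.0))
  expect_equal(nai(mid), -50)
  poor <- data.frame(depth = c(0, 60, 120), nox = c(0.2, 0.5, 1.5))
  expect_equal(nai(poor), -120)
  # explicit bottom depth overrides the deepest sampled level
  poor$bottom_depth <- 150
  expect_equal(nai(poor), -150)
  expect_true(is.na(nai(data.frame(depth = 0, nox = NA))))
})

test_that("oxygen solubility is monotone and matches the published check value", {
  expect_lt(o2_saturation(25, 35), o2_saturation(15, 35))
  expect_lt(o2_saturation(20, 36), o2_saturation(20, 34))
  # combined-fit check value: 274.61 umol/kg at T = 10, S = 35
  expect_equal(o2_saturation(10, 35) * 1000 / 1.025, 274.61,
               tolerance = 1e-3)
  expect_warning(o2_saturation(45, 35), "fit range")
})

test_that("plume thickness interpolates the 35-salinity horizon", {
  oceanic <- data.frame(depth = c(0, 50), salinity = c(36, 36.5))
  expect_true(is.na(plume_thickness(oceanic)))
  pl <- data.frame(depth = c(0, 10, 20), salinity = c(30, 30, 36))
  expect_equal(plume_thickness(pl), 10 + 10 * 5 / 6)
  fresh <- data.frame(depth = c(0, 80), salinity = c(20, 30))
  th <- plume_thickness(fresh)
  expect_equal(as.numeric(th), 80)
  expect_true(isTRUE(attr(th, "censored")))
})

test_that("station_features assembles the predictor vector and tolerates gaps", {
  cast <- gen_ctd_cast(mld = 20, nox_surface = 0.1)
  f <- station_features(cast$ctd, cast$nutrients, surface_chla = 0.4)
  expect_equal(f$mld, 20, tolerance = 1)  # within one grid step
  expect_true(all(is.finite(unlist(f))))
  expect_equal(f$surface_chla, 0.4)
  expect_lt(f$nai, 0)
  # oceanic cast where NOx never reaches 2 uM: NAI = -bottom
  oc <- gen_ctd_cast(mld = 70, sal_surface = 36, sal_deep = 36.5,
                     nox_surface = 0.1, nox_deep = 1.5, depth_max = 120)
  fo <- station_features(oc$ctd, oc$nutrients)
  expect_equal(fo$nai, -120)
  expect_true(is.na(fo$plume_thickness))  # surface already >= 35
  # missing oxygen sensor leaves oxygen features missing, others valid
  ctd2 <- cast$ctd[, setdiff(names(cast$ctd), "oxygen")]
  f2 <- station_features(ctd2, cast$nutrients)
  expect_true(is.na(f2$surface_oxygen))
  expect_true(is.finite(f2$mld))
})

test_that("EOS surface density is sane and feeds N2 when sigma is absent", {
  # denser when colder and saltier
  expect_gt(sigma_theta_surface(10, 36), sigma_theta_surface(25, 34))
  ctd <- data.frame(depth = seq(0, 40, 2),
                    temperature = seq(28, 20, length.out = 21),
                    salinity = seq(30, 36, length.out = 21))
  bv <- buoyancy_frequency(ctd)
  expect_true(all(bv$n2 > 0))  # stably stratified
})
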