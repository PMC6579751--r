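dilute_nacl <- function(c_left = 10, c_right = 10) {
  dplyr::bind_rows(
    species("Na", +1, 1.334e-5, c_left, c_right),
    species("Cl", -1, 2.032e-5, c_left, c_right))
}

test_that("GHK reference behaves analytically", {
  sp <- species("K", +1, 1.96e-5, 100, 100)
  v <- seq(-100, 100, 25)
  i <- vapply(v, function(vv) ghk_current(sp, vv, 40, 50), 0)
  fit <- lm(i ~ v)
  expect_equal(unname(coef(fit)[1]), 0, tolerance = 1e-12)  # through origin
  expect_lt(max(abs(residuals(fit))), 1e-3 * max(abs(i)))   # linear
  # divalent Nernst closed form
  expect_equal(nernst(+2, 10, 100, temperature = 298.15),
               1000 * 8.314462618 * 298.15 / (2 * 96485.33212) * log(10),
               tolerance = 1e-12)
  # GHK zero-current voltage equals Nernst for a single species
  spg <- species("Ca", +2, 0.79e-5, 10, 100)
  vz <- nernst(+2, 10, 100)
  expect_lt(abs(ghk_current(spg, vz, 40, 50)),
            1e-9 * abs(ghk_current(spg, vz + 25, 40, 50)))
  expect_error(ghk_current(species("Na", 1, 1e-5, 0, 0), 10, 40, 50))
})

test_that("the solver reproduces GHK on a neutral uniform pore within 2%", {
  sys <- make_pnp_fixture(pnp_fixture_spec(length = 40,
                                           radius_profile = list(
                                             type = "uniform", r = 4),
                                           species_table = dilute_nacl()))
  for (v in c(-100, -40, 40, 100)) {
    got <- solve_pnp(sys, v)
    want <- ghk_current(dilute_nacl(), v, 40, pi * 16)
    expect_equal(got$current, want, tolerance = 0.02)
    expect_lt(got$flux_constancy, 0.01)
  }
})

test_that("mirror-symmetric systems yield antisymmetric currents", {
  ring <- data.frame(z = 0, charge = -2, sigma = 2)   # even in z
  sys <- make_pnp_fixture(pnp_fixture_spec(ring_charges = ring,
                                           species_table = dilute_nacl(150,
                                                                       150)))
  for (v in c(30, 80)) {
    ip <- solve_pnp(sys, v)$current
    im <- solve_pnp(sys, -v)$current
    expect_equal(ip, -im, tolerance = 0.005 * max(abs(ip), abs(im)))
  }
})

test_that("currents are grid-converged to 1%", {
  mk <- function(step) {
    ring <- data.frame(z = 10, charge = -3, sigma = 2)
    make_pnp_fixture(pnp_fixture_spec(ring_charges = ring, step = step,
                                      species_table = dilute_nacl(150, 50)))
  }
  i1 <- solve_pnp(mk(0.5), -60)$current
  i2 <- solve_pnp(mk(0.25), -60)$current
  expect_equal(i1, i2, tolerance = 0.01)
})

test_that("the potential flattens to bath values away from the charge", {
  ring <- data.frame(z = 0, charge = -3, sigma = 2)
  sys <- make_pnp_fixture(pnp_fixture_spec(length = 160, ring_charges = ring,
                                           species_table = dilute_nacl(150,
                                                                       150)))
  sol <- solve_pnp(sys, 0)
  # Debye length ~ 7.9 A at 150 mM; within three lengths of each boundary
  # the potential has relaxed to the bath value (the central ring is ~10
  # confined-screening lengths away)
  expect_gt(max(abs(sol$phi)), 5)                      # the well is there
  expect_lt(max(abs(sol$phi[abs(sys$z) > 80 - 24])), 0.5)
})

test_that("uniform diffusivity scaling changes currents but not reversal", {
  ring <- data.frame(z = 15, charge = -3, sigma = 2)
  mk <- function(fd) {
    sp <- dplyr::bind_rows(
      species("Na", +1, 1.334e-5, 150, 15, f_D = fd),
      species("Cl", -1, 2.032e-5, 150, 15, f_D = fd))
    make_pnp_fixture(pnp_fixture_spec(ring_charges = ring,
                                      species_table = sp))
  }
  iv1 <- iv_curve(mk(0.1), seq(-80, 80, 40))
  iv2 <- iv_curve(mk(0.02), seq(-80, 80, 40))
  expect_equal(attr(iv1, "v_rev"), attr(iv2, "v_rev"), tolerance = 0.3)
  expect_equal(iv1$current / iv2$current, rep(5, nrow(iv1)),
               tolerance = 1e-3)
})

test_that("reversal potentials are bracketed, refined and flagged", {
  # symmetric neutral system: V_rev = 0
  sys0 <- make_pnp_fixture(pnp_fixture_spec(species_table = dilute_nacl(150,
                                                                        150)))
  iv0 <- iv_curve(sys0, seq(-50, 50, 25))
  expect_equal(attr(iv0, "v_rev"), 0, tolerance = 0.1)
  # single-species system reverses exactly at Nernst
  spn <- species("Na", +1, 1.334e-5, 150, 15)
  sysn <- make_pnp_fixture(pnp_fixture_spec(species_table = spn))
  ivn <- iv_curve(sysn, seq(-80, -40, 10))
  expect_equal(attr(ivn, "v_rev"), nernst(+1, 150, 15), tolerance = 0.2)
  # no crossing inside the ramp: reported as NA
  iv_off <- iv_curve(sysn, seq(20, 60, 20))
  expect_true(is.na(attr(iv_off, "v_rev")))
})

test_that("structural charge mapping is normalized and radially aware", {
  x <- cached_channel()
  prof <- pore_radius_profile(x, cached_channel_axis(), step = 1)
  rho <- map_fixed_charge(x, prof, radial_weight = "uniform")
  ch <- attr(rho, "charges")
  dz <- prof$z[2] - prof$z[1]
  expect_equal(sum(rho) * dz, sum(ch$charge), tolerance = 1e-6)
  expect_true(all(ch$radial <= 12))
  # per-ring totals carry the formal charges of the tagged rings
  tot <- tapply(ch$charge, ch$resseq, sum)
  expect_equal(as.numeric(tot[c("155", "157", "163", "178")]),
               c(6, 6, 6, -6))
  # pairing the basic rings leaves the acidic filter only
  rho_p <- map_fixed_charge(x, prof, radial_weight = "uniform",
                            paired_basic = TRUE)
  expect_lt(sum(rho_p) * dz, 0)
  chp <- attr(rho_p, "charges")
  expect_true(all(chp$weight[chp$charge > 0] == 0))
  # a lone acidic ring integrates to exactly -1 per residue
  expect_warning(
    rho0 <- map_fixed_charge(x, prof, radial_cutoff = 0.01),
    "no charged residues")
  expect_equal(sum(rho0), 0)
})
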