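test_that("bundle builder produces an exactly symmetric, deterministic fixture", {
  b1 <- build_bundle(bundle_spec())
  b2 <- build_bundle(bundle_spec())
  expect_identical(b1, b2)                                  # deterministic
  expect_equal(length(unique(b1$chain)), 6)
  expect_lt(symmetry_order_parameter(b1, 6), 1e-8)          # exact C6
  # round-trips through the structure writer
  f <- withr::local_tempfile(fileext = ".pdb")
  write_structure(b1, f, "pdb")
  expect_equal(nrow(read_structure(f)), nrow(b1))
})

test_that("geometrically impossible bundle specs are refused", {
  expect_error(build_bundle(bundle_spec(bundle_radius = 3)), "pore")
  expect_error(bundle_spec(n_helices = 6, symmetry_order = 4), "divisible")
})

test_that("twist-open transform is the identity at zero and errors on odd chains", {
  b <- small_bundle()
  t0 <- twist_open_transform()
  expect_equal_xyz(apply_twist_open(b, t0), b, tol = 1e-12)
  odd <- select_atoms(b, chains = c("A", "B", "C"))
  expect_error(apply_twist_open(odd, t0), "even")
})

test_that("imposed per-helix rotations are recovered exactly by the rotation metric", {
  b <- build_bundle(bundle_spec())
  ax <- compute_pore_axis(b)
  t <- twist_open_transform(rotation_set1 = 14, rotation_set2 = 0)
  open <- apply_twist_open(b, t)
  rot <- helix_rotation(b, open, 171, axis = ax)
  chains <- sort(unique(b$chain))
  set1 <- chains[c(1, 3, 5)]
  expect_equal(rot$theta[rot$chain %in% set1], rep(14, 3), tolerance = 1e-9)
  expect_equal(rot$theta[!rot$chain %in% set1], rep(0, 3), tolerance = 1e-9)
})

test_that("imposed radial shifts change ring distances by the closed-form amount", {
  b <- build_bundle(bundle_spec())
  ax <- compute_pore_axis(b)
  t <- twist_open_transform(radial_shift_set1 = 3)
  open <- apply_twist_open(b, t)
  q <- interchain_distance(open, 152, axis = ax)
  # closed form: set-1 chains stay C3-equivalent, so the pair distance is
  # sqrt(3) times the new ring radius of the marker CA
  ca <- b[b$chain == "A" & b$resseq == 152 & b$name == "CA", ]
  er <- c(1, 0)                                 # chain A radial direction
  v <- c(ca$x, ca$y) + 3 * er
  expect_equal(q$mean[q$set == "set1"], sqrt(3) * sqrt(sum(v^2)),
               tolerance = 1e-9)
  # untouched set 2 keeps the reference distance
  q0 <- interchain_distance(b, 152, axis = ax)
  expect_equal(q$mean[q$set == "set2"], q0$mean[q0$set == "set2"],
               tolerance = 1e-9)
})

test_that("twist metrics are invariant under a global rigid motion", {
  b <- build_bundle(bundle_spec())
  t <- twist_open_transform(rotation_set1 = 10, radial_shift_set2 = 2)
  open <- apply_twist_open(b, t)
  rt <- twistgate:::random_rigid_transform(seed = 7)
  b_m <- twistgate:::apply_rigid_to_structure(b, rt)
  open_m <- twistgate:::apply_rigid_to_structure(open, rt)
  ax <- compute_pore_axis(b)
  ax_m <- compute_pore_axis(b_m)
  r1 <- helix_rotation(b, open, 171, axis = ax)
  r2 <- helix_rotation(b_m, open_m, 171, axis = ax_m)
  expect_equal(r2$theta, r1$theta, tolerance = 1e-6)
  q1 <- interchain_distance(open, 152, axis = ax)
  q2 <- interchain_distance(open_m, 152, axis = ax_m)
  expect_equal(q2$mean, q1$mean, tolerance = 1e-9)
})

test_that("PNP fixtures encode symmetry and the Nernst limit", {
  # uniform neutral cylinder, symmetric baths: I(0) = 0, I odd in V
  sys <- make_pnp_fixture(pnp_fixture_spec())
  i0 <- solve_pnp(sys, 0)$current
  expect_lt(abs(i0), 1e-10)
  ip <- solve_pnp(sys, 60)$current
  im <- solve_pnp(sys, -60)$current
  expect_equal(ip, -im, tolerance = 5e-3)

  # single-species gradient: zero current exactly at the Nernst potential
  sp <- species("Na", +1, 1.334e-5, c_left = 150, c_right = 15)
  sysn <- make_pnp_fixture(pnp_fixture_spec(species_table = sp))
  vn <- nernst(+1, 150, 15)
  expect_equal(vn, 1000 * 8.314462618 * 298.15 / 96485.33212 * log(0.1),
               tolerance = 1e-12)
  i_at_nernst <- solve_pnp(sysn, vn)$current
  i_off <- solve_pnp(sysn, vn + 50)$current
  expect_lt(abs(i_at_nernst), 1e-3 * abs(i_off))

  expect_error(species("X", +1, 0, 10, 10), "D > 0")
})

test_that("charged-ring fixtures are cation-selective and inwardly rectified", {
  ring <- data.frame(z = 18, charge = -3, sigma = 2)
  sp <- dplyr::bind_rows(
    species("Na", +1, 1.334e-5, 150, 150),
    species("Cl", -1, 2.032e-5, 150, 150))
  sys <- make_pnp_fixture(pnp_fixture_spec(ring_charges = ring,
                                           species_table = sp))
  ineg <- solve_pnp(sys, -100)
  ipos <- solve_pnp(sys, 100)
  expect_gt(abs(ineg$current) / abs(ipos$current), 1)   # inward rectification
  # cation selectivity: with a bath gradient the reversal moves toward the
  # cation equilibrium potential
  spg <- dplyr::bind_rows(
    species("Na", +1, 1.334e-5, 15, 150),
    species("Cl", -1, 2.032e-5, 15, 150))
  sys_neutral <- make_pnp_fixture(pnp_fixture_spec(species_table = spg))
  sys_ring <- make_pnp_fixture(pnp_fixture_spec(ring_charges = ring,
                                                species_table = spg))
  v_neutral <- attr(iv_curve(sys_neutral, seq(-80, 80, 20)), "v_rev")
  v_ring <- attr(iv_curve(sys_ring, seq(-80, 80, 20)), "v_rev")
  expect_gt(v_ring, v_neutral)          # toward E_Na = +59 mV: cation side
})
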