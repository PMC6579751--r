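test_that("pore axis matches the construction axis and orients by ring rule", {
  b <- build_bundle(bundle_spec())
  ax <- compute_pore_axis(b)
  expect_lt(acos(min(abs(sum(ax$direction * c(0, 0, 1))), 1)), 1e-6)
  expect_gt(ax$direction[3], 0)       # E178 ring above K163 ring: +z up
  # orientation must never be guessed silently
  no_tags <- select_atoms(b, residues = 144:160)
  expect_error(compute_pore_axis(no_tags), "orient")
  # frame covariance: the axis follows a rigid motion of the structure
  rt <- twistgate:::random_rigid_transform(seed = 5)
  bm <- twistgate:::apply_rigid_to_structure(b, rt)
  axm <- compute_pore_axis(bm)
  expect_equal(abs(sum(axm$direction %*% rt$R %*% ax$direction)), 1,
               tolerance = 1e-6)
})

test_that("pore radius profile matches a direct on-axis evaluation", {
  b <- build_bundle(bundle_spec())
  ax <- compute_pore_axis(b)
  pr <- pore_radius_profile(b, ax, z_range = c(-15, 15), step = 2.5)
  expect_true(all(pr$radius > 0))
  # brute-force oracle: on the exactly symmetric fixture the optimal sphere
  # center is on the axis, so radius(z) = min over atoms of (3D dist - vdw)
  xyz <- sweep(twistgate:::coords(b), 2, ax$origin) %*%
    t(twistgate:::axis_frame(ax))
  vdw <- twistgate:::atom_radii(b)
  oracle <- vapply(pr$z, function(z) {
    min(sqrt(xyz[, 1]^2 + xyz[, 2]^2 + (xyz[, 3] - z)^2) - vdw)
  }, 0)
  expect_equal(pr$radius, oracle, tolerance = 0.05)
  # center optimization is a no-op for the axisymmetric fixture
  pr0 <- pore_radius_profile(b, ax, z_range = c(-15, 15), step = 2.5,
                             optimize_center = FALSE)
  expect_equal(pr$radius, pr0$radius, tolerance = 1e-3)
})

test_that("a constriction fixture puts the minimum radius at its center", {
  spec <- pnp_fixture_spec(radius_profile = list(type = "constriction",
                                                 z0 = 5, width = 4,
                                                 r_min = 1.5, r_out = 6))
  sys <- make_pnp_fixture(spec)
  expect_equal(sys$z[which.min(sys$radius)], 5, tolerance = 0.51)
  expect_equal(min(sys$radius), 1.5, tolerance = 1e-6)
})

test_that("helix rotation is zero on identical structures and NA for glycine", {
  b <- build_bundle(bundle_spec())
  ax <- compute_pore_axis(b)
  rot <- helix_rotation(b, b, c(167, 170, 171), axis = ax)
  expect_true(all(abs(rot$theta[rot$resseq != 170]) < 1e-9))
  expect_true(all(is.na(rot$theta[rot$resseq == 170])))   # glycine, no CB
  expect_false(any(is.na(rot$theta_mean[rot$resseq == 171])))
})

test_that("interchain distances follow hexagon geometry exactly", {
  b <- build_bundle(bundle_spec())
  ax <- compute_pore_axis(b)
  q <- interchain_distance(b, 152, axis = ax)
  ca <- b[b$chain == "A" & b$resseq == 152 & b$name == "CA", ]
  rho <- sqrt(ca$x^2 + ca$y^2)
  expect_equal(q$mean[q$set == "set1"], rho * sqrt(3), tolerance = 1e-9)
  expect_equal(q$mean[q$set == "set2"], rho * sqrt(3), tolerance = 1e-9)
  expect_equal(q$sd[1:2], c(0, 0), tolerance = 1e-9)
  expect_error(interchain_distance(b, 152, atom = "NZ"), "missing")
})

test_that("salt bridges respect the distance threshold and match brute force", {
  b <- build_bundle(bundle_spec())
  # engineer an Arg...Glu pair at a controlled N-O distance
  place_pair <- function(x, d) {
    nh <- x$chain == "A" & x$resseq == 155 & x$name == "NH1"
    oe <- x$chain == "B" & x$resseq == 178 & x$name == "OE1"
    x[nh, c("x", "y", "z")] <- list(0, 0, 50)
    x[oe, c("x", "y", "z")] <- list(d, 0, 50)
    x
  }
  near <- place_pair(b, 3.5)
  far <- place_pair(b, 4.5)
  hit <- salt_bridges(near, pairs = data.frame(resseq_basic = 155,
                                               resseq_acidic = 178))
  expect_true(any(hit$chain_basic == "A" & hit$chain_acidic == "B" &
                    abs(hit$dist - 3.5) < 1e-9))
  miss <- salt_bridges(far, pairs = data.frame(resseq_basic = 155,
                                               resseq_acidic = 178))
  expect_false(any(miss$chain_basic == "A" & miss$chain_acidic == "B"))

  # oracle: quadratic all-pairs scan reproduces the detected set
  sb <- salt_bridges(b, cutoff = 6)
  bas <- b[(b$resname == "ARG" & b$name %in% c("NH1", "NH2", "NE")) |
             (b$resname == "LYS" & b$name == "NZ"), ]
  aci <- b[b$resname == "GLU" & b$name %in% c("OE1", "OE2"), ]
  found <- 0
  for (i in seq_len(nrow(bas))) for (j in seq_len(nrow(aci))) {
    d <- sqrt(sum((as.numeric(bas[i, c("x", "y", "z")]) -
                     as.numeric(aci[j, c("x", "y", "z")]))^2))
    if (d <= 6) {
      found <- found + 1
      key <- paste(bas$chain[i], bas$resseq[i], aci$chain[j], aci$resseq[j])
      keys <- paste(sb$chain_basic, sb$resseq_basic, sb$chain_acidic,
                    sb$resseq_acidic)
      expect_true(key %in% keys)
    }
  }
  expect_gte(found, nrow(sb))   # every reported pair has >= 1 atom contact
})

test_that("contact persistence reports presence per structure", {
  x <- cached_channel()
  pairs <- twistgate:::default_cc_pairs()
  same <- contact_persistence(x, x, pairs)
  expect_identical(same$present_ref, same$present_alt)
  expect_true(all(same$present_ref))
  none <- contact_persistence(x, x, pairs, cutoff = 0)
  expect_false(any(none$present_ref))
  t <- twist_open_transform(radial_shift_set1 = 6, radial_shift_set2 = 6)
  apart <- apply_twist_open(x, t, segment = c(311, 326),
                            residues = 311:326)
  broke <- contact_persistence(x, apart, pairs)
  expect_true(all(broke$present_ref) && !any(broke$present_alt))
  expect_error(contact_persistence(x, x, data.frame(chain1 = "A",
                                                    resseq1 = 1, chain2 = "A",
                                                    resseq2 = 2)),
               "unresolvable")
})

test_that("solvent accessibility matches closed forms and a fine-grid oracle", {
  lone <- as_structure(tibble::tibble(name = "CA", resname = "ALA",
                                      resseq = 1, chain = "A",
                                      x = 0, y = 0, z = 0, element = "C"))
  s1 <- twistgate:::sasa_atoms(lone, n_points = 960)
  r <- twistgate:::VDW_RADII[["C"]] + 1.4
  expect_equal(s1$area, 4 * pi * r^2, tolerance = 0.01 * 4 * pi * r^2)

  two_far <- as_structure(tibble::tibble(
    name = c("CA", "CA"), resname = "ALA", resseq = c(1, 2),
    chain = "A", x = c(0, 50), y = 0, z = 0, element = "C"))
  s2 <- twistgate:::sasa_atoms(two_far, n_points = 960)
  expect_equal(sum(s2$area), 2 * 4 * pi * r^2,
               tolerance = 0.01 * 8 * pi * r^2)

  # small cluster vs high-density point oracle
  clu <- as_structure(tibble::tibble(
    name = c("CA", "CB", "OE1", "NZ"), resname = "ALA", resseq = 1:4,
    chain = "A", x = c(0, 1.6, 2.5, 0.8), y = c(0, 0.4, 1.9, -1.2),
    z = c(0, 1.1, 0.7, 2.0), element = c("C", "C", "O", "N")))
  coarse <- twistgate:::sasa_atoms(clu, n_points = 960)
  fine <- twistgate:::sasa_atoms(clu, n_points = 1e5)
  expect_equal(sum(coarse$area), sum(fine$area),
               tolerance = 0.02 * sum(fine$area))
  expect_error(sasa_residues(clu, n_points = 16), "floor")
})

test_that("relative exposure changes are defined only for exposed residues", {
  b <- build_bundle(bundle_spec(helix_length = 8))
  de <- delta_exposure(b, b, n_points = 120)
  expect_true(all(de$rel_change[de$defined] == 0))
  expect_true(all(c("sasa_ref", "sasa_alt", "defined") %in% names(de)))
})

test_that("symmetry order parameters capture the 6-fold/3-fold mismatch", {
  b <- build_bundle(bundle_spec())
  expect_lt(symmetry_order_parameter(b, 6), 1e-8)
  expect_lt(symmetry_order_parameter(b, 3), 1e-8)
  # set-asymmetric twist: C6 broken, C3 preserved
  t <- twist_open_transform(rotation_set1 = 20, radial_shift_set1 = 2)
  tw <- apply_twist_open(b, t)
  expect_gt(symmetry_order_parameter(tw, 6), 0.5)
  expect_lt(symmetry_order_parameter(tw, 3), 1e-6)
  # monotone growth with perturbation size
  set.seed(9)
  noise <- function(sig) {
    x <- b
    x$x <- x$x + rnorm(nrow(x), 0, sig)
    x$y <- x$y + rnorm(nrow(x), 0, sig)
    x$z <- x$z + rnorm(nrow(x), 0, sig)
    x
  }
  r <- vapply(c(0.05, 0.2, 0.8), function(s) {
    symmetry_order_parameter(noise(s), 6, refine_axis = FALSE)
  }, 0)
  expect_true(all(diff(r) > 0))
  expect_error(symmetry_order_parameter(b, 4), "divisible")
})
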