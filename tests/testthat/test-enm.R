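test_that("connected networks have exactly six rigid-body modes", {
  co <- to_coarse(small_bundle())
  ms <- compute_modes(co, cutoff = 13, n_modes = 20)
  expect_equal(ms$n_zero, 6)
  expect_true(all(diff(ms$values) >= -1e-12))
  expect_lt(max(abs(crossprod(ms$vectors) - diag(ncol(ms$vectors)))), 1e-8)
})

test_that("a translation lies exactly in the Hessian nullspace", {
  co <- to_coarse(small_bundle(len = 6))
  xyz <- as.matrix(co[, c("x", "y", "z")])
  dd <- as.matrix(dist(xyz))
  H <- twistgate:::anm_hessian(xyz, dd <= 13 & dd > 0, dd, 1)
  tvec <- rep(c(1, 0, 0), nrow(co))
  expect_lt(max(abs(H %*% tvec)), 1e-12)
  expect_equal(max(abs(H - t(H))), 0)          # symmetric by construction
})

test_that("iterative and dense eigensolvers agree on a small model", {
  skip_if_not_installed("RSpectra")
  co <- to_coarse(select_atoms(small_bundle(len = 10), chains = c("A", "B")))
  # force both paths on the same 20-site toy model
  xyz <- as.matrix(co[, c("x", "y", "z")])
  dd <- as.matrix(dist(xyz))
  H <- twistgate:::anm_hessian(xyz, dd <= 13 & dd > 0, dd, 1)
  dense <- sort(eigen(H, symmetric = TRUE, only.values = TRUE)$values)
  iter <- RSpectra::eigs_sym(H, k = 18, sigma = -1e-4)$values
  expect_equal(sort(iter)[7:18], dense[7:18], tolerance = 1e-8)
  # and the packaged solver returns the dense nontrivial spectrum
  ms <- compute_modes(co, cutoff = 13, n_modes = 12)
  expect_equal(ms$values, dense[7:18], tolerance = 1e-8)
})

test_that("disconnected networks are reported with component counts", {
  co <- to_coarse(small_bundle(len = 6, bundle_radius = 40))
  expect_error(compute_modes(co, cutoff = 13), "disconnected.*components")
})

test_that("n_modes beyond 3N - 6 is clamped with a warning", {
  co <- to_coarse(select_atoms(small_bundle(len = 5), chains = "A"))
  expect_warning(ms <- compute_modes(co, cutoff = 13, n_modes = 500),
                 "clamped")
  expect_equal(length(ms$values), 3 * nrow(co) - 6)
})

test_that("collectivity matches its entropy definition and limit cases", {
  co <- to_coarse(small_bundle())
  ms <- compute_modes(co, cutoff = 13, n_modes = 10)
  n <- nrow(co)
  # uniform-magnitude mode: kappa = 1; single-site mode: kappa = 1/N
  ms_fake <- ms
  ms_fake$vectors[, 1] <- rep(1 / sqrt(3 * n), 3 * n)
  expect_equal(collectivity(ms_fake, 1), 1, tolerance = 1e-12)
  ms_fake$vectors[, 2] <- c(1, rep(0, 3 * n - 1))
  expect_equal(collectivity(ms_fake, 2), 1 / n, tolerance = 1e-12)
  # independent entropy-formula evaluation for a real mode
  u2 <- rowSums(twistgate:::mode_field(ms, 3)^2)
  p <- u2 / sum(u2)
  expect_equal(collectivity(ms, 3),
               exp(-sum(p[p > 0] * log(p[p > 0]))) / n, tolerance = 1e-12)
})

test_that("mode overlap is a complete cosine decomposition", {
  co <- to_coarse(select_atoms(small_bundle(len = 6), chains = c("A", "B")))
  n <- nrow(co)
  ms <- compute_modes(co, cutoff = 13, n_modes = 3 * n - 6)
  expect_equal(mode_overlap(ms, 4, twistgate:::mode_field(ms, 4)), 1,
               tolerance = 1e-10)
  expect_equal(mode_overlap(ms, 2, twistgate:::mode_field(ms, 5)), 0,
               tolerance = 1e-10)
  expect_error(mode_overlap(ms, 1, rep(0, 3 * n)), "zero")
  # completeness: any displacement orthogonal to the rigid modes is fully
  # captured by the nontrivial spectrum
  set.seed(42)
  d <- rnorm(3 * n)
  rigid <- {
    xyz <- as.matrix(co[, c("x", "y", "z")])
    dd <- as.matrix(dist(xyz))
    H <- twistgate:::anm_hessian(xyz, dd <= 13 & dd > 0, dd, 1)
    es <- eigen(H, symmetric = TRUE)
    es$vectors[, (3 * n - 5):(3 * n)]
  }
  d <- d - rigid %*% crossprod(rigid, d)
  tot <- sum(vapply(seq_along(ms$values),
                    function(k) mode_overlap(ms, k, as.vector(d))^2, 0))
  expect_equal(tot, 1, tolerance = 1e-8)
})

test_that("symmetry scores identify the totally symmetric representation", {
  co <- to_coarse(small_bundle())
  ms <- compute_modes(co, cutoff = 13, n_modes = 12)
  expect_equal(symmetry_score(ms, 1, order = 1), 1)
  # analytically constructed breathing mode is exactly C6-symmetric
  xyz <- as.matrix(co[, c("x", "y", "z")])
  rad <- xyz; rad[, 3] <- 0
  rad <- rad / sqrt(rowSums(rad^2))
  v <- as.vector(t(rad)); v <- v / sqrt(sum(v^2))
  w <- twistgate:::symmetry_transform_vector(ms, v, 6)
  expect_equal(sum(w * v), 1, tolerance = 1e-9)
  # random unit vectors are far from symmetric on average
  set.seed(3)
  sc <- replicate(20, {
    u <- rnorm(length(v)); u <- u / sqrt(sum(u^2))
    sum(twistgate:::symmetry_transform_vector(ms, u, 6) * u)
  })
  expect_lt(mean(abs(sc)), 0.35)
  expect_error(symmetry_score(ms, 1, order = 4), "divisible")
})

test_that("the C6 bundle has a cleanly symmetric low-frequency mode", {
  co <- to_coarse(build_bundle(bundle_spec()))
  ms <- compute_modes(co, cutoff = 13, n_modes = 10)
  c6 <- vapply(1:10, function(k) symmetry_score(ms, k, 6), 0)
  expect_gt(max(c6), 0.9)
})

test_that("the spectrum is invariant under rigid motion of the input", {
  co <- to_coarse(small_bundle())
  ms1 <- compute_modes(co, cutoff = 13, n_modes = 8)
  rt <- twistgate:::random_rigid_transform(seed = 11)
  co2 <- co
  xyz <- twistgate:::transform_coords(as.matrix(co[, c("x", "y", "z")]),
                                      rt$R, rt$t)
  co2$x <- xyz[, 1]; co2$y <- xyz[, 2]; co2$z <- xyz[, 3]
  ms2 <- compute_modes(co2, cutoff = 13, n_modes = 8)
  expect_equal(ms2$values, ms1$values, tolerance = 1e-6)
})
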