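channel_scores <- function() {
  memo("channel_scores", function() {
    x <- cached_channel()
    ms <- compute_modes(to_coarse(x), cutoff = 13, n_modes = 30)
    spec <- constraint_spec(cc_break_pairs = twistgate:::default_cc_pairs())
    list(x = x, ms = ms, spec = spec,
         scores = score_modes(ms, spec, cached_channel_axis()))
  })
}

test_that("mode scores encode the gating constraints deterministically", {
  cs <- channel_scores()
  sc <- cs$scores
  expect_equal(nrow(sc), length(cs$ms$values))
  expect_true(all(sc$f_sym >= -1 & sc$f_sym <= 1))
  expect_true(all(sc$kappa > 0 & sc$kappa <= 1))
  expect_true(all(sc$sign %in% c(-1, 1)))
  # scoring twice gives identical tables (determinism)
  sc2 <- score_modes(cs$ms, cs$spec, cached_channel_axis())
  expect_equal(sc, sc2)
  # zero weights zero the combined score
  spec0 <- cs$spec
  spec0$weights[] <- 0
  sc0 <- score_modes(cs$ms, spec0, cached_channel_axis())
  expect_true(all(sc0$combined == 0))
})

test_that("mode selection filters and breaks ties by index", {
  cs <- channel_scores()
  sel <- select_modes(cs$scores, top_k = 3)
  expect_length(sel, 3)
  expect_true(all(cs$scores$kappa[sel] >= 0.1))
  expect_true(all(cs$scores$f_sym[sel] >= 0.5))
  # a single passing mode is returned regardless of top_k
  one <- cs$scores[cs$scores$mode == sel[1], ]
  fake <- cs$scores
  fake$kappa[fake$mode != sel[1]] <- 0
  expect_equal(select_modes(fake, top_k = 5), sel[1])
  # exact ties resolve to the lowest index
  tied <- cs$scores
  tied$combined <- 1
  tied$kappa <- 0.5
  tied$f_sym <- 1
  expect_equal(select_modes(tied, top_k = 2), c(1L, 2L))
  # nothing passing is an explicit error suggesting relaxation
  none <- cs$scores
  none$kappa <- 0
  expect_error(select_modes(none), "relaxing")
})

test_that("deformation is exact at zero amplitude and linear for small ones", {
  cs <- channel_scores()
  x <- cs$x
  d0 <- deform(x, cs$ms, c(`1` = 0))
  expect_equal_xyz(d0$structure, x, tol = 1e-12)
  eps <- 1e-4
  d1 <- deform(x, cs$ms, c(`1` = eps))
  got <- as.matrix(d1$coarse[, c("x", "y", "z")]) -
    as.matrix(cs$ms$sites[, c("x", "y", "z")])
  want <- eps * twistgate:::mode_field(cs$ms, 1)
  expect_lt(max(abs(got - want)), 1e-9)
})

test_that("gating metrics evaluate the closed state onto its own references", {
  cs <- channel_scores()
  gm <- gating_metrics(cs$x, cs$spec, cached_channel_axis())
  m0 <- gm$eval(as.matrix(gm$sites[, c("x", "y", "z")]))
  expect_equal(unname(m0["q_set1"]), 16.2, tolerance = 1e-2)
  expect_equal(unname(m0["rot_gate"]), 0)
  expect_equal(unname(m0["filter_rad"]), unname(gm$targets["filter_rad"]))
  expect_equal(unname(m0["bridge"]), unname(gm$targets["bridge"]))
})

test_that("amplitude choice is a fixed point when targets equal the reference", {
  cs <- channel_scores()
  gm <- gating_metrics(cs$x, cs$spec, cached_channel_axis())
  m0 <- gm$eval(as.matrix(gm$sites[, c("x", "y", "z")]))
  gm$targets <- m0                         # ask for the closed state itself
  pool <- select_modes(cs$scores, top_k = nrow(cs$scores),
                       min_collectivity = 0.02)
  amp <- choose_amplitudes(cs$ms, cs$scores, pool, gm)
  expect_lt(amp$a * max(sqrt(rowSums(amp$direction^2))), 0.05)
})

test_that("regularization restores bonds and resolves clashes minimally", {
  co <- to_coarse(small_bundle(len = 8))
  xyz <- as.matrix(co[, c("x", "y", "z")])
  reg0 <- twistgate:::regularize_trace(co, xyz)
  expect_lt(max(abs(reg0 - xyz)), 1e-12)               # already regular
  expect_equal(attr(reg0, "iterations"), 0)

  # stretch one bond to 4.6 A
  stretched <- xyz
  i <- which(co$chain == "A" & co$resseq == 147)
  bond_dir <- xyz[i + 1, ] - xyz[i, ]
  bond_dir <- bond_dir / sqrt(sum(bond_dir^2))
  stretched[i, ] <- xyz[i + 1, ] - 4.6 * bond_dir
  reg1 <- twistgate:::regularize_trace(co, stretched)
  l <- sqrt(sum((reg1[i + 1, ] - reg1[i, ])^2))
  expect_true(l >= 3.6 && l <= 4.0)
  # untouched bonds stay put
  bonds <- twistgate:::consecutive_bonds(co)
  keep <- bonds[, 1] != i & bonds[, 2] != i
  bl_new <- sqrt(rowSums((reg1[bonds[keep, 1], ] -
                            reg1[bonds[keep, 2], ])^2))
  bl_old <- sqrt(rowSums((xyz[bonds[keep, 1], ] -
                            xyz[bonds[keep, 2], ])^2))
  expect_lt(max(abs(bl_new - bl_old)), 0.05)

  # a deliberate 2.0 A clash is pushed back beyond 3.4 A
  clash <- xyz
  j <- which(co$chain == "B" & co$resseq == 150)
  clash[j, ] <- xyz[i, ] + c(2, 0, 0)
  reg2 <- twistgate:::regularize_trace(co, clash)
  dd <- as.matrix(dist(reg2))
  dd[cbind(bonds[, 1], bonds[, 2])] <- Inf
  dd[cbind(bonds[, 2], bonds[, 1])] <- Inf
  diag(dd) <- Inf
  expect_gte(min(dd), 3.4)
})

test_that("side-chain relaxation restores reachable reference contacts", {
  x <- cached_channel()
  # swing chain A's K157 side chain away, then relax it back
  broken <- twistgate:::move_group_to(x, "A", 157, "NZ",
                                      twistgate:::residue_atom_xyz(x, "A",
                                                                   157,
                                                                   "CA") +
                                        c(0, 0, 5))
  sb0 <- salt_bridges(broken, pairs = data.frame(resseq_basic = 157,
                                                 resseq_acidic = 245))
  expect_equal(nrow(sb0), 5)                 # A's bridge broken
  fixed <- relax_side_chains(broken, x)
  sb1 <- salt_bridges(fixed, pairs = data.frame(resseq_basic = 157,
                                                resseq_acidic = 245))
  expect_equal(nrow(sb1), 6)
})

test_that("the full pipeline is deterministic and honors degraded symmetry", {
  x <- cached_channel()
  r1 <- generate_open_state(x, n_modes = 30, max_steps = 1)
  r2 <- generate_open_state(x, n_modes = 30, max_steps = 1)
  expect_equal_xyz(r1$open, r2$open, tol = 1e-9)
  lo <- generate_open_state(x, constraints = local({
    cs <- constraint_spec(symmetry_order = 1,
                          cc_break_pairs = twistgate:::default_cc_pairs())
    cs
  }), n_modes = 30, max_steps = 1)
  expect_true(lo$report$low_symmetry)
})

test_that("the generated open state honors the constraint bookkeeping", {
  res <- cached_open_state()
  r <- res$report
  expect_lt(r$filter_shape_rmsd, 0.5)            # filter ring stays rigid
  expect_lt(r$symmetry$order3, 0.1)              # symmetric motion
  # the coiled-coil contacts separate while TM3/TM4 packing persists
  cc <- contact_persistence(res$closed, res$open,
                            twistgate:::default_cc_pairs())
  expect_true(all(cc$present_ref) && !any(cc$present_alt))
  keep <- contact_persistence(
    res$closed, res$open,
    data.frame(chain1 = LETTERS[1:6], resseq1 = 304L,
               chain2 = LETTERS[1:6], resseq2 = 246L))
  expect_true(all(keep$present_alt))
})
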