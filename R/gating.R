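#' Gating constraint specification
#'
#' Machine encoding of the five structural criteria that define the gating
#' motion: (1) the acidic selectivity-filter ring stays rigid; (2) the
#' hydrophobic gate plus the first basic residue are released; (3) cytosolic
#' motions of the pore helix are coupled to the peripheral helices; (4) the
#' coiled-coil pairing of neighboring cytosolic extensions breaks; (5) the
#' motion is Cn-symmetric. Defaults carry the channel's canonical residue
#' numbers.
#'
#' @param filter_rigid residue numbers of the filter ring (default 178).
#' @param gate_release residues of the released gate (default 163, 171, 174).
#' @param cyto_tm1 residue range (length-2) of the cytosolic pore-helix
#'   segment.
#' @param cyto_peripheral residue ranges (list of length-2 vectors) of
#'   cytosolic peripheral segments.
#' @param cc_break_pairs data frame `chain1`, `resseq1`, `chain2`, `resseq2`
#'   of coiled-coil contacts expected to separate; NULL disables the term.
#' @param symmetry_order Cn order of the motion (default 3).
#' @param weights named numeric: `filter`, `gate`, `couple`, `cc`, `sym`
#'   (non-negative; default all 1).
#' @return object of class `constraint_spec`.
#' @export
constraint_spec <- function(filter_rigid = 178,
                            gate_release = c(163, 171, 174),
                            cyto_tm1 = c(144, 160),
                            cyto_peripheral = list(c(235, 250),
                                                   c(300, 326)),
                            cc_break_pairs = NULL,
                            symmetry_order = 3,
                            weights = c(filter = 1, gate = 1, couple = 1,
                                        cc = 1, sym = 1)) {
  stopifnot(all(weights >= 0))
  w <- c(filter = 1, gate = 1, couple = 1, cc = 1, sym = 1)
  w[names(weights)] <- weights
  structure(list(filter_rigid = filter_rigid, gate_release = gate_release,
                 cyto_tm1 = cyto_tm1, cyto_peripheral = cyto_peripheral,
                 cc_break_pairs = cc_break_pairs,
                 symmetry_order = symmetry_order, weights = w),
            class = "constraint_spec")
}

# Default coiled-coil break pairs for the hexameric channel model: the
# I316-L319 contact on each paired TM4-ext.
default_cc_pairs <- function(chains = LETTERS[1:6]) {
  a <- chains[seq(1, length(chains), by = 2)]
  b <- chains[seq(2, length(chains), by = 2)]
  tibble(chain1 = a, resseq1 = 316L, chain2 = b, resseq2 = 319L)
}

#' Score normal modes against the gating constraints
#'
#' Computes one row of feature scores per nontrivial mode. Eigenvector signs
#' are first resolved so that the mean radial displacement at the gate sites
#' is positive (pore-opening); the resolved sign is reported. Features:
#' `f_filter` (filter mean squared displacement over the all-site mean;
#' lower is better), `f_gate` (in-plane radial+tangential gate displacement
#' relative to the overall RMS; higher better), `f_couple` (mean cosine
#' similarity between cytosolic pore-helix displacements and their nearest
#' peripheral cytosolic sites), `f_cc` (mean initial rate of increase of the
#' coiled-coil pair distances per unit amplitude), `f_sym` (signed Cn
#' symmetry score; only modes near +1 transform as the totally symmetric
#' representation), plus collectivity `kappa`. The `combined` score is the
#' weight-dot-product of per-feature rank normalizations to \[0, 1\]
#' (f_filter entering with inverted rank), making the weights unit-free.
#'
#' @param ms a `tg_modes` object.
#' @param spec a [constraint_spec()].
#' @param axis pore axis (list with origin/direction); default from the
#'   coarse sites via [compute_pore_axis()] conventions cannot be applied to
#'   bare sites, so pass the axis computed on the parent structure when tags
#'   are absent.
#' @return tibble, one row per mode, ordered by mode index; ties in
#'   `combined` are broken by mode index when ranking.
#' @export
score_modes <- function(ms, spec, axis) {
  sites <- ms$sites
  n <- nrow(sites)
  xyz <- as.matrix(sites[, c("x", "y", "z")])
  d <- axis$direction
  rel <- sweep(xyz, 2, axis$origin)
  zc <- rel %*% d
  radial <- rel - zc %*% t(d)
  rnorm_ <- sqrt(rowSums(radial^2))
  er <- radial / pmax(rnorm_, 1e-9)
  et <- t(apply(er, 1, function(u) pracma_cross(d, u)))

  i_filter <- which(sites$resseq %in% spec$filter_rigid)
  i_gate <- which(sites$resseq %in% spec$gate_release)
  i_cyt1 <- which(sites$resseq >= spec$cyto_tm1[1] &
                    sites$resseq <= spec$cyto_tm1[2])
  i_per <- which(purrr::map_lgl(sites$resseq, function(r) {
    any(purrr::map_lgl(spec$cyto_peripheral,
                       function(rg) r >= rg[1] && r <= rg[2]))
  }))
  if (length(i_filter) == 0 || length(i_gate) == 0) {
    stop("filter/gate residues not present in the coarse model",
         call. = FALSE)
  }
  # nearest peripheral partner per cytosolic pore-helix site, same chain
  near_per <- vapply(i_cyt1, function(i) {
    cand <- i_per[sites$chain[i_per] == sites$chain[i]]
    if (length(cand) == 0) return(NA_integer_)
    dd <- rowSums(sweep(xyz[cand, , drop = FALSE], 2, xyz[i, ])^2)
    cand[which.min(dd)]
  }, integer(1))

  cc <- spec$cc_break_pairs
  cc_idx <- NULL
  if (!is.null(cc)) {
    cc_idx <- cbind(
      match(paste(cc$chain1, cc$resseq1), paste(sites$chain, sites$resseq)),
      match(paste(cc$chain2, cc$resseq2), paste(sites$chain, sites$resseq))
    )
    if (any(is.na(cc_idx))) {
      stop("cc_break_pairs reference residues absent from the model",
           call. = FALSE)
    }
  }

  K <- length(ms$values)
  rows <- vector("list", K)
  for (k in seq_len(K)) {
    U <- mode_field(ms, k)
    ur <- rowSums(U * er)
    sgn <- if (mean(ur[i_gate]) < 0) -1 else 1
    U <- sgn * U
    ur <- sgn * ur
    ut <- rowSums(U * et)
    msd_all <- mean(rowSums(U^2))
    f_filter <- mean(rowSums(U[i_filter, , drop = FALSE]^2)) / msd_all
    f_gate <- mean(sqrt(ur[i_gate]^2 + ut[i_gate]^2)) / sqrt(msd_all)
    ok <- !is.na(near_per)
    f_couple <- if (any(ok)) {
      mean(vapply(which(ok), function(ii) {
        a <- U[i_cyt1[ii], ]; b <- U[near_per[ii], ]
        na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
        if (na < 1e-12 || nb < 1e-12) 0 else sum(a * b) / (na * nb)
      }, 0))
    } else NA_real_
    f_cc <- if (!is.null(cc_idx)) {
      mean(vapply(seq_len(nrow(cc_idx)), function(p) {
        i <- cc_idx[p, 1]; j <- cc_idx[p, 2]
        rij <- xyz[i, ] - xyz[j, ]
        sum(rij * (U[i, ] - U[j, ])) / sqrt(sum(rij^2))
      }, 0))
    } else NA_real_
    f_sym <- symmetry_score(ms, k, spec$symmetry_order)
    rows[[k]] <- tibble(mode = k, sign = sgn, lambda = ms$values[k],
                        kappa = collectivity(ms, k),
                        f_filter = f_filter, f_gate = f_gate,
                        f_couple = f_couple, f_cc = f_cc, f_sym = f_sym)
  }
  out <- dplyr::bind_rows(rows)
  rankp <- function(v, invert = FALSE) {
    if (all(is.na(v))) return(rep(0, length(v)))
    r <- rank(if (invert) -v else v, ties.method = "average",
              na.last = "keep")
    (r - 1) / max(length(v) - 1, 1)
  }
  w <- spec$weights
  out$combined <- w["filter"] * rankp(out$f_filter, invert = TRUE) +
    w["gate"] * rankp(out$f_gate) +
    w["couple"] * rankp(out$f_couple) +
    w["cc"] * rankp(out$f_cc) +
    w["sym"] * rankp(out$f_sym)
  if (all(w == 0)) out$combined <- rep(0, nrow(out))
  out
}

#' Select gating candidate modes
#'
#' Filters by collectivity and symmetry, then takes the `top_k` modes by
#' combined score (ties broken by lower mode index).
#'
#' @param scores output of [score_modes()].
#' @param top_k number of modes to keep (default 3).
#' @param min_collectivity,min_sym filter thresholds.
#' @return integer mode indices (ordered by descending combined score).
#' @export
select_modes <- function(scores, top_k = 3, min_collectivity = 0.1,
                         min_sym = 0.5) {
  pass <- scores[scores$kappa >= min_collectivity &
                   scores$f_sym >= min_sym, ]
  if (nrow(pass) == 0) {
    stop("no mode passes the collectivity/symmetry filters; consider ",
         "relaxing min_collectivity (", min_collectivity, ") or min_sym (",
         min_sym, ")", call. = FALSE)
  }
  pass <- pass[order(-pass$combined, pass$mode), ]
  utils::head(pass$mode, top_k)
}

#' Deform a structure along normal modes
#'
#' Displaces the C-alpha sites by `sum_k a_k v_k` and reconstructs all-atom
#' coordinates by applying, per residue, the rigid transform that maps its
#' local C-alpha frame (previous/self/next C-alpha, one-sided at chain
#' breaks and termini) from the reference to the deformed coarse model.
#' Amplitudes are in Angstrom-weighted eigenvector units.
#'
#' @param x reference atom tibble (all-atom).
#' @param ms `tg_modes` computed on `to_coarse(x)`.
#' @param amplitudes named numeric: names are mode indices, values
#'   amplitudes (signs included).
#' @return object of class `deformed_state`: list with `structure`
#'   (all-atom tibble), `coarse` (deformed sites), `amplitudes`, and a
#'   `report` (max bond deviation, CA clash count).
#' @export
deform <- function(x, ms, amplitudes) {
  sites <- ms$sites
  n <- nrow(sites)
  disp <- matrix(0, n, 3)
  ks <- as.integer(names(amplitudes))
  stopifnot(all(ks >= 1 & ks <= length(ms$values)))
  for (i in seq_along(ks)) {
    disp <- disp + amplitudes[i] * mode_field(ms, ks[i])
  }
  ref_ca <- as.matrix(sites[, c("x", "y", "z")])
  def_ca <- ref_ca + disp
  new_sites <- sites
  new_sites$x <- def_ca[, 1]; new_sites$y <- def_ca[, 2]
  new_sites$z <- def_ca[, 3]
  out <- rebuild_all_atom(x, sites, def_ca)
  structure(list(structure = out, coarse = new_sites,
                 amplitudes = amplitudes,
                 report = deformation_report(new_sites)),
            class = "deformed_state")
}

# Map all-atom coordinates through per-residue rigid frames defined by the
# CA trace before/after deformation.
rebuild_all_atom <- function(x, sites, def_ca) {
  ref_ca <- as.matrix(sites[, c("x", "y", "z")])
  key <- paste(sites$chain, sites$resseq)
  out <- x
  xyz <- coords(x)
  for (i in seq_len(nrow(sites))) {
    idx <- frame_neighbors(sites, i)
    R <- if (length(idx) >= 2) {
      kb <- kabsch(ref_ca[c(i, idx), , drop = FALSE],
                   def_ca[c(i, idx), , drop = FALSE])
      kb$R
    } else diag(3)
    sel <- which(x$chain == sites$chain[i] & x$resseq == sites$resseq[i] &
                   !x$het)
    if (length(sel) == 0) next
    local <- sweep(xyz[sel, , drop = FALSE], 2, ref_ca[i, ])
    moved <- sweep(local %*% t(R), 2, -def_ca[i, ])
    out[sel, c("x", "y", "z")] <- as.data.frame(moved)
  }
  out
}

# Indices of the sequence neighbors (resseq +/- 1 and +/- 2 fallback, same
# chain) used to define residue i's local frame.
frame_neighbors <- function(sites, i) {
  ch <- sites$chain[i]; rs <- sites$resseq[i]
  cand <- c(rs - 1, rs + 1, rs - 2, rs + 2)
  idx <- integer(0)
  for (r in cand) {
    j <- which(sites$chain == ch & sites$resseq == r)
    if (length(j) == 1) idx <- c(idx, j)
    if (length(idx) >= 2) break
  }
  idx
}

deformation_report <- function(sites) {
  xyz <- as.matrix(sites[, c("x", "y", "z")])
  bonds <- consecutive_bonds(sites)
  bl <- sqrt(rowSums((xyz[bonds[, 1], , drop = FALSE] -
                        xyz[bonds[, 2], , drop = FALSE])^2))
  dd <- as.matrix(stats::dist(xyz))
  nonbond <- dd
  nonbond[cbind(bonds[, 1], bonds[, 2])] <- Inf
  nonbond[cbind(bonds[, 2], bonds[, 1])] <- Inf
  diag(nonbond) <- Inf
  list(max_bond_dev = if (length(bl)) max(abs(bl - 3.8)) else 0,
       clash_count = sum(nonbond < 3.4) / 2,
       min_nonbond = min(nonbond))
}

consecutive_bonds <- function(sites) {
  i <- seq_len(nrow(sites) - 1)
  ok <- sites$chain[i] == sites$chain[i + 1] &
    sites$resseq[i + 1] == sites$resseq[i] + 1L
  cbind(i[ok], i[ok] + 1L)
}

#' Build the gating metric set for targeted deformation
#'
#' Encodes the gating constraints as a vector of smooth geometric
#' observables of the C-alpha model, each with a target value and a weight:
#' alternate-set marker-ring distances (dilation targets), mean radial
#' position of the gate ring (release target: dilate by `gate_dilation`),
#' mean radial position of the filter ring (rigidity: keep), mean
#' pore-helix-to-peripheral cytosolic distance (coupling: keep), mean
#' counterclockwise tangential displacement of the gate ring (the
#' reorientation direction reported by accessibility studies of the gate;
#' positive target), and mean tangential displacement of the cytosolic
#' pore-helix sites on alternate-set-2 chains (clockwise; negative target).
#'
#' @param x closed-state atom tibble (reference).
#' @param spec a [constraint_spec()].
#' @param axis pore axis of `x`.
#' @param targets list with `q_resseq` (default 152), `q_set1`, `q_set2`
#'   (Angstrom), `gate_dilation` (default 1.5 A), `rot_gate_arc` (default
#'   +1.3 A tangential), `rot_cyto_arc` (default -2 A tangential).
#' @return object of class `gating_metrics`: `eval(xyz)` returning the
#'   metric vector, plus `targets`, `weights`, `sites` (the coarse
#'   reference).
#' @export
gating_metrics <- function(x, spec, axis = compute_pore_axis(x),
                           targets = list()) {
  sites0 <- to_coarse(x)
  xyz0 <- as.matrix(sites0[, c("x", "y", "z")])
  n <- nrow(xyz0)
  d <- axis$direction
  rel <- sweep(xyz0, 2, axis$origin)
  zc <- as.vector(rel %*% d)
  radial <- rel - zc %*% t(d)
  rad0 <- sqrt(rowSums(radial^2))
  er <- radial / pmax(rad0, 1e-9)
  et <- t(apply(er, 1, function(u) pracma_cross(d, u)))

  q_res <- targets$q_resseq %||% 152
  q1 <- targets$q_set1 %||% 22.3
  q2 <- targets$q_set2 %||% 18.4
  gate_dil <- targets$gate_dilation %||% 1.5
  rot_gate <- targets$rot_gate_arc %||% 1.3
  rot_cyto <- targets$rot_cyto_arc %||% -2.0

  az <- azimuthal_chain_order(sites0, axis)
  set1 <- az[seq(1, length(az), by = 2)]
  set2 <- az[seq(2, length(az), by = 2)]
  marker_idx <- function(set) {
    idx <- vapply(set, function(ch) {
      which(sites0$chain == ch & sites0$resseq == q_res)[1]
    }, integer(1))
    if (any(is.na(idx))) {
      stop("marker residue ", q_res, " missing from some chains",
           call. = FALSE)
    }
    t(utils::combn(idx, 2))
  }
  p1 <- marker_idx(set1); p2 <- marker_idx(set2)
  i_gate <- which(sites0$resseq %in% spec$gate_release)
  i_filter <- which(sites0$resseq %in% spec$filter_rigid)
  i_cyt1 <- which(sites0$resseq >= spec$cyto_tm1[1] &
                    sites0$resseq <= spec$cyto_tm1[2])
  i_per <- which(vapply(sites0$resseq, function(r) {
    any(vapply(spec$cyto_peripheral,
               function(rg) r >= rg[1] && r <= rg[2], TRUE))
  }, TRUE))
  near_per <- vapply(i_cyt1, function(i) {
    cand <- i_per[sites0$chain[i_per] == sites0$chain[i]]
    if (length(cand) == 0) return(NA_integer_)
    dd <- rowSums(sweep(xyz0[cand, , drop = FALSE], 2, xyz0[i, ])^2)
    cand[which.min(dd)]
  }, integer(1))
  cp <- cbind(i_cyt1[!is.na(near_per)], near_per[!is.na(near_per)])
  i_cyt2 <- i_cyt1[sites0$chain[i_cyt1] %in% set2]
  # closed-state intra-chain salt bridges joining the cytosolic pore helix
  # to a peripheral helix are the physical carriers of the coupling
  # constraint: preserve their CA distances explicitly
  in_per <- function(r) any(vapply(spec$cyto_peripheral,
                                   function(rg) r >= rg[1] && r <= rg[2],
                                   TRUE))
  sb0 <- salt_bridges(x)
  br <- NULL
  if (nrow(sb0) > 0) {
    keep <- sb0$intra_chain &
      ((sb0$resseq_basic >= spec$cyto_tm1[1] &
          sb0$resseq_basic <= spec$cyto_tm1[2] &
          vapply(sb0$resseq_acidic, in_per, TRUE)) |
         (sb0$resseq_acidic >= spec$cyto_tm1[1] &
            sb0$resseq_acidic <= spec$cyto_tm1[2] &
            vapply(sb0$resseq_basic, in_per, TRUE)))
    sbk <- sb0[keep, ]
    if (nrow(sbk) > 0) {
      br <- cbind(
        vapply(seq_len(nrow(sbk)), function(i) {
          which(sites0$chain == sbk$chain_basic[i] &
                  sites0$resseq == sbk$resseq_basic[i])[1]
        }, integer(1)),
        vapply(seq_len(nrow(sbk)), function(i) {
          which(sites0$chain == sbk$chain_acidic[i] &
                  sites0$resseq == sbk$resseq_acidic[i])[1]
        }, integer(1))
      )
    }
  }

  pair_mean <- function(xyz, p) {
    mean(sqrt(rowSums((xyz[p[, 1], , drop = FALSE] -
                         xyz[p[, 2], , drop = FALSE])^2)))
  }
  rad_mean <- function(xyz, idx) {
    relx <- sweep(xyz[idx, , drop = FALSE], 2, axis$origin)
    zz <- as.vector(relx %*% d)
    mean(sqrt(rowSums((relx - zz %*% t(d))^2)))
  }
  eval_fn <- function(xyz) {
    disp <- xyz - xyz0
    out <- c(q_set1 = pair_mean(xyz, p1),
             q_set2 = pair_mean(xyz, p2),
             gate_rad = rad_mean(xyz, i_gate),
             filter_rad = rad_mean(xyz, i_filter),
             couple = pair_mean(xyz, cp),
             rot_gate = mean(rowSums(disp[i_gate, , drop = FALSE] *
                                       et[i_gate, , drop = FALSE])),
             rot_cyto2 = mean(rowSums(disp[i_cyt2, , drop = FALSE] *
                                        et[i_cyt2, , drop = FALSE])))
    if (!is.null(br)) out <- c(out, bridge = pair_mean(xyz, br))
    out
  }
  m0 <- eval_fn(xyz0)
  tv <- c(q_set1 = q1, q_set2 = q2,
          gate_rad = unname(m0["gate_rad"]) + gate_dil,
          filter_rad = unname(m0["filter_rad"]),
          couple = unname(m0["couple"]),
          rot_gate = rot_gate, rot_cyto2 = rot_cyto)
  wv <- c(q_set1 = 1, q_set2 = 1, gate_rad = 1, filter_rad = 2,
          couple = 2, rot_gate = 1, rot_cyto2 = 0.5)
  if (!is.null(br)) {
    tv <- c(tv, bridge = unname(m0["bridge"]))
    wv <- c(wv, bridge = 2)
  }
  structure(list(eval = eval_fn, targets = tv, weights = wv,
                 sites = sites0, closed = m0, axis = axis,
                 chain_sets = list(set1 = set1, set2 = set2)),
            class = "gating_metrics")
}

#' Choose deformation amplitudes by constraint-target matching
#'
#' One targeting step: linearizes the gating metrics along each candidate
#' mode (finite differences), solves a stiffness-weighted ridge
#' least-squares problem for the amplitude combination whose response moves
#' the metrics toward their targets at minimal elastic energy, then
#' line-searches a scalar along the combined direction against the full
#' nonlinear metrics. The step is bounded so that no site moves more than
#' `max_site_disp` Angstrom.
#'
#' @param ms `tg_modes` of the current coarse model.
#' @param scores score table from [score_modes()] on `ms`.
#' @param modes candidate mode indices (from [select_modes()]).
#' @param metrics a [gating_metrics()] object (fixed reference targets).
#' @param max_site_disp per-step bound on the largest site displacement
#'   (Angstrom).
#' @param ridge relative ridge parameter of the response solve.
#' @return list with `amplitudes` (named per mode, signs included), `a`
#'   (line-search scalar), `achieved` (metric vector after the step),
#'   `gap` (targets minus achieved, weighted), `direction` (n x 3
#'   displacement field), `warning` (TRUE if the step stalled).
#' @export
choose_amplitudes <- function(ms, scores, modes, metrics,
                              max_site_disp = 2.5, ridge = 1e-3) {
  stopifnot(inherits(metrics, "gating_metrics"), length(modes) >= 1)
  cur <- as.matrix(ms$sites[, c("x", "y", "z")])
  m0 <- metrics$eval(cur)
  gap <- metrics$targets - m0
  wv <- metrics$weights
  sgn <- scores$sign[match(modes, scores$mode)]
  eps <- 0.5
  R <- matrix(vapply(seq_along(modes), function(i) {
    U <- sgn[i] * mode_field(ms, modes[i])
    (metrics$eval(cur + eps * U) - m0) / eps
  }, numeric(length(m0))), nrow = length(m0))
  Rw <- R * wv
  gw <- gap * wv
  lam <- ms$values[modes]
  D <- diag(1 / lam, length(modes))
  M <- Rw %*% D %*% t(Rw)
  mu <- ridge * max(diag(M))
  # adaptive ridge: damp until the full-gap solution is not badly
  # ill-conditioned (pathological site displacements)
  for (tries in 1:6) {
    w <- as.vector(D %*% t(Rw) %*% solve(M + mu * diag(nrow(M)), gw))
    dirf <- matrix(0, nrow(cur), 3)
    for (i in seq_along(modes)) {
      dirf <- dirf + w[i] * sgn[i] * mode_field(ms, modes[i])
    }
    mx <- max(sqrt(rowSums(dirf^2)))
    if (mx <= 10 * max_site_disp) break
    mu <- mu * 10
  }
  if (mx < 1e-12) {
    return(list(amplitudes = stats::setNames(numeric(length(modes)),
                                             modes),
                a = 0, achieved = m0, gap = gw, direction = dirf,
                warning = TRUE))
  }
  a_cap <- min(1.3, max_site_disp / mx)
  miss <- function(a) {
    sum(((metrics$eval(cur + a * dirf) - metrics$targets) * wv)^2)
  }
  a <- stats::optimize(miss, c(0, a_cap), tol = 1e-4)$minimum
  if (miss(a_cap) < miss(a)) a <- a_cap
  achieved <- metrics$eval(cur + a * dirf)
  list(amplitudes = stats::setNames(a * w * sgn, modes), a = a,
       achieved = achieved, gap = (metrics$targets - achieved) * wv,
       direction = dirf, warning = a * mx < 1e-3 * max_site_disp)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Rotamer re-pointing after backbone deformation
#'
#' The frame-based all-atom rebuild carries side chains rigidly with their
#' backbone, which can swing an interacting pair apart even when the
#' backbone geometry that supports the interaction is preserved. In a real
#' structure side chains would repack; this pass emulates that at the
#' pseudo-atom level: for every residue pair interacting in the reference
#' structure (salt bridges plus any `extra_pairs`), the distal side-chain
#' atoms of both residues are re-pointed toward each other at their original
#' reach whenever the backbone still allows the contact.
#'
#' @param open deformed atom tibble.
#' @param closed reference atom tibble.
#' @param extra_pairs optional tibble `chain1`, `resseq1`, `chain2`,
#'   `resseq2` of non-salt-bridge contacts to restore.
#' @param max_strain maximum increase of the base-atom (CB) distance,
#'   Angstrom, for which re-pointing is attempted.
#' @return atom tibble.
#' @export
relax_side_chains <- function(open, closed, extra_pairs = NULL,
                              max_strain = 5) {
  sb <- salt_bridges(closed)
  pairs <- tibble(chain1 = sb$chain_basic, resseq1 = sb$resseq_basic,
                  chain2 = sb$chain_acidic, resseq2 = sb$resseq_acidic)
  if (!is.null(extra_pairs)) pairs <- dplyr::bind_rows(pairs, extra_pairs)
  base_xyz <- function(x, ch, rs) {
    r <- x[x$chain == ch & x$resseq == rs, ]
    nm <- if ("CB" %in% r$name) "CB" else "CA"
    as.numeric(r[r$name == nm, c("x", "y", "z")][1, ])
  }
  distal_names <- function(x, ch, rs) {
    setdiff(x$name[x$chain == ch & x$resseq == rs], c("CA", "CB"))
  }
  for (p in seq_len(nrow(pairs))) {
    ch1 <- pairs$chain1[p]; rs1 <- pairs$resseq1[p]
    ch2 <- pairs$chain2[p]; rs2 <- pairs$resseq2[p]
    d1 <- distal_names(open, ch1, rs1)
    d2 <- distal_names(open, ch2, rs2)
    if (length(d1) == 0 || length(d2) == 0) next
    b1c <- base_xyz(closed, ch1, rs1); b2c <- base_xyz(closed, ch2, rs2)
    b1o <- base_xyz(open, ch1, rs1); b2o <- base_xyz(open, ch2, rs2)
    dc <- sqrt(sum((b1c - b2c)^2)); do <- sqrt(sum((b1o - b2o)^2))
    if (do > dc + max_strain) next
    g1c <- colMeans(coords(closed[closed$chain == ch1 &
                                    closed$resseq == rs1 &
                                    closed$name %in% d1, , drop = FALSE]))
    g2c <- colMeans(coords(closed[closed$chain == ch2 &
                                    closed$resseq == rs2 &
                                    closed$name %in% d2, , drop = FALSE]))
    r1 <- sqrt(sum((g1c - b1c)^2)); r2 <- sqrt(sum((g2c - b2c)^2))
    u <- (b2o - b1o) / max(do, 1e-9)
    gap_c <- dc - r1 - r2                  # closed-state group gap
    gap_o <- max(do - r1 - r2, min(gap_c, do - 2))
    # place groups along the line, reproducing the closed gap if possible
    c1 <- b1o + ((do - gap_o) / 2) * u
    c2 <- b2o - ((do - gap_o) / 2) * u
    open <- move_group_to(open, ch1, rs1, d1, c1)
    open <- move_group_to(open, ch2, rs2, d2, c2)
  }
  open
}

# Default z-window of the hydrophobic gate: around the gate residues.
gate_z_window <- function(x, axis) {
  ca <- x[x$name == "CA" & x$resseq %in% c(167, 171, 174), ]
  if (nrow(ca) == 0) ca <- x[x$name == "CA", ]
  zc <- sweep(coords(ca), 2, axis$origin) %*% axis$direction
  range(zc) + c(-2, 2)
}

#' Geometric regularization of a deformed C-alpha trace
#'
#' Linear mode displacement distorts virtual CA-CA bonds at large amplitude.
#' This pass iteratively projects consecutive-bond lengths back into
#' 3.8 +/- 0.2 Angstrom and pushes clashing (< 3.4 A) nonbonded CA pairs
#' apart, using symmetric minimal displacements (SHAKE-style), which keeps
#' the result close to the input in RMSD. All-atom coordinates are rebuilt
#' from the regularized trace.
#'
#' @param d a `deformed_state`.
#' @param x reference all-atom structure the state was built from.
#' @param ms the `tg_modes` used (provides the reference coarse model).
#' @param max_iter iteration cap (error if not converged).
#' @return a `deformed_state` with updated coordinates and report (fields
#'   `iterations`, `max_bond_dev`, `clash_count`).
#' @export
regularize <- function(d, x, ms, max_iter = 500) {
  sites <- d$coarse
  xyz <- as.matrix(sites[, c("x", "y", "z")])
  bonds <- consecutive_bonds(sites)
  it <- 0
  repeat {
    rep0 <- deformation_report(replace_xyz(sites, xyz))
    if (rep0$max_bond_dev <= 0.2 + 1e-9 && rep0$clash_count == 0) break
    if (it >= max_iter) {
      stop("regularization failed to converge after ", max_iter,
           " iterations (max bond deviation ",
           round(rep0$max_bond_dev, 3), " A, ", rep0$clash_count,
           " clashes)", call. = FALSE)
    }
    it <- it + 1
    # bond projection
    for (b in seq_len(nrow(bonds))) {
      i <- bonds[b, 1]; j <- bonds[b, 2]
      v <- xyz[j, ] - xyz[i, ]
      l <- sqrt(sum(v^2))
      if (abs(l - 3.8) > 0.15) {
        corr <- 0.5 * (l - 3.8) * v / l
        xyz[i, ] <- xyz[i, ] + corr
        xyz[j, ] <- xyz[j, ] - corr
      }
    }
    # clash resolution
    dd <- as.matrix(stats::dist(xyz))
    dd[cbind(bonds[, 1], bonds[, 2])] <- Inf
    dd[cbind(bonds[, 2], bonds[, 1])] <- Inf
    diag(dd) <- Inf
    cl <- which(dd < 3.4 & upper.tri(dd), arr.ind = TRUE)
    for (p in seq_len(nrow(cl))) {
      i <- cl[p, 1]; j <- cl[p, 2]
      v <- xyz[j, ] - xyz[i, ]
      l <- sqrt(sum(v^2))
      corr <- 0.5 * (3.45 - l) * v / max(l, 1e-6)
      xyz[i, ] <- xyz[i, ] - corr
      xyz[j, ] <- xyz[j, ] + corr
    }
  }
  new_sites <- replace_xyz(sites, xyz)
  out_struct <- rebuild_all_atom(x, ms$sites, xyz)
  rep1 <- deformation_report(new_sites)
  rep1$iterations <- it
  structure(list(structure = out_struct, coarse = new_sites,
                 amplitudes = d$amplitudes, report = rep1),
            class = "deformed_state")
}

replace_xyz <- function(sites, xyz) {
  sites$x <- xyz[, 1]; sites$y <- xyz[, 2]; sites$z <- xyz[, 3]
  sites
}

# SHAKE-style projection of a CA trace onto bond/clash constraints.
regularize_trace <- function(sites, xyz, max_iter = 500, bond_tol = 0.2) {
  bonds <- consecutive_bonds(sites)
  it <- 0
  repeat {
    rep0 <- deformation_report(replace_xyz(sites, xyz))
    if (rep0$max_bond_dev <= bond_tol + 1e-9 && rep0$clash_count == 0) break
    if (it >= max_iter) {
      stop("regularization failed to converge after ", max_iter,
           " iterations (max bond deviation ",
           round(rep0$max_bond_dev, 3), " A, ", rep0$clash_count,
           " clashes)", call. = FALSE)
    }
    it <- it + 1
    for (b in seq_len(nrow(bonds))) {
      i <- bonds[b, 1]; j <- bonds[b, 2]
      v <- xyz[j, ] - xyz[i, ]
      l <- sqrt(sum(v^2))
      if (abs(l - 3.8) > 0.15) {
        corr <- 0.5 * (l - 3.8) * v / l
        xyz[i, ] <- xyz[i, ] + corr
        xyz[j, ] <- xyz[j, ] - corr
      }
    }
    dd <- as.matrix(stats::dist(xyz))
    dd[cbind(bonds[, 1], bonds[, 2])] <- Inf
    dd[cbind(bonds[, 2], bonds[, 1])] <- Inf
    diag(dd) <- Inf
    cl <- which(dd < 3.4 & upper.tri(dd), arr.ind = TRUE)
    for (p in seq_len(nrow(cl))) {
      i <- cl[p, 1]; j <- cl[p, 2]
      v <- xyz[j, ] - xyz[i, ]
      l <- sqrt(sum(v^2))
      corr <- 0.5 * (3.45 - l) * v / max(l, 1e-6)
      xyz[i, ] <- xyz[i, ] - corr
      xyz[j, ] <- xyz[j, ] + corr
    }
  }
  attr(xyz, "iterations") <- it
  xyz
}

#' Generate a putative open-state model
#'
#' The full constraint-guided pipeline. The closed structure is
#' coarse-grained and its elastic-network modes computed; modes are scored
#' against the gating constraints and the Cn-symmetric candidates retained;
#' a stiffness-weighted linear-response step ([choose_amplitudes()]) moves
#' the structure toward the gating targets; modes are recomputed along the
#' path (the deformation is followed adiabatically in capped steps) until
#' the targets are met; the C-alpha trace is then regularized, all-atom
#' coordinates are rebuilt from local frames, and interacting side chains
#' re-pointed ([relax_side_chains()]). The report compares open vs closed:
#' alternate-set marker distances, rotation angles, displacement of filter
#' vs gate, and symmetry order parameters.
#'
#' @param x closed-state atom tibble (hexamer or compatible fixture).
#' @param constraints a [constraint_spec()]; `NULL` uses defaults with
#'   coiled-coil pairs auto-derived when residue 316/319 tags are present.
#' @param targets see [gating_metrics()]; default: marker dilation to
#'   22.3 / 18.4 Angstrom at residue 152 with the standard release/rigidity
#'   terms.
#' @param cutoff,n_modes elastic-network parameters per step.
#' @param min_collectivity,min_sym candidate-mode filters (the candidate
#'   pool is every passing mode; the report lists the top-scoring three).
#' @param max_steps cap on path steps.
#' @param step_cap largest per-site displacement per step, Angstrom.
#' @param tol weighted target tolerance for convergence.
#' @param keep_contacts optional contact pairs (tibble `chain1`, `resseq1`,
#'   `chain2`, `resseq2`) whose side chains are re-pointed after
#'   deformation, in addition to reference salt bridges.
#' @param rotation_residues residues reported in the rotation table.
#' @return object of class `open_state`: list with `open` (atom tibble),
#'   `closed`, `state` (`deformed_state`), `scores` (last step), `modes`
#'   (top candidates), `report`.
#' @export
generate_open_state <- function(x, constraints = NULL, targets = NULL,
                                cutoff = 13, n_modes = 150,
                                min_collectivity = 0.02, min_sym = 0.5,
                                max_steps = 20, step_cap = 3, tol = 0.15,
                                keep_contacts = NULL,
                                rotation_residues = c(155, 167, 171)) {
  chains <- sort(unique(x$chain[!x$het]))
  if (is.null(constraints)) {
    constraints <- constraint_spec()
    if (all(c(316L, 319L) %in% x$resseq)) {
      constraints$cc_break_pairs <- default_cc_pairs(chains)
    }
  }
  if (is.null(keep_contacts) && all(c(199L, 262L, 304L, 246L) %in% x$resseq)) {
    keep_contacts <- dplyr::bind_rows(
      tibble(chain1 = chains, resseq1 = 262L, chain2 = chains,
             resseq2 = 199L),
      tibble(chain1 = chains, resseq1 = 304L, chain2 = chains,
             resseq2 = 246L)
    )
  }
  axis <- compute_pore_axis(x)
  gm <- gating_metrics(x, constraints, axis, targets %||% list())
  coarse0 <- gm$sites
  cur <- coarse0
  steps <- list()
  scores <- NULL; ms <- NULL
  n_modes_eff <- min(n_modes, 3 * nrow(coarse0) - 6)
  ord <- constraints$symmetry_order
  for (step in seq_len(max_steps)) {
    ms <- compute_modes(cur, cutoff = cutoff, n_modes = n_modes_eff)
    scores <- score_modes(ms, constraints, axis)
    pool <- tryCatch(
      select_modes(scores, top_k = nrow(scores),
                   min_collectivity = min_collectivity,
                   min_sym = min_sym),
      error = function(e) NULL)
    if (is.null(pool)) break
    amp <- choose_amplitudes(ms, scores, pool, gm,
                             max_site_disp = step_cap)
    cur <- replace_xyz(cur, as.matrix(cur[, c("x", "y", "z")]) +
                         amp$a * amp$direction)
    # the gating motion is Cn-symmetric by assumption; project out
    # numerical symmetry drift so the candidate pool stays clean
    cur <- symmetrize_sites(cur, ord, axis)
    steps[[step]] <- amp$amplitudes
    wg <- max(abs((gm$eval(as.matrix(cur[, c("x", "y", "z")])) -
                     gm$targets) * gm$weights))
    if (wg < tol || amp$warning) break
  }
  # regularize; if that degrades the targets, refine once more and re-relax
  for (pass in 1:2) {
    xyz <- regularize_trace(coarse0,
                            as.matrix(cur[, c("x", "y", "z")]))
    cur <- symmetrize_sites(replace_xyz(cur, xyz), ord, axis)
    wg <- max(abs((gm$eval(as.matrix(cur[, c("x", "y", "z")])) -
                     gm$targets) * gm$weights))
    if (wg < tol || pass == 2) break
    ms <- compute_modes(cur, cutoff = cutoff, n_modes = n_modes_eff)
    scores <- score_modes(ms, constraints, axis)
    pool <- tryCatch(
      select_modes(scores, top_k = nrow(scores),
                   min_collectivity = min_collectivity,
                   min_sym = min_sym),
      error = function(e) NULL)
    if (is.null(pool)) break
    amp <- choose_amplitudes(ms, scores, pool, gm,
                             max_site_disp = step_cap)
    cur <- replace_xyz(cur, as.matrix(cur[, c("x", "y", "z")]) +
                         amp$a * amp$direction)
    cur <- symmetrize_sites(cur, ord, axis)
    steps[[length(steps) + 1]] <- amp$amplitudes
  }
  open <- rebuild_all_atom(x, coarse0, as.matrix(cur[, c("x", "y", "z")]))
  open <- relax_side_chains(open, x, extra_pairs = keep_contacts)
  dstate <- structure(list(structure = open, coarse = cur,
                           amplitudes = steps,
                           report = deformation_report(cur)),
                      class = "deformed_state")
  top3 <- select_modes(scores, top_k = 3,
                       min_collectivity = min_collectivity,
                       min_sym = min_sym)
  report <- open_state_report(x, open, axis, gm, scores, top3,
                              constraints, rotation_residues,
                              n_steps = length(steps))
  structure(list(open = open, closed = x, state = dstate, scores = scores,
                 modes = top3, constraints = constraints,
                 metrics = gm, report = report),
            class = "open_state")
}
open_state_report <- function(closed, open, axis, gm, scores, modes,
                              constraints, rotation_residues,
                              n_steps = NA_integer_) {
  q_res <- 152
  qc <- interchain_distance(closed, q_res, axis = axis)
  qo <- interchain_distance(open, q_res, axis = axis)
  rot <- tryCatch(
    helix_rotation(closed, open, rotation_residues, axis = axis),
    error = function(e) NULL
  )
  sym <- tryCatch(list(
    order3 = symmetry_order_parameter(open, 3),
    order6 = symmetry_order_parameter(open, 6)
  ), error = function(e) NULL)
  # constraint bookkeeping: the filter must move less than the gate
  csel <- to_coarse(closed)
  osel <- to_coarse(open)
  dsp <- sqrt(rowSums((as.matrix(osel[, c("x", "y", "z")]) -
                         as.matrix(csel[, c("x", "y", "z")]))^2))
  filt <- mean(dsp[csel$resseq %in% constraints$filter_rigid])
  gate <- mean(dsp[csel$resseq %in% constraints$gate_release])
  # filter rigidity is a shape statement: RMSD of the filter ring after
  # optimal rigid superposition (the ring may ride the collective twist)
  fi <- csel$resseq %in% constraints$filter_rigid
  filt_shape <- kabsch(as.matrix(osel[fi, c("x", "y", "z")]),
                       as.matrix(csel[fi, c("x", "y", "z")]))$rmsd
  achieved <- gm$eval(as.matrix(osel[, c("x", "y", "z")]))
  wgap <- max(abs((achieved - gm$targets) * gm$weights))
  list(
    q_closed = qc, q_open = qo, rotation = rot, symmetry = sym,
    filter_mean_disp = filt, gate_mean_disp = gate,
    filter_shape_rmsd = filt_shape,
    n_steps = n_steps, amplitude_warning = wgap > 0.5,
    achieved = achieved, targets = gm$targets,
    selected_modes = modes,
    low_symmetry = constraints$symmetry_order == 1
  )
}

#' @export
print.open_state <- function(x, ...) {
  r <- x$report
  cat("<open_state> top modes:", paste(r$selected_modes, collapse = ","),
      " steps:", r$n_steps, "\n")
  cat("  marker distances closed set1/set2: ",
      signif(r$q_closed$mean[1], 4), "/", signif(r$q_closed$mean[2], 4),
      "  open: ", signif(r$q_open$mean[1], 4), "/",
      signif(r$q_open$mean[2], 4), "\n", sep = "")
  invisible(x)
}

#' @method tidy open_state
#' @export
tidy.open_state <- function(x, ...) {
  r <- x$report
  dplyr::bind_rows(
    tibble(quantity = "marker_dist_set1", closed = r$q_closed$mean[1],
           open = r$q_open$mean[1]),
    tibble(quantity = "marker_dist_set2", closed = r$q_closed$mean[2],
           open = r$q_open$mean[2]),
    if (!is.null(r$rotation)) {
      rr <- r$rotation |>
        dplyr::distinct(.data$resseq, .keep_all = TRUE)
      tibble(quantity = paste0("rotation_", rr$resseq),
             closed = 0, open = rr$theta_mean)
    }
  )
}

#' @method glance open_state
#' @export
glance.open_state <- function(x, ...) {
  r <- x$report
  tibble(
    n_steps = r$n_steps,
    target_warning = r$amplitude_warning,
    filter_mean_disp = r$filter_mean_disp,
    gate_mean_disp = r$gate_mean_disp,
    sym3 = if (!is.null(r$symmetry)) r$symmetry$order3 else NA_real_,
    sym6 = if (!is.null(r$symmetry)) r$symmetry$order6 else NA_real_
  )
}
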