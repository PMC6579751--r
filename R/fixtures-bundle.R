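#' Specification for a synthetic hexameric helix-bundle channel
#'
#' Describes an idealized Cn-symmetric bundle of straight alpha-helices around
#' a central pore, with tagged positions mimicking the functional register of
#' a CRAC-type pore helix: an acidic selectivity-filter ring near the
#' extracellular end, a hydrophobic gate below it, a basic ring, and polar /
#' charged residues at the cytosolic end. Residues carry real amino-acid names
#' so that salt-bridge and charge-mapping code paths run unmodified.
#'
#' @param n_helices number of helices (chains).
#' @param helix_length residues per helix.
#' @param bundle_radius distance pore axis to helix axis, Angstrom.
#' @param helix_tilt degrees; positive tilts helix tops (+z, extracellular)
#'   toward the pore axis.
#' @param rise_per_residue,twist_per_residue ideal helix parameters
#'   (Angstrom, degrees).
#' @param symmetry_order rotational symmetry; must divide `n_helices`.
#' @param start_resseq author-number of the first residue; the default 144
#'   puts the tagged positions at the channel's canonical numbers (Q152,
#'   R155, K157, K163, L167, G170, F171, V174, E178).
#' @param sequence character vector of 3-letter residue names, length
#'   `helix_length`; default is a generic hydrophobic repeat with the tags
#'   above written in at their register.
#' @param phase0 azimuthal phase (degrees) of the first residue about its
#'   helix axis; the default faces the gate residue toward the pore.
#' @param helix_radius radius of the C-alpha spiral about the helix axis.
#' @param seed integer; fixtures are deterministic functions of (spec, seed).
#' @return object of class `bundle_spec`.
#' @export
bundle_spec <- function(n_helices = 6, helix_length = 40, bundle_radius = 10,
                        helix_tilt = 0, rise_per_residue = 1.5,
                        twist_per_residue = 100, symmetry_order = 6,
                        start_resseq = 144, sequence = NULL, phase0 = 0,
                        helix_radius = 2.3, seed = 1L) {
  if (n_helices %% symmetry_order != 0) {
    stop("n_helices must be divisible by symmetry_order", call. = FALSE)
  }
  if (is.null(sequence)) {
    sequence <- rep(c("LEU", "ALA", "VAL", "SER"),
                    length.out = helix_length)
    tags <- c(`152` = "GLN", `155` = "ARG", `157` = "LYS", `163` = "LYS",
              `167` = "LEU", `170` = "GLY", `171` = "PHE", `174` = "VAL",
              `178` = "GLU")
    idx <- as.integer(names(tags)) - start_resseq + 1L
    ok <- idx >= 1 & idx <= helix_length
    sequence[idx[ok]] <- tags[ok]
  }
  stopifnot(length(sequence) == helix_length)
  structure(list(
    n_helices = n_helices, helix_length = helix_length,
    bundle_radius = bundle_radius, helix_tilt = helix_tilt,
    rise_per_residue = rise_per_residue,
    twist_per_residue = twist_per_residue,
    symmetry_order = symmetry_order, start_resseq = start_resseq,
    sequence = sequence, phase0 = phase0, helix_radius = helix_radius,
    seed = as.integer(seed)
  ), class = "bundle_spec")
}

# Side-chain pseudo-atom templates: atom names placed beyond CB along a
# direction `dir`, at the stated distance from CB. Coarse but sufficient for
# salt-bridge detection, charge mapping, rotation metrics and SASA deltas.
SIDE_CHAIN_ATOMS <- list(
  GLU = list(atoms = c("OE1", "OE2"), dist = c(2.4, 2.4),
             spread = c(-0.55, 0.55), element = c("O", "O")),
  ASP = list(atoms = c("OD1", "OD2"), dist = c(1.9, 1.9),
             spread = c(-0.55, 0.55), element = c("O", "O")),
  LYS = list(atoms = "NZ", dist = 3.2, spread = 0, element = "N"),
  ARG = list(atoms = c("NE", "NH1", "NH2"), dist = c(2.6, 3.6, 3.6),
             spread = c(0, -0.6, 0.6), element = c("N", "N", "N")),
  TYR = list(atoms = "OH", dist = 3.6, spread = 0, element = "O"),
  GLN = list(atoms = c("OE1", "NE2"), dist = c(2.3, 2.3),
             spread = c(-0.5, 0.5), element = c("O", "N")),
  THR = list(atoms = "CG2", dist = 1.3, spread = 0, element = "C"),
  ILE = list(atoms = "CD1", dist = 2.4, spread = 0, element = "C"),
  LEU = list(atoms = "CD1", dist = 2.0, spread = 0, element = "C"),
  PHE = list(atoms = "CZ", dist = 2.9, spread = 0, element = "C")
)

# Build one residue's atoms given CA position, a local helix axis direction
# (unit), and the outward side-chain direction (unit, perpendicular-ish).
residue_atoms <- function(resname, resseq, chain, ca, side_dir, axis_dir) {
  rows <- list(tibble(name = "CA", element = "C", resname = resname,
                      resseq = resseq, chain = chain,
                      x = ca[1], y = ca[2], z = ca[3]))
  if (resname != "GLY") {
    # canonical-ish CB: mostly along the side direction, nudged against the
    # helix direction as in a real L-amino acid
    cb_dir <- side_dir * 0.94 - axis_dir * 0.34
    cb_dir <- cb_dir / sqrt(sum(cb_dir^2))
    cb <- ca + 1.53 * cb_dir
    rows <- c(rows, list(tibble(name = "CB", element = "C",
                                resname = resname, resseq = resseq,
                                chain = chain, x = cb[1], y = cb[2],
                                z = cb[3])))
    tmpl <- SIDE_CHAIN_ATOMS[[resname]]
    if (!is.null(tmpl)) {
      perp <- pracma_cross(axis_dir, cb_dir)
      perp <- perp / sqrt(sum(perp^2))
      for (j in seq_along(tmpl$atoms)) {
        p <- cb + tmpl$dist[j] * cb_dir + tmpl$spread[j] * perp
        rows <- c(rows, list(tibble(name = tmpl$atoms[j],
                                    element = tmpl$element[j],
                                    resname = resname, resseq = resseq,
                                    chain = chain,
                                    x = p[1], y = p[2], z = p[3])))
      }
    }
  }
  dplyr::bind_rows(rows)
}

# Place an ideal helix along an axis segment; returns an atom tibble.
# `axis_from`/`axis_to` are 3-vectors; residues are spaced evenly along the
# segment with the given twist; side chains point radially out of the helix.
place_helix <- function(chain, resseq, resnames, axis_from, axis_to,
                        twist = 100, phase0 = 0, helix_radius = 2.3) {
  nres <- length(resseq)
  d <- axis_to - axis_from
  L <- sqrt(sum(d^2))
  d <- d / L
  step <- if (nres > 1) L / (nres - 1) else 0
  # local frame perpendicular to the axis; e1 points away from the z axis
  ref <- c(axis_from[1], axis_from[2], 0)
  if (sqrt(sum(ref^2)) < 1e-8) ref <- c(1, 0, 0)
  e1 <- ref - sum(ref * d) * d
  e1 <- e1 / sqrt(sum(e1^2))
  e2 <- pracma_cross(d, e1)
  out <- vector("list", nres)
  for (i in seq_len(nres)) {
    phi <- deg2rad(phase0 + (i - 1) * twist)
    axp <- axis_from + (i - 1) * step * d
    side <- cos(phi) * e1 + sin(phi) * e2
    ca <- axp + helix_radius * side
    out[[i]] <- residue_atoms(resnames[i], resseq[i], chain, ca, side, d)
  }
  dplyr::bind_rows(out)
}

#' Build a synthetic Cn-symmetric helix bundle
#'
#' Places `n_helices` ideal helices on a circle about the z axis (+z is the
#' extracellular side by convention), with exact rotational symmetry by
#' construction. The output is a regular atom tibble and round-trips through
#' [write_structure()] / [read_structure()].
#'
#' @param spec a [bundle_spec()].
#' @return atom tibble with chains `A`, `B`, ... in azimuthal order; the spec
#'   is attached as attribute `"bundle_spec"`.
#' @export
build_bundle <- function(spec) {
  stopifnot(inherits(spec, "bundle_spec"))
  n <- spec$n_helices
  tilt <- deg2rad(spec$helix_tilt)
  len <- (spec$helix_length - 1) * spec$rise_per_residue
  chains <- vector("list", n)
  for (k in seq_len(n)) {
    th <- 2 * pi * (k - 1) / n
    er <- c(cos(th), sin(th), 0)
    base <- spec$bundle_radius * er
    top <- base + len * (cos(tilt) * c(0, 0, 1) - sin(tilt) * er)
    chains[[k]] <- place_helix(
      chain = LETTERS[k],
      resseq = spec$start_resseq + seq_len(spec$helix_length) - 1L,
      resnames = spec$sequence,
      axis_from = base, axis_to = top,
      twist = spec$twist_per_residue, phase0 = spec$phase0,
      helix_radius = spec$helix_radius
    )
  }
  x <- as_structure(dplyr::bind_rows(chains))
  # exact construction axes, used by apply_twist_open for rigid ground truth
  axes <- lapply(seq_len(n), function(k) {
    th <- 2 * pi * (k - 1) / n
    er <- c(cos(th), sin(th), 0)
    list(origin = spec$bundle_radius * er,
         direction = cos(tilt) * c(0, 0, 1) - sin(tilt) * er)
  })
  names(axes) <- LETTERS[seq_len(n)]
  # validity: the bundle must leave an open pore and must not self-intersect
  min_r <- spec$bundle_radius - spec$helix_radius - 4.5
  if (min_r <= 0) {
    stop("bundle_spec leaves no open pore (bundle_radius too small for the ",
         "helix envelope)", call. = FALSE)
  }
  ca <- coords(x[x$name == "CA", ])
  ch <- x$chain[x$name == "CA"]
  dmin <- Inf
  for (k in seq_len(n - 1)) {
    a <- ca[ch == LETTERS[k], , drop = FALSE]
    b <- ca[ch != LETTERS[k] & ch > LETTERS[k], , drop = FALSE]
    if (nrow(b) > 0) {
      dd <- sqrt(outer(rowSums(a^2), rowSums(b^2), "+") - 2 * a %*% t(b))
      dmin <- min(dmin, dd, na.rm = TRUE)
    }
  }
  if (is.finite(dmin) && dmin < 2.0) {
    stop("bundle_spec is self-intersecting (inter-chain CA distance ",
         round(dmin, 2), " A)", call. = FALSE)
  }
  attr(x, "bundle_spec") <- spec
  attr(x, "helix_axes") <- axes
  x
}

#' Ground-truth twist-to-open transform for synthetic fixtures
#'
#' Encodes the alternating two-set gating pattern: helices 1,3,5 (set 1) and
#' 2,4,6 (set 2) receive independent axial spins and radial displacements.
#'
#' @param rotation_set1,rotation_set2 degrees of rotation about the chosen
#'   axis (positive = counterclockwise viewed from +z / extracellular).
#' @param radial_shift_set1,radial_shift_set2 outward radial translation in
#'   Angstrom (negative moves inward).
#' @param applied_about `"own_axis"` (each helix spins about its own axis) or
#'   `"pore_axis"` (whole-chain rotation about the pore axis).
#' @return object of class `twist_transform`.
#' @export
twist_open_transform <- function(rotation_set1 = 0, rotation_set2 = 0,
                                 radial_shift_set1 = 0, radial_shift_set2 = 0,
                                 applied_about = c("own_axis", "pore_axis")) {
  applied_about <- match.arg(applied_about)
  structure(list(rotation_set1 = rotation_set1,
                 rotation_set2 = rotation_set2,
                 radial_shift_set1 = radial_shift_set1,
                 radial_shift_set2 = radial_shift_set2,
                 applied_about = applied_about),
            class = "twist_transform")
}

#' Apply a ground-truth twist-open transform to a bundle
#'
#' Rigid per-chain motion: rotation about the chain's own helix axis (or the
#' pore axis) plus radial translation, alternating between the two chain
#' sets. Chains are assigned to sets in alphabetical (= azimuthal) order:
#' 1st, 3rd, 5th chain form set 1.
#'
#' @param x atom tibble (even chain count).
#' @param t a [twist_open_transform()].
#' @param segment optional integer range `c(lo, hi)` of residue numbers used
#'   to fit each chain's own axis (defaults to all residues of the chain).
#' @param residues optional integer vector of residue numbers to move; atoms
#'   of other residues stay fixed (e.g. twist the pore helix while holding
#'   the peripheral helices still). Default: move everything.
#' @return transformed atom tibble; the transform is recorded in attribute
#'   `"twist_transform"`.
#' @export
apply_twist_open <- function(x, t, segment = NULL, residues = NULL) {
  stopifnot(inherits(t, "twist_transform"))
  chains <- sort(unique(x$chain))
  if (length(chains) %% 2 != 0) {
    stop("twist-open transform needs an even chain count", call. = FALSE)
  }
  set1 <- chains[seq(1, length(chains), by = 2)]
  pore_ax <- list(origin = c(0, 0, 0), direction = c(0, 0, 1))
  ca_all <- x[x$name == "CA", ]
  if (nrow(ca_all) >= 3) {
    pore_ax <- principal_axis(coords(ca_all))
    if (pore_ax$direction[3] < 0) pore_ax$direction <- -pore_ax$direction
  }
  out <- x
  for (ch in chains) {
    in1 <- ch %in% set1
    rot <- if (in1) t$rotation_set1 else t$rotation_set2
    shift <- if (in1) t$radial_shift_set1 else t$radial_shift_set2
    sel <- out$chain == ch
    if (!is.null(residues)) sel <- sel & out$resseq %in% residues
    if (!any(sel)) next
    xyz <- coords(out[sel, ])
    axes <- attr(x, "helix_axes")
    if (!is.null(axes) && ch %in% names(axes) && is.null(segment)) {
      own <- axes[[ch]]
    } else {
      ca <- x[x$name == "CA" & x$chain == ch, ]
      if (!is.null(segment)) {
        ca <- ca[ca$resseq >= segment[1] & ca$resseq <= segment[2], ]
      }
      own <- principal_axis(coords(ca))
    }
    if (sum(own$direction * pore_ax$direction) < 0) {
      own$direction <- -own$direction
    }
    if (rot != 0) {
      ax <- if (t$applied_about == "own_axis") own else pore_ax
      xyz <- rotate_about_line(xyz, ax$origin, ax$direction, rot)
      own$origin <- as.vector(rotate_about_line(
        matrix(own$origin, 1, 3), ax$origin, ax$direction, rot))
    }
    if (shift != 0) {
      r <- own$origin - pore_ax$origin
      r <- r - sum(r * pore_ax$direction) * pore_ax$direction
      r <- r / sqrt(sum(r^2))
      xyz <- sweep(xyz, 2, -shift * r)
    }
    out[sel, c("x", "y", "z")] <- as.data.frame(xyz)
  }
  attr(out, "twist_transform") <- t
  attr(out, "chain_sets") <- list(set1 = set1, set2 = setdiff(chains, set1))
  out
}
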