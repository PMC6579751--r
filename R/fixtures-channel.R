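#' Synthetic closed-state model of a hexameric CRAC-type channel
#'
#' Builds a fully synthetic, idealized stand-in for the closed-state crystal
#' structure of the hexameric Orai channel: six subunits, each contributing a
#' pore-lining TM1 helix plus peripheral TM2/TM3/TM4 helices and a cytosolic
#' TM4 extension, using the channel's author residue numbering (Q152, R155,
#' K157, K163, L167, G170, F171, V174, E178 on TM1; C198/Y199 on TM2; E245,
#' T246, A247, E262 on TM3; L304 on TM4; I316, L319 on TM4-ext). It is a
#' geometric emulation, not an experimental structure:
#'
#' * the pore-lining TM1 ring is exactly C6-symmetric and is calibrated so
#'   that the alternate-chain Q152 C-alpha distance equals
#'   `q152_distance` (default 16.2 Angstrom, the closed-state value);
#' * TM4-ext helices pair up on neighboring subunits (an I316--L319 contact
#'   per pair), which breaks the overall symmetry from C6 down to C3 -- the
#'   pore/overall symmetry mismatch characteristic of this channel family;
#' * each subunit carries an intra-chain K157--E245 salt bridge and an
#'   E262--Y199 hydrogen-bond contact, and R155 side-chain nitrogens point
#'   into the pore;
#' * loop2 (which carries E221) is omitted by default, mirroring the
#'   unresolved loop of the closed-state crystal structure; with
#'   `include_loop2 = TRUE` a single E221 pseudo-residue per chain is placed
#'   where a clockwise R155 rotation of `loop2_rotation` degrees would land
#'   the guanidinium group, so the R155--E221 bridge forms only in a twisted
#'   open form.
#'
#' @param q152_distance target closed-state alternate-chain Q152 CA--CA
#'   distance, Angstrom.
#' @param include_loop2 place the E221 pseudo-residue (see above).
#' @param loop2_rotation clockwise TM1 rotation (degrees, negative) used to
#'   position E221 when `include_loop2 = TRUE`.
#' @param tm1_top_radius radius (Angstrom) of the TM1 helix axis at the
#'   extracellular end; together with the calibrated bottom radius this sets
#'   the inward tilt of the pore helices and hence the closed-gate
#'   constriction (default 7.2).
#' @return atom tibble; chain sets and builder parameters are attached as
#'   attributes (`"channel_params"`).
#' @export
synthetic_closed_channel <- function(q152_distance = 16.2,
                                     include_loop2 = FALSE,
                                     loop2_rotation = -58,
                                     tm1_top_radius = 7.2) {
  target_rho <- q152_distance / sqrt(3)
  # two-pass calibration of the TM1 bottom radius: the Q152 ring radius is an
  # affine function of it, so one correction lands exactly on target
  rb <- target_rho
  for (pass in 1:4) {
    ca <- tm1_q152_radius(rb, tm1_top_radius)
    rb <- rb + (target_rho - ca)
  }
  chains <- lapply(seq_len(6), function(k) {
    build_subunit(k, rb1 = rb, rt1 = tm1_top_radius)
  })
  x <- as_structure(dplyr::bind_rows(chains))
  x <- engineer_channel_links(x)
  if (include_loop2) {
    x <- add_loop2_ghost(x, loop2_rotation)
  }
  attr(x, "channel_params") <- list(
    q152_distance = q152_distance, tm1_bottom_radius = rb,
    tm1_top_radius = tm1_top_radius, include_loop2 = include_loop2,
    loop2_rotation = loop2_rotation, symmetry_order = 3,
    tm1_range = c(144L, 183L), tm4ext_range = c(311L, 326L),
    synthetic = TRUE
  )
  x
}

# Q152 CA ring radius of a TM1 helix with given bottom/top axis radii.
tm1_q152_radius <- function(rb1, rt1) {
  h <- tm1_helix("A", 0, rb1, rt1)
  ca <- h[h$name == "CA" & h$resseq == 152, ]
  sqrt(ca$x^2 + ca$y^2)
}

TM1_SEQ <- local({
  s <- rep(c("LEU", "ALA", "VAL", "SER"), length.out = 40)
  tags <- c(`152` = "GLN", `155` = "ARG", `157` = "LYS", `163` = "LYS",
            `167` = "LEU", `170` = "GLY", `171` = "PHE", `174` = "VAL",
            `178` = "GLU")
  s[as.integer(names(tags)) - 143L] <- tags
  s
})

seg_sequence <- function(len, tags = NULL, start = 1L) {
  s <- rep(c("ALA", "LEU", "SER", "VAL"), length.out = len)
  if (!is.null(tags)) s[as.integer(names(tags)) - start + 1L] <- tags
  s
}

tm1_helix <- function(chain, az_deg, rb1, rt1) {
  az <- deg2rad(az_deg)
  er <- c(cos(az), sin(az), 0)
  place_helix(chain, 144:183, TM1_SEQ,
              axis_from = rb1 * er,
              axis_to = rt1 * er + c(0, 0, 58.5),
              twist = 100, phase0 = 0, helix_radius = 2.3)
}

# One subunit: TM1 (up), TM2 (down), TM3 (up), TM4 (down) + TM4-ext.
# Even-index subunits (k odd in 1-based counting: A, C, E) swing their
# TM4-ext toward the next subunit, odd-index ones toward the previous, so
# TM4-exts pair up (A-B, C-D, E-F): overall symmetry C3, pore symmetry C6.
build_subunit <- function(k, rb1, rt1) {
  az0 <- 60 * (k - 1)
  pol <- function(r, daz, z) {
    a <- deg2rad(az0 + daz)
    c(r * cos(a), r * sin(a), z)
  }
  toward_next <- k %% 2 == 1
  # paired exts converge azimuthally below the membrane: A's swings toward
  # B's and vice versa, meeting at ~9 A axis separation
  ext_daz <- if (toward_next) 52 else 15
  ext_r <- if (toward_next) 24.5 else 26.5
  # helix-axis separations are kept at ~8-9 A (physical packing) between
  # TM1-TM2, TM2-TM3, TM3-TM4 and across subunit interfaces
  dplyr::bind_rows(
    tm1_helix(LETTERS[k], az0, rb1, rt1),
    place_helix(LETTERS[k], 196:216,
                seg_sequence(21, c(`198` = "CYS", `199` = "TYR"), 196L),
                axis_from = pol(14.5, 30, 52), axis_to = pol(14.5, 30, 22),
                twist = 100, phase0 = 40),
    place_helix(LETTERS[k], 235:264,
                seg_sequence(30, c(`245` = "GLU", `246` = "THR",
                                   `247` = "ALA", `262` = "GLU"), 235L),
                axis_from = pol(17, 60, 4), axis_to = pol(17, 60, 47.5),
                twist = 100, phase0 = 120),
    place_helix(LETTERS[k], 288:310,
                seg_sequence(23, c(`304` = "LEU"), 288L),
                axis_from = pol(22, 40, 48), axis_to = pol(22, 40, 15),
                twist = 100, phase0 = 200),
    place_helix(LETTERS[k], 311:326,
                seg_sequence(16, c(`316` = "ILE", `319` = "LEU"), 311L),
                axis_from = pol(22, 40, if (toward_next) 13.2 else 13.6),
                axis_to = pol(ext_r, ext_daz, -8),
                twist = 100, phase0 = 340)
  )
}

# Reposition the distal side-chain atoms of residue (chain, resseq) so that
# their centroid sits on the line toward a target point, `reach` Angstrom
# from CB (or CA for GLY), preserving the atom group's internal offsets.
point_side_chain_at <- function(x, chain, resseq, target, gap = NULL) {
  sel <- x$chain == chain & x$resseq == resseq
  res <- x[sel, ]
  base_atom <- if ("CB" %in% res$name) "CB" else "CA"
  base <- as.numeric(res[res$name == base_atom, c("x", "y", "z")])
  distal <- setdiff(res$name, c("CA", "CB"))
  if (length(distal) == 0) return(x)
  dir <- target - base
  dist_bt <- sqrt(sum(dir^2))
  dir <- dir / dist_bt
  old <- coords(res[res$name %in% distal, , drop = FALSE])
  reach <- mean(sqrt(rowSums(sweep(old, 2, base)^2)))
  if (!is.null(gap)) reach <- max(dist_bt - gap, 1.0)
  ctr_new <- base + reach * dir
  spread <- sweep(old, 2, colMeans(old))
  # keep the group's internal geometry, re-centered on the new direction
  xyz <- sweep(spread, 2, -ctr_new)
  x[sel & x$name %in% distal, c("x", "y", "z")] <- as.data.frame(xyz)
  x
}

residue_atom_xyz <- function(x, chain, resseq, name) {
  r <- x[x$chain == chain & x$resseq == resseq & x$name == name, ]
  if (nrow(r) == 0) stop("atom not found: ", chain, resseq, ":", name)
  as.numeric(r[1, c("x", "y", "z")])
}

# Engineer the closed-state interaction network.
engineer_channel_links <- function(x) {
  chains <- sort(unique(x$chain))
  axis_dir <- c(0, 0, 1)
  for (i in seq_along(chains)) {
    ch <- chains[i]
    # pore-facing rings at defined radii from the axis: R155 guanidinium
    # points into the pore (closed-state orientation), K163 lines the basic
    # region, F171 forms the narrow hydrophobic gate, E178 the filter ring
    ca155 <- residue_atom_xyz(x, ch, 155, "CA")
    x <- point_side_chain_at(x, ch, 155, c(0, 0, ca155[3]), gap = 4.5)
    ca163 <- residue_atom_xyz(x, ch, 163, "CA")
    x <- point_side_chain_at(x, ch, 163, c(0, 0, ca163[3]), gap = 3.5)
    ca171 <- residue_atom_xyz(x, ch, 171, "CA")
    x <- point_side_chain_at(x, ch, 171, c(0, 0, ca171[3]), gap = 2.5)
    ca178 <- residue_atom_xyz(x, ch, 178, "CA")
    x <- point_side_chain_at(x, ch, 178, c(0, 0, ca178[3]), gap = 2.6)
    # intra-chain K157-E245 salt bridge (TM1-TM3 coupling)
    ca157 <- residue_atom_xyz(x, ch, 157, "CA")
    ca245 <- residue_atom_xyz(x, ch, 245, "CA")
    mid <- (ca157 + ca245) / 2
    u <- (ca157 - ca245); u <- u / sqrt(sum(u^2))
    x <- move_group_to(x, ch, 157, "NZ", mid + 1.45 * u)
    x <- move_group_to(x, ch, 245, c("OE1", "OE2"), mid - 1.45 * u)
    # intra-chain E262-Y199 hydrogen bond
    e262 <- residue_atom_xyz(x, ch, 262, "CA")
    y199 <- residue_atom_xyz(x, ch, 199, "CA")
    mid2 <- (e262 + y199) / 2
    v <- (y199 - e262); v <- v / sqrt(sum(v^2))
    x <- move_group_to(x, ch, 199, "OH", mid2 + 1.4 * v)
    x <- move_group_to(x, ch, 262, c("OE1", "OE2"), mid2 - 1.4 * v)
    # intra-chain L304 against T246/A247 (TM3-TM4 packing)
    l304 <- residue_atom_xyz(x, ch, 304, "CA")
    t246 <- residue_atom_xyz(x, ch, 246, "CA")
    mid3 <- (l304 + t246) / 2
    w <- (l304 - t246); w <- w / sqrt(sum(w^2))
    x <- move_group_to(x, ch, 304, "CD1", mid3 + 1.9 * w)
    x <- move_group_to(x, ch, 246, "CG2", mid3 - 1.9 * w)
  }
  # inter-chain coiled-coil contacts I316(A)-L319(B) on paired TM4-exts
  for (k in seq(1, length(chains), by = 2)) {
    a <- chains[k]; b <- chains[k + 1]
    i316 <- residue_atom_xyz(x, a, 316, "CA")
    l319 <- residue_atom_xyz(x, b, 319, "CA")
    mid <- (i316 + l319) / 2
    u <- (i316 - l319); u <- u / sqrt(sum(u^2))
    x <- move_group_to(x, a, 316, "CD1", mid + 1.9 * u)
    x <- move_group_to(x, b, 319, "CD1", mid - 1.9 * u)
  }
  x
}

# Move a named atom group of one residue so its centroid is at `pos`.
move_group_to <- function(x, chain, resseq, names, pos) {
  sel <- x$chain == chain & x$resseq == resseq & x$name %in% names
  if (!any(sel)) stop("atoms not found: ", chain, resseq)
  old <- coords(x[sel, , drop = FALSE])
  shift <- pos - colMeans(old)
  x[sel, c("x", "y", "z")] <- as.data.frame(sweep(old, 2, -shift))
  x
}

# Place the E221 loop2 pseudo-residue where a clockwise TM1 rotation of
# `rotation` degrees would carry the R155 guanidinium centroid.
add_loop2_ghost <- function(x, rotation) {
  chains <- sort(unique(x$chain))
  ghosts <- lapply(chains, function(ch) {
    ca <- x[x$name == "CA" & x$chain == ch & x$resseq >= 144 &
              x$resseq <= 183, ]
    own <- principal_axis(coords(ca))
    if (own$direction[3] < 0) own$direction <- -own$direction
    guan <- colMeans(coords(
      x[x$chain == ch & x$resseq == 155 &
          x$name %in% c("NE", "NH1", "NH2"), , drop = FALSE]))
    landing <- as.vector(rotate_about_line(matrix(guan, 1, 3),
                                           own$origin, own$direction,
                                           rotation))
    out_dir <- landing - own$origin
    out_dir[3] <- 0
    out_dir <- out_dir / sqrt(sum(out_dir^2))
    # carboxylate slightly outside and above the landing spot: reachable
    # (~3 A) once the guanidinium has swung onto it, > 4 A from every
    # closed-state guanidinium (including the neighboring chain)
    oe <- landing + 1.5 * out_dir + c(0, 0, 2.6)
    cb <- oe + 2.4 * out_dir + c(0, 0, 1.0)
    ca221 <- cb + 1.53 * out_dir
    tibble(
      name = c("CA", "CB", "OE1", "OE2"),
      element = c("C", "C", "O", "O"),
      resname = "GLU", resseq = 221L, chain = ch,
      x = c(ca221[1], cb[1], oe[1] - 0.3, oe[1] + 0.3),
      y = c(ca221[2], cb[2], oe[2], oe[2]),
      z = c(ca221[3], cb[3], oe[3] - 0.4, oe[3] + 0.4)
    )
  })
  as_structure(dplyr::bind_rows(x, dplyr::bind_rows(ghosts)))
}
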