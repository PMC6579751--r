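#' Per-helix rotation angles between two structures
#'
#' Measures the axial reorientation of a residue's side chain between a
#' reference and an alternate structure. Per chain: a local helix axis is
#' fitted (principal axis of the C-alpha window of `window` residues centered
#' on the target), the alternate window is brought onto the reference by the
#' minimal rotation aligning the two local axes plus a translation (no
#' azimuthal fitting -- the azimuth is the observable), and theta is the
#' signed angle between the CA-to-CB vectors projected onto the plane
#' perpendicular to the axis. Positive theta is counterclockwise viewed from
#' the extracellular (+z) side of the pore axis.
#'
#' Glycine (no CB) yields an `NA` entry for that chain, excluded from means.
#'
#' @param ref,alt atom tibbles with matching chains/residues.
#' @param residues integer vector of residue numbers to measure.
#' @param window odd window width in residues for the local axis fit
#'   (default 7; at least 4 present residues required).
#' @param axis pore axis of `ref` (for the sign convention); default
#'   computed via [compute_pore_axis()].
#' @return tibble with one row per (chain, residue): `chain`, `resseq`,
#'   `theta` (degrees in (-180, 180\]), plus per-residue summary columns
#'   `theta_mean`, `theta_sd` over defined chains.
#' @export
helix_rotation <- function(ref, alt, residues, window = 7,
                           axis = compute_pore_axis(ref)) {
  half <- floor(window / 2)
  chains <- sort(unique(ref$chain[!ref$het]))
  rows <- list()
  for (rs in residues) {
    for (ch in chains) {
      theta <- helix_rotation_one(ref, alt, ch, rs, half, axis)
      rows <- c(rows, list(tibble(chain = ch, resseq = rs, theta = theta)))
    }
  }
  out <- dplyr::bind_rows(rows)
  out |>
    dplyr::group_by(.data$resseq) |>
    dplyr::mutate(theta_mean = mean(.data$theta, na.rm = TRUE),
                  theta_sd = stats::sd(.data$theta, na.rm = TRUE)) |>
    dplyr::ungroup()
}

# Local helix axis from consecutive C-alpha positions by the curvature
# (bisector) construction: chord differences of an ideal helix lie exactly in
# planes perpendicular to the axis, so their cross products give the axis
# direction exactly; real (deformed) helices get a least-squares average.
# Oriented along increasing residue index.
helix_axis_fit <- function(ca) {
  m <- nrow(ca)
  stopifnot(m >= 4)
  A <- diff(ca)                  # chords
  D <- diff(A)                   # curvature vectors, perpendicular to axis
  cr <- vapply(seq_len(nrow(D) - 1), function(i) {
    pracma_cross(D[i, ], D[i + 1, ])
  }, numeric(3))
  cr <- matrix(cr, nrow = 3)
  ref <- cr[, 1]
  for (j in seq_len(ncol(cr))) {
    if (sum(cr[, j] * ref) < 0) cr[, j] <- -cr[, j]
  }
  d <- rowMeans(cr)
  d <- d / sqrt(sum(d^2))
  span <- ca[m, ] - ca[1, ]
  if (sum(d * span) < 0) d <- -d
  list(origin = colMeans(ca), direction = d)
}

helix_rotation_one <- function(ref, alt, ch, rs, half, axis) {
  win <- (rs - half):(rs + half)
  ca_r <- ref[ref$chain == ch & ref$name == "CA" & ref$resseq %in% win, ]
  ca_a <- alt[alt$chain == ch & alt$name == "CA" & alt$resseq %in% win, ]
  common <- intersect(ca_r$resseq, ca_a$resseq)
  if (length(common) < 4) {
    stop("fewer than 4 window residues present for ", ch, rs, call. = FALSE)
  }
  ca_r <- ca_r[match(common, ca_r$resseq), ]
  ca_a <- ca_a[match(common, ca_a$resseq), ]
  cb_r <- ref[ref$chain == ch & ref$resseq == rs & ref$name == "CB", ]
  cb_a <- alt[alt$chain == ch & alt$resseq == rs & alt$name == "CB", ]
  if (nrow(cb_r) == 0 || nrow(cb_a) == 0) return(NA_real_)  # glycine
  cav_r <- ref[ref$chain == ch & ref$resseq == rs & ref$name == "CA", ]
  cav_a <- alt[alt$chain == ch & alt$resseq == rs & alt$name == "CA", ]
  ax_r <- helix_axis_fit(as.matrix(ca_r[, c("x", "y", "z")]))
  ax_a <- helix_axis_fit(as.matrix(ca_a[, c("x", "y", "z")]))
  R <- rotation_between(ax_a$direction, ax_r$direction)
  u <- as.numeric(cb_r[1, c("x", "y", "z")]) -
    as.numeric(cav_r[1, c("x", "y", "z")])
  v0 <- as.numeric(cb_a[1, c("x", "y", "z")]) -
    as.numeric(cav_a[1, c("x", "y", "z")])
  v <- as.vector(R %*% v0)
  # measure about the local axis, signed as seen from the extracellular side
  d <- ax_r$direction
  if (sum(d * axis$direction) < 0) d <- -d
  signed_angle(u, v, d)
}

#' Alternate-chain interchain distances at one residue
#'
#' The hexamer's chains are split into the two interleaved triplets
#' (azimuthal order 1,3,5 and 2,4,6; set 1 contains the alphabetically first
#' chain). Within each triplet the three pairwise atom distances are
#' reported, plus their mean and sd and the overall mean -- the dashed-line
#' dilation metric of the gating motion.
#'
#' @param x atom tibble (residue present on all chains).
#' @param resseq residue number.
#' @param atom atom name (default "CA").
#' @param axis pore axis used for the azimuthal chain ordering.
#' @return tibble with columns `set` ("set1"/"set2"/"overall"), `chains`,
#'   `mean`, `sd`, `n_pairs`.
#' @export
interchain_distance <- function(x, resseq, atom = "CA",
                                axis = compute_pore_axis(x)) {
  at <- x[x$resseq == resseq & x$name == atom & !x$het, ]
  chains <- sort(unique(x$chain[!x$het]))
  missing <- setdiff(chains, at$chain)
  if (length(missing) > 0) {
    stop("residue ", resseq, " (", atom, ") missing on chains: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  az <- azimuthal_chain_order(
    x[x$name == "CA" & !x$het, c("chain", "resseq", "x", "y", "z")], axis)
  set1 <- az[seq(1, length(az), by = 2)]
  set2 <- az[seq(2, length(az), by = 2)]
  pair_d <- function(set) {
    cc <- t(utils::combn(set, 2))
    d <- apply(cc, 1, function(p) {
      a <- as.numeric(at[at$chain == p[1], c("x", "y", "z")][1, ])
      b <- as.numeric(at[at$chain == p[2], c("x", "y", "z")][1, ])
      sqrt(sum((a - b)^2))
    })
    d
  }
  d1 <- pair_d(set1); d2 <- pair_d(set2)
  tibble(
    set = c("set1", "set2", "overall"),
    chains = c(paste(set1, collapse = ""), paste(set2, collapse = ""),
               paste(az, collapse = "")),
    mean = c(mean(d1), mean(d2), mean(c(d1, d2))),
    sd = c(stats::sd(d1), stats::sd(d2), stats::sd(c(d1, d2))),
    n_pairs = c(length(d1), length(d2), length(d1) + length(d2))
  )
}
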