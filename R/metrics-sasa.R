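#' Solvent-accessible surface area (Shrake--Rupley)
#'
#' Rolling-probe SASA with a deterministic golden-spiral point set on each
#' atom sphere (no random numbers, so results are exactly reproducible). Per
#' atom, the accessible fraction of `n_points` surface points not buried in
#' any neighbor sphere is converted to area; per-residue sums are reported.
#'
#' @param x atom tibble (heavy atoms).
#' @param probe probe radius, Angstrom (default 1.4, water).
#' @param n_points surface points per atom (default 960; fewer than 32 is
#'   refused as too inaccurate).
#' @return tibble with per-residue rows: `chain`, `resseq`, `resname`,
#'   `sasa` (A^2), `sasa_side` (side-chain atoms only, i.e. excluding
#'   N/CA/C/O backbone names).
#' @export
sasa_residues <- function(x, probe = 1.4, n_points = 960) {
  if (n_points < 32) stop("n_points < 32 is below the accuracy floor",
                          call. = FALSE)
  at <- sasa_atoms(x, probe, n_points)
  bb <- c("N", "CA", "C", "O")
  at |>
    dplyr::group_by(.data$chain, .data$resseq, .data$resname) |>
    dplyr::summarise(
      sasa = sum(.data$area),
      sasa_side = sum(.data$area[!(.data$name %in% bb)]),
      .groups = "drop"
    )
}

# Per-atom SASA; returns x with an `area` column.
sasa_atoms <- function(x, probe = 1.4, n_points = 960) {
  xyz <- coords(x)
  rad <- atom_radii(x) + probe
  n <- nrow(xyz)
  pts <- golden_spiral_points(n_points)
  d2 <- outer(rowSums(xyz^2), rowSums(xyz^2), "+") - 2 * xyz %*% t(xyz)
  area <- numeric(n)
  for (i in seq_len(n)) {
    nb <- which(d2[i, ] < (rad[i] + rad)^2 & seq_len(n) != i)
    sp <- sweep(pts * rad[i], 2, xyz[i, ], "+")
    if (length(nb) == 0) {
      acc <- n_points
    } else {
      buried <- rep(FALSE, n_points)
      for (j in nb) {
        dj <- (sp[, 1] - xyz[j, 1])^2 + (sp[, 2] - xyz[j, 2])^2 +
          (sp[, 3] - xyz[j, 3])^2
        buried <- buried | dj < rad[j]^2
        if (all(buried)) break
      }
      acc <- sum(!buried)
    }
    area[i] <- 4 * pi * rad[i]^2 * acc / n_points
  }
  out <- x
  out$area <- area
  out
}

#' Relative solvent-exposure change between two structures
#'
#' (alt - ref)/ref per residue, the metric used to describe how gate
#' residues bury or expose their side chains during gating. Residues whose
#' reference SASA is below 1 A^2 have no meaningful relative change and are
#' flagged (`defined = FALSE`).
#'
#' @param ref,alt atom tibbles.
#' @param residues residue numbers to report (default: all shared).
#' @param mode `"side_chain"` (default) or `"residue"` -- which atom set the
#'   relative change is computed over.
#' @inheritParams sasa_residues
#' @return tibble `chain`, `resseq`, `resname`, `sasa_ref`, `sasa_alt`,
#'   `rel_change`, `defined`.
#' @export
delta_exposure <- function(ref, alt, residues = NULL,
                           mode = c("side_chain", "residue"),
                           probe = 1.4, n_points = 960) {
  mode <- match.arg(mode)
  col <- if (mode == "side_chain") "sasa_side" else "sasa"
  sr <- sasa_residues(ref, probe, n_points)
  sa <- sasa_residues(alt, probe, n_points)
  if (!is.null(residues)) {
    sr <- sr[sr$resseq %in% residues, ]
    sa <- sa[sa$resseq %in% residues, ]
  }
  out <- dplyr::inner_join(
    sr |> dplyr::select("chain", "resseq", "resname",
                        sasa_ref = dplyr::all_of(col)),
    sa |> dplyr::select("chain", "resseq", sasa_alt = dplyr::all_of(col)),
    by = c("chain", "resseq")
  )
  out$defined <- out$sasa_ref > 1
  out$rel_change <- ifelse(out$defined,
                           (out$sasa_alt - out$sasa_ref) / out$sasa_ref,
                           NA_real_)
  out
}
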