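# Bondi-type heavy-atom radii (Angstrom); hydrogens are never present in the
# structures this package handles, so heavy atoms carry slightly inflated
# united radii for C/N.
VDW_RADII <- c(C = 1.88, N = 1.64, O = 1.46, S = 1.77, P = 1.80,
               H = 1.20, DEFAULT = 1.70)

atom_radii <- function(x) {
  r <- VDW_RADII[x$element]
  r[is.na(r)] <- VDW_RADII[["DEFAULT"]]
  unname(r)
}

#' Pore axis of a channel structure
#'
#' The axis is the principal inertia axis of the pore-lining C-alpha
#' selection, through their centroid. Orientation (+z = extracellular) is
#' fixed by the ring rule: the acidic selectivity-filter ring must lie at
#' higher z than the basic ring. If either tag is absent the orientation is
#' an explicit error -- it is never guessed.
#'
#' @param x atom tibble.
#' @param lining_resseq residue numbers of the pore-lining helix used for
#'   the inertia fit (default: every protein residue).
#' @param filter_resseq,basic_resseq residue numbers of the filter (acidic)
#'   and basic rings used to orient +z; defaults 178 and 163.
#' @return list with `origin`, `direction` (unit, +z extracellular).
#' @export
compute_pore_axis <- function(x, lining_resseq = NULL,
                              filter_resseq = 178, basic_resseq = 163) {
  ca <- x[x$name == "CA" & !x$het, ]
  if (!is.null(lining_resseq)) ca <- ca[ca$resseq %in% lining_resseq, ]
  if (length(unique(ca$chain)) < 2) {
    stop("pore axis needs a lining selection spanning >= 2 chains",
         call. = FALSE)
  }
  ax <- principal_axis(coords(ca))
  fil <- ca[ca$resseq %in% filter_resseq, ]
  bas <- ca[ca$resseq %in% basic_resseq, ]
  if (nrow(fil) == 0 || nrow(bas) == 0) {
    stop("cannot orient pore axis: filter (", paste(filter_resseq,
         collapse = ","), ") or basic (", paste(basic_resseq, collapse = ","),
         ") ring residues absent from the lining selection", call. = FALSE)
  }
  proj <- function(m) mean(as.matrix(m[, c("x", "y", "z")]) %*% ax$direction)
  if (proj(fil) < proj(bas)) ax$direction <- -ax$direction
  ax
}

# Coordinates expressed in the axis frame: z along the axis, origin at
# ax$origin.
axis_frame <- function(ax) {
  d <- ax$direction
  e1 <- c(1, 0, 0) - d[1] * d
  if (sqrt(sum(e1^2)) < 1e-6) e1 <- c(0, 1, 0) - d[2] * d
  e1 <- e1 / sqrt(sum(e1^2))
  e2 <- pracma_cross(d, e1)
  rbind(e1, e2, d)
}

#' Pore radius profile
#'
#' HOLE-style geometric profile: at each position z along the pore axis the
#' radius is the largest sphere that fits among the van der Waals spheres of
#' all atoms, with the sphere center optimized in the plane perpendicular to
#' the axis (derivative-free search started on the axis). Radii above
#' `cap` Angstrom mean the pore is locally unbounded and are capped and
#' flagged.
#'
#' @param x atom tibble.
#' @param axis from [compute_pore_axis()].
#' @param z_range length-2 numeric (along-axis coordinates, Angstrom);
#'   default spans the lining atoms.
#' @param step grid step in z (default 0.5).
#' @param optimize_center logical; FALSE evaluates the radius on the axis
#'   itself (useful for exactly symmetric fixtures).
#' @param cap radius cap, Angstrom.
#' @return tibble with columns `z`, `radius`, `cx`, `cy` (in-plane center,
#'   axis frame), `capped`; class `pore_profile`, with the axis attached as
#'   attribute `"axis"`.
#' @export
pore_radius_profile <- function(x, axis = compute_pore_axis(x),
                                z_range = NULL, step = 0.5,
                                optimize_center = TRUE, cap = 15) {
  M <- axis_frame(axis)
  xyz <- sweep(coords(x), 2, axis$origin) %*% t(M)
  rad <- atom_radii(x)
  if (is.null(z_range)) {
    z_range <- stats::quantile(xyz[, 3], c(0.02, 0.98))
  }
  zs <- seq(z_range[1], z_range[2], by = step)
  # pore radius at in-plane point (cx, cy) for slab near z: distance to the
  # nearest atom surface, using full 3D distances (atoms above/below count)
  prof <- purrr::map(zs, function(z) {
    near <- which(abs(xyz[, 3] - z) < cap + 4)
    a <- xyz[near, , drop = FALSE]
    r <- rad[near]
    f <- function(c2) {
      d <- sqrt((a[, 1] - c2[1])^2 + (a[, 2] - c2[2])^2 + (a[, 3] - z)^2) - r
      -min(d)
    }
    ctr <- c(0, 0)
    if (optimize_center && length(near) > 0) {
      opt <- stats::optim(ctr, f, method = "Nelder-Mead",
                          control = list(reltol = 1e-10, maxit = 400))
      ctr <- opt$par
    }
    rr <- if (length(near) == 0) cap else -f(ctr)
    tibble(z = z, radius = min(rr, cap), cx = ctr[1], cy = ctr[2],
           capped = rr >= cap)
  })
  out <- dplyr::bind_rows(prof)
  class(out) <- c("pore_profile", class(out))
  attr(out, "axis") <- axis
  out
}

#' @rdname pore_radius_profile
#' @param object a `pore_profile`.
#' @param ... unused.
#' @method autoplot pore_profile
#' @export
autoplot.pore_profile <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$z, y = .data$radius)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "position along pore axis (Å, +z extracellular)",
                  y = "pore radius (Å)") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
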