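# Physical constants (CODATA).
.FARADAY <- 96485.33212      # C/mol
.RGAS <- 8.314462618         # J/mol/K
.ECHARGE <- 1.602176634e-19  # C
.EPS0 <- 8.8541878128e-12    # F/m

#' Define ionic species for the transport model
#'
#' @param name species label.
#' @param valence integer charge number (non-zero).
#' @param D bulk diffusivity, cm^2/s.
#' @param c_left,c_right bath concentrations, mM; left is the intracellular
#'   (-z) side, right the extracellular (+z) side.
#' @param f_D dimensionless pore diffusivity scaling (default 0.1); affects
#'   current magnitudes, not reversal potentials.
#' @return one-row tibble; rows from several calls bind into a species table.
#' @export
species <- function(name, valence, D, c_left, c_right, f_D = 0.1) {
  stopifnot(valence != 0, D > 0, c_left >= 0, c_right >= 0, f_D > 0)
  tibble(name = name, valence = as.integer(valence), D = D,
         c_left = c_left, c_right = c_right, f_D = f_D)
}

#' Bath condition presets
#'
#' `"nacl_symmetric"`: plain 150 mM NaCl on both sides (the neutral
#' default; uniform in-pore diffusivity scaling 0.1).
#'
#' `"paper_guess"`: a whole-cell-like recording condition -- 150 mM NaCl +
#' 20 mM CaCl2 extracellular against 150 mM NaCl with ~100 nM free Ca2+
#' intracellular. The recording solutions behind the published
#' reversal-potential value are not stated in the available text, so this
#' preset is an assumption-laden stand-in, named accordingly. Mean-field
#' PNP with point ions cannot produce the channel family's hallmark
#' divalent-over-monovalent selectivity (experimentally P_Ca/P_Na > 1000)
#' from electrostatics alone, so the preset encodes it in the in-pore
#' diffusivity scalings: f_D = 0.1 for Ca2+ against 0.001 for Na+/Cl-
#' (a 100-fold transport preference which, combined with the
#' electrostatic Ca2+ enrichment at the acidic filter, yields an effective
#' permeability ratio of the experimental order).
#'
#' @param name preset name.
#' @return species table.
#' @export
bath_preset <- function(name = c("nacl_symmetric", "paper_guess")) {
  name <- match.arg(name)
  switch(name,
    nacl_symmetric = dplyr::bind_rows(
      species("Na", +1, 1.334e-5, 150, 150),
      species("Cl", -1, 2.032e-5, 150, 150)
    ),
    paper_guess = dplyr::bind_rows(
      species("Na", +1, 1.334e-5, 150, 150, f_D = 0.001),
      species("Ca", +2, 0.792e-5, 1e-4, 20, f_D = 0.1),
      species("Cl", -1, 2.032e-5, 150.0002, 190, f_D = 0.001)
    )
  )
}

#' Assemble a 1D PNP system
#'
#' @param z grid positions along the pore axis, Angstrom, strictly
#'   increasing, uniform step.
#' @param radius pore radius at each node, Angstrom (> 0); the area profile
#'   is `pi * radius^2`.
#' @param rho_f fixed-charge line density at each node, elementary charges
#'   per Angstrom (Gaussian-smeared ring charges integrate to their total).
#' @param species_table from [species()] / [bath_preset()].
#' @param eps relative permittivity (scalar or per-node; default 78).
#' @param temperature Kelvin.
#' @return object of class `pnp_system`.
#' @export
pnp_system <- function(z, radius, rho_f = NULL, species_table,
                       eps = 78, temperature = 298.15) {
  n <- length(z)
  stopifnot(n >= 5, all(diff(z) > 0), length(radius) == n, all(radius > 0))
  h <- diff(z)
  if (max(abs(h - h[1])) > 1e-9 * h[1]) {
    stop("grid must be uniform", call. = FALSE)
  }
  if (is.null(rho_f)) rho_f <- numeric(n)
  stopifnot(length(rho_f) == n)
  if (length(eps) == 1) eps <- rep(eps, n)
  structure(list(z = z, radius = radius, area = pi * radius^2,
                 rho_f = rho_f, eps = eps, temperature = temperature,
                 species = species_table),
            class = "pnp_system")
}

#' @export
print.pnp_system <- function(x, ...) {
  cat("<pnp_system> ", length(x$z), " nodes over ",
      round(diff(range(x$z)), 1), " A; radius ",
      round(min(x$radius), 2), "-", round(max(x$radius), 2),
      " A; total fixed charge ",
      round(sum(x$rho_f) * (x$z[2] - x$z[1]), 3), " e; ",
      nrow(x$species), " species\n", sep = "")
  invisible(x)
}

#' Specification for a synthetic PNP test system
#'
#' @param length pore length, Angstrom.
#' @param radius_profile list: `list(type = "uniform", r = ...)` or
#'   `list(type = "constriction", z0 = , width = , r_min = , r_out = )`
#'   (Gaussian-shaped constriction centered at `z0`).
#' @param ring_charges data frame with columns `z` (Angstrom, relative to
#'   the pore center at 0), `charge` (total e), `sigma` (smearing width, >0);
#'   NULL for a neutral pore.
#' @param species_table species table (default symmetric NaCl).
#' @param step grid step, Angstrom.
#' @return object of class `pnp_fixture_spec`.
#' @export
pnp_fixture_spec <- function(length = 40,
                             radius_profile = list(type = "uniform", r = 4),
                             ring_charges = NULL,
                             species_table = bath_preset("nacl_symmetric"),
                             step = 0.5) {
  if (!is.null(ring_charges)) stopifnot(all(ring_charges$sigma > 0))
  stopifnot(all(species_table$D > 0))
  structure(list(length = length, radius_profile = radius_profile,
                 ring_charges = ring_charges,
                 species_table = species_table, step = step),
            class = "pnp_fixture_spec")
}

#' Build a PNP system from a fixture spec
#'
#' @param spec a [pnp_fixture_spec()].
#' @return `pnp_system`.
#' @export
make_pnp_fixture <- function(spec) {
  stopifnot(inherits(spec, "pnp_fixture_spec"))
  z <- seq(-spec$length / 2, spec$length / 2, by = spec$step)
  rp <- spec$radius_profile
  radius <- switch(rp$type,
    uniform = rep(rp$r, length(z)),
    constriction = rp$r_out - (rp$r_out - rp$r_min) *
      exp(-(z - rp$z0)^2 / (2 * rp$width^2)),
    stop("unknown radius_profile type: ", rp$type)
  )
  stopifnot(all(radius > 0))
  rho <- numeric(length(z))
  if (!is.null(spec$ring_charges)) {
    rho <- smear_ring_charges(z, spec$ring_charges)
  }
  pnp_system(z, radius, rho, spec$species_table)
}

# Gaussian smearing of ring charges onto a grid; discrete normalization so
# that sum(rho) * dz equals each ring's total charge exactly.
smear_ring_charges <- function(z, rings) {
  dz <- z[2] - z[1]
  rho <- numeric(length(z))
  for (i in seq_len(nrow(rings))) {
    g <- exp(-(z - rings$z[i])^2 / (2 * rings$sigma[i]^2))
    s <- sum(g) * dz
    if (s <= 0) stop("ring charge falls outside the grid", call. = FALSE)
    rho <- rho + rings$charge[i] * g / s
  }
  rho
}

# Formal side-chain charges and their carrier atom groups.
CHARGE_GROUPS <- list(
  GLU = list(atoms = c("OE1", "OE2"), q = -1),
  ASP = list(atoms = c("OD1", "OD2"), q = -1),
  LYS = list(atoms = "NZ", q = +1),
  ARG = list(atoms = c("NE", "NH1", "NH2"), q = +1)
)

#' Map structural fixed charge onto a pore-axis grid
#'
#' Formal charges (Glu/Asp -1, Arg/Lys +1, His configurable, termini
#' ignored) located at side-chain charged-group centroids within
#' `radial_cutoff` of the pore axis are smeared as normalized Gaussians in z
#' onto the profile's grid. The discrete integral of the returned line
#' density equals the summed mapped charge.
#'
#' @param x atom tibble.
#' @param profile a [pore_radius_profile()] (supplies the axis and z grid).
#' @param radial_cutoff Angstrom; charges further from the axis are outside
#'   the pore's electrostatic core and excluded.
#' @param sigma Gaussian smear width in z, Angstrom.
#' @param his_charge formal charge assigned to histidine (default 0).
#' @param radial_weight `"uniform"` counts every charge inside the cutoff
#'   in full; `"gaussian"` attenuates a charge by `exp(-(r/lambda)^2)` with
#'   its radial distance r from the axis. The attenuation expresses the 1D
#'   reduction: a charged group far from the axis faces the pore lumen only
#'   partially and is otherwise screened inside the protein/headgroup
#'   region, so collapsing it fully onto the axis overstates its effect on
#'   the area-averaged potential.
#' @param lambda radial attenuation length for `"gaussian"`, Angstrom.
#' @param paired_basic if TRUE, basic (Arg/Lys) charges enter as net zero:
#'   they are treated as permanently paired with mobile counter-anions (the
#'   crystallographic anion site in the basic region and the anion-assisted
#'   conduction mode reported for this channel family).
#' @return numeric line density (e/Angstrom) on `profile$z`, with the mapped
#'   charges attached as attribute `"charges"` (tibble; `weight` column
#'   holds the applied attenuation).
#' @export
map_fixed_charge <- function(x, profile, radial_cutoff = 12, sigma = 2,
                             his_charge = 0,
                             radial_weight = c("uniform", "gaussian"),
                             lambda = 6, paired_basic = FALSE) {
  radial_weight <- match.arg(radial_weight)
  axis <- attr(profile, "axis")
  stopifnot(!is.null(axis))
  M <- axis_frame(axis)
  groups <- CHARGE_GROUPS
  if (his_charge != 0) {
    groups$HIS <- list(atoms = c("ND1", "NE2"), q = his_charge)
  }
  rows <- list()
  res <- x[!x$het & x$resname %in% names(groups), ] |>
    dplyr::distinct(.data$chain, .data$resseq, .data$resname)
  for (i in seq_len(nrow(res))) {
    g <- groups[[res$resname[i]]]
    at <- x[x$chain == res$chain[i] & x$resseq == res$resseq[i] &
              x$name %in% g$atoms, ]
    if (nrow(at) == 0) next
    ctr <- colMeans(coords(at))
    loc <- as.vector(M %*% (ctr - axis$origin))
    r <- sqrt(loc[1]^2 + loc[2]^2)
    if (r > radial_cutoff) next
    rows <- c(rows, list(tibble(chain = res$chain[i],
                                resseq = res$resseq[i],
                                resname = res$resname[i],
                                z = loc[3], radial = r, charge = g$q)))
  }
  zg <- profile$z
  if (length(rows) == 0) {
    warning("no charged residues within ", radial_cutoff,
            " A of the pore axis; returning a neutral profile")
    rho <- numeric(length(zg))
    attr(rho, "charges") <- tibble(chain = character(), resseq = integer(),
                                   resname = character(), z = numeric(),
                                   radial = numeric(), charge = numeric())
    return(rho)
  }
  ch <- dplyr::bind_rows(rows)
  ch$weight <- if (radial_weight == "gaussian") {
    exp(-(ch$radial / lambda)^2)
  } else {
    rep(1, nrow(ch))
  }
  if (paired_basic) ch$weight[ch$charge > 0] <- 0
  rho <- smear_ring_charges(zg, tibble(z = ch$z,
                                       charge = ch$charge * ch$weight,
                                       sigma = sigma))
  attr(rho, "charges") <- ch
  rho
}

#' Build a PNP system from a channel structure
#'
#' Convenience wrapper: pore radius profile -> area, structural fixed charge
#' -> smeared line density, plus a bath preset.
#'
#' @param x atom tibble (open-state model).
#' @param species_table species table (default `bath_preset("paper_guess")`).
#' @param step grid step, Angstrom.
#' @param z_range along-axis range; default the profile's.
#' @param min_radius floor on the radius (Angstrom) to keep the area
#'   positive through tightly packed sections.
#' @param radial_weight charge attenuation mode, see [map_fixed_charge()]
#'   (default `"gaussian"`: the structure-derived wall charges enter the 1D
#'   model attenuated by radial distance from the axis).
#' @param paired_basic see [map_fixed_charge()]; default TRUE for channel
#'   models (anion-paired basic region).
#' @param ... passed to [map_fixed_charge()].
#' @return `pnp_system`.
#' @export
pnp_from_structure <- function(x, species_table = bath_preset("paper_guess"),
                               step = 0.5, z_range = NULL, min_radius = 1,
                               radial_weight = "gaussian",
                               paired_basic = TRUE, ...) {
  axis <- compute_pore_axis(x)
  prof <- pore_radius_profile(x, axis, z_range = z_range, step = step)
  rho <- map_fixed_charge(x, prof, radial_weight = radial_weight,
                          paired_basic = paired_basic, ...)
  pnp_system(prof$z, pmax(prof$radius, min_radius), as.numeric(rho),
             species_table)
}
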