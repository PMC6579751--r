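#' Cn symmetry order parameter of a structure
#'
#' RMS deviation (Angstrom) between the selected coordinates and their image
#' under the cyclic symmetry operation: rotation by 360/order about the pore
#' axis combined with the induced chain permutation. The axis placement
#' (direction + in-plane origin) is refined numerically to minimize the RMS,
#' so the measure reports genuine asymmetry, not axis misplacement. Zero for
#' a perfect Cn structure.
#'
#' The hexameric channel family's signature is a 6-fold pore inside a 3-fold
#' overall architecture: order 3 on the whole structure is ~0 while order 6
#' is not.
#'
#' @param x atom tibble.
#' @param order symmetry order (chain count must be divisible by it).
#' @param resseq optional residue selection.
#' @param atom atom name used for the comparison (default "CA").
#' @param refine_axis logical; FALSE uses the principal axis as-is.
#' @return RMS deviation in Angstrom.
#' @export
symmetry_order_parameter <- function(x, order, resseq = NULL, atom = "CA",
                                     refine_axis = TRUE) {
  sel <- x[x$name == atom & !x$het, ]
  if (!is.null(resseq)) sel <- sel[sel$resseq %in% resseq, ]
  chains <- sort(unique(sel$chain))
  nc <- length(chains)
  if (nc %% order != 0) {
    stop("chain count ", nc, " not divisible by order ", order,
         call. = FALSE)
  }
  ax0 <- symmetry_axis(coords(sel))
  az <- azimuthal_chain_order(sel[, c("chain", "resseq", "x", "y", "z")],
                              ax0)
  step <- nc / order
  key <- paste(sel$chain, sel$resseq)
  perm <- integer(nrow(sel))
  for (i in seq_len(nrow(sel))) {
    ci <- match(sel$chain[i], az)
    cj <- az[((ci - 1 + step) %% nc) + 1]
    perm[i] <- match(paste(cj, sel$resseq[i]), key)
  }
  if (any(is.na(perm))) {
    stop("chains are not residue-wise equivalent under the Cn map",
         call. = FALSE)
  }
  xyz <- coords(sel)
  M <- axis_frame(ax0)
  rms_for <- function(par) {
    # par: in-plane origin shift (2) + axis tilt (2, small-angle)
    d <- ax0$direction + par[3] * M[1, ] + par[4] * M[2, ]
    d <- d / sqrt(sum(d^2))
    o <- ax0$origin + par[1] * M[1, ] + par[2] * M[2, ]
    img <- rotate_about_line(xyz, o, d, 360 / order)
    sqrt(mean(rowSums((img - xyz[perm, , drop = FALSE])^2)))
  }
  r0 <- rms_for(c(0, 0, 0, 0))
  if (!refine_axis || r0 < 1e-9) return(r0)
  opt <- stats::optim(c(0, 0, 0, 0), rms_for, method = "Nelder-Mead",
                      control = list(reltol = 1e-10, maxit = 500))
  min(r0, opt$value)
}

# Group-average coordinates over the Cn symmetry operation (exact projection
# onto the symmetric subspace). Used to keep a deformation path that is
# symmetric by assumption from drifting numerically.
symmetrize_sites <- function(sites, order, axis) {
  xyz <- as.matrix(sites[, c("x", "y", "z")])
  chains <- sort(unique(sites$chain))
  nc <- length(chains)
  if (order <= 1 || nc %% order != 0) return(sites)
  az <- azimuthal_chain_order(sites, axis)
  step <- nc / order
  key <- paste(sites$chain, sites$resseq)
  perm <- integer(nrow(sites))
  for (i in seq_len(nrow(sites))) {
    ci <- match(sites$chain[i], az)
    cj <- az[((ci - 1 + step) %% nc) + 1]
    perm[i] <- match(paste(cj, sites$resseq[i]), key)
  }
  if (any(is.na(perm))) return(sites)
  acc <- xyz
  idx <- seq_len(nrow(sites))
  cur_perm <- perm
  for (g in seq_len(order - 1)) {
    img <- rotate_about_line(xyz[cur_perm, , drop = FALSE], axis$origin,
                             axis$direction, -360 * g / order)
    acc <- acc + img
    cur_perm <- perm[cur_perm]
  }
  sites$x <- acc[, 1] / order
  sites$y <- acc[, 2] / order
  sites$z <- acc[, 3] / order
  sites
}
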