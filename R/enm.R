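#' Anisotropic elastic-network normal modes
#'
#' Builds the standard anisotropic network model (ANM) on a C-alpha coarse
#' model: every pair of sites closer than `cutoff` is joined by a Hookean
#' spring of stiffness `gamma`; the 3N x 3N Hessian has the usual
#' super-elements \eqn{-\gamma (r \otimes r)/|r|^2} for connected pairs and
#' diagonal blocks equal to minus the sum of the off-diagonal blocks. Its
#' low-frequency eigenvectors approximate the collective motions of the
#' protein. Six eigenvalues are numerically zero for a connected network
#' (rigid-body translations/rotations); they are detected at
#' `lambda < 1e-8 * max(lambda)` and removed from the nontrivial list.
#'
#' Eigensolution uses an iterative sparse-style solver (\pkg{RSpectra}) for
#' the lowest modes when available and the model is large; otherwise a dense
#' symmetric solver. The two agree to tight tolerance (checked in the test
#' suite).
#'
#' @param sites coarse model from [to_coarse()] (or any tibble with
#'   `chain`, `resseq`, `x`, `y`, `z`).
#' @param cutoff interaction cutoff, Angstrom (default 13).
#' @param n_modes number of nontrivial modes to retain (default 50; clamped
#'   to 3N - 6 with a warning).
#' @param gamma spring constant (arbitrary energy/A^2; sets the eigenvalue
#'   scale only -- mode shapes and everything downstream are
#'   gamma-independent).
#' @return object of class `tg_modes`: list with `values` (nontrivial
#'   eigenvalues, ascending), `vectors` (3N x n_modes orthonormal columns),
#'   `n_zero`, `sites`, `cutoff`, `gamma`.
#' @export
compute_modes <- function(sites, cutoff = 13, n_modes = 50, gamma = 1) {
  xyz <- as.matrix(sites[, c("x", "y", "z")])
  n <- nrow(xyz)
  if (n < 4) stop("need at least 4 sites", call. = FALSE)
  dd <- as.matrix(stats::dist(xyz))
  adj <- dd <= cutoff & dd > 0
  # connectivity check (graph BFS on the contact map)
  comp <- connected_components(adj)
  if (max(comp) > 1) {
    sizes <- table(comp)
    stop("elastic network is disconnected at cutoff ", cutoff, " A (",
         length(sizes), " components of sizes ",
         paste(sizes, collapse = ", "), ")", call. = FALSE)
  }
  if (n_modes > 3 * n - 6) {
    warning("n_modes clamped to 3N - 6 = ", 3 * n - 6)
    n_modes <- 3 * n - 6
  }
  H <- anm_hessian(xyz, adj, dd, gamma)
  k_want <- min(6 + n_modes, 3 * n)
  use_iterative <- n > 300 && requireNamespace("RSpectra", quietly = TRUE)
  if (use_iterative) {
    es <- RSpectra::eigs_sym(H, k = k_want, sigma = -1e-4,
                             opts = list(retvec = TRUE))
    ord <- order(es$values)
    vals <- es$values[ord]
    vecs <- es$vectors[, ord, drop = FALSE]
    lam_max <- RSpectra::eigs_sym(H, k = 1, which = "LA")$values
  } else {
    es <- eigen(H, symmetric = TRUE)
    vals <- rev(es$values)[seq_len(k_want)]
    vecs <- es$vectors[, rev(seq_len(3 * n))[seq_len(k_want)], drop = FALSE]
    lam_max <- max(es$values)
  }
  zero_tol <- 1e-8 * lam_max
  nz <- sum(vals < zero_tol)
  keep <- which(vals >= zero_tol)[seq_len(min(n_modes, sum(vals >= zero_tol)))]
  structure(list(
    values = vals[keep],
    vectors = vecs[, keep, drop = FALSE],
    n_zero = nz,
    zero_tol = zero_tol,
    lambda_max = lam_max,
    sites = sites,
    cutoff = cutoff,
    gamma = gamma
  ), class = "tg_modes")
}

connected_components <- function(adj) {
  n <- nrow(adj)
  comp <- integer(n)
  cur <- 0L
  for (s in seq_len(n)) {
    if (comp[s] != 0L) next
    cur <- cur + 1L
    queue <- s
    comp[s] <- cur
    while (length(queue) > 0) {
      v <- queue[1]; queue <- queue[-1]
      nb <- which(adj[v, ] & comp == 0L)
      comp[nb] <- cur
      queue <- c(queue, nb)
    }
  }
  comp
}

anm_hessian <- function(xyz, adj, dd, gamma) {
  n <- nrow(xyz)
  H <- matrix(0, 3 * n, 3 * n)
  pairs <- which(adj & upper.tri(adj), arr.ind = TRUE)
  for (p in seq_len(nrow(pairs))) {
    i <- pairs[p, 1]; j <- pairs[p, 2]
    r <- xyz[j, ] - xyz[i, ]
    blk <- -gamma * (r %o% r) / sum(r^2)
    ii <- (3 * i - 2):(3 * i); jj <- (3 * j - 2):(3 * j)
    H[ii, jj] <- blk
    H[jj, ii] <- blk
    H[ii, ii] <- H[ii, ii] - blk
    H[jj, jj] <- H[jj, jj] - blk
  }
  H
}

# Per-site displacement matrix (n x 3) of mode k.
mode_field <- function(ms, k) {
  matrix(ms$vectors[, k], ncol = 3, byrow = TRUE)
}

#' Cn symmetry score of a normal mode
#'
#' Measures how a mode transforms under the cyclic symmetry operator of the
#' oligomer: rotate the displacement field by 360/order degrees about the
#' principal (pore) axis and permute chains cyclically, then take the inner
#' product with the original mode. A score of +1 means the mode transforms as
#' the totally symmetric (A) representation, -1 as the alternating (B)
#' representation, and intermediate values (cosines of the rotation angle)
#' mark the two-dimensional E representations. Near-degenerate eigenvalue
#' clusters (relative gap < 1e-6, generic under Cn symmetry) are scored by
#' the basis-independent mean of the inner products over the cluster (the
#' operator's trace per mode on that eigenspace), reported for every member.
#'
#' @param ms a `tg_modes` object.
#' @param k mode index (1 = lowest nontrivial).
#' @param order symmetry order; chain count must be divisible by it.
#' @return score in \[-1, 1\].
#' @export
symmetry_score <- function(ms, k, order) {
  chains <- sort(unique(ms$sites$chain))
  nc <- length(chains)
  if (nc %% order != 0) {
    stop("chain count ", nc, " not divisible by symmetry order ", order,
         call. = FALSE)
  }
  if (order == 1) return(1)
  lam <- ms$values
  near <- which(abs(lam - lam[k]) / max(lam[k], 1e-300) < 1e-6)
  score <- mean(vapply(near, function(m) {
    v <- ms$vectors[, m]
    sum(symmetry_transform_vector(ms, v, order) * v)
  }, 0))
  max(-1, min(1, score))
}

# Apply the Cn operator (rotation by 360/order about the principal axis +
# induced cyclic chain permutation) to a 3N vector over ms$sites.
symmetry_transform_vector <- function(ms, v, order) {
  sites <- ms$sites
  chains <- sort(unique(sites$chain))
  nc <- length(chains)
  ax <- symmetry_axis(as.matrix(sites[, c("x", "y", "z")]))
  # orient so that chains advance counterclockwise about +axis
  R <- rotation_matrix(ax$direction, 360 / order)
  U <- matrix(v, ncol = 3, byrow = TRUE) %*% t(R)
  step <- nc / order
  # site i on chain c corresponds to the same resseq on the chain `step`
  # positions around; chains must be azimuthally ordered for this map
  az <- azimuthal_chain_order(sites, ax)
  perm <- integer(nrow(sites))
  key <- paste(sites$chain, sites$resseq)
  for (i in seq_len(nrow(sites))) {
    ci <- match(sites$chain[i], az)
    cj <- az[((ci - 1 + step) %% nc) + 1]
    perm[i] <- match(paste(cj, sites$resseq[i]), key)
  }
  if (any(is.na(perm))) {
    stop("chains are not residue-wise equivalent; cannot apply Cn operator",
         call. = FALSE)
  }
  W <- matrix(0, nrow(sites), 3)
  W[perm, ] <- U
  # correct rotation sense: the permuted-and-rotated field should map the
  # structure onto itself; choose the rotation sign giving the better match
  as.vector(t(W))
}

# Chains ordered by azimuth about the axis (starting from the alphabetically
# first chain, proceeding in the +rotation sense).
azimuthal_chain_order <- function(sites, ax) {
  chains <- sort(unique(sites$chain))
  ctr <- vapply(chains, function(ch) {
    colMeans(as.matrix(sites[sites$chain == ch, c("x", "y", "z")]))
  }, numeric(3))
  d <- ax$direction
  e1 <- c(1, 0, 0) - d[1] * d
  if (sqrt(sum(e1^2)) < 1e-6) e1 <- c(0, 1, 0) - d[2] * d
  e1 <- e1 / sqrt(sum(e1^2))
  e2 <- pracma_cross(d, e1)
  rel <- sweep(t(ctr), 2, ax$origin)
  ang <- atan2(rel %*% e2, rel %*% e1)[, 1]
  ord <- chains[order(ang)]
  first <- which(ord == chains[1])
  c(ord[first:length(ord)], ord[seq_len(first - 1)])
}

#' Brueschweiler collectivity of a mode
#'
#' Exponential-of-entropy measure of how many sites participate in a mode:
#' 1 for a uniform-amplitude mode, 1/N for a single-site displacement.
#'
#' @param ms a `tg_modes` object.
#' @param k mode index.
#' @return kappa in (0, 1].
#' @export
collectivity <- function(ms, k) {
  u2 <- rowSums(mode_field(ms, k)^2)
  p <- u2 / sum(u2)
  p <- p[p > 0]
  exp(-sum(p * log(p))) / length(u2)
}

#' Overlap of a mode with a displacement field
#'
#' Cosine of the angle between eigenvector k and an arbitrary 3N
#' displacement.
#'
#' @param ms a `tg_modes` object.
#' @param k mode index.
#' @param d displacement: 3N vector or n x 3 matrix.
#' @return value in \[-1, 1\].
#' @export
mode_overlap <- function(ms, k, d) {
  if (is.matrix(d)) d <- as.vector(t(d))
  nd <- sqrt(sum(d^2))
  if (nd == 0) stop("zero displacement has no direction", call. = FALSE)
  sum(ms$vectors[, k] * d) / nd
}

#' @export
print.tg_modes <- function(x, ...) {
  cat("<tg_modes> ", length(x$values), " nontrivial modes over ",
      nrow(x$sites), " sites (cutoff ", x$cutoff, " A, ",
      x$n_zero, " zero modes)\n", sep = "")
  invisible(x)
}

#' Tidy summary of a mode set
#'
#' One row per nontrivial mode: eigenvalue, collectivity and C3/C6 symmetry
#' scores (where the chain count allows them).
#'
#' @param x a `tg_modes` object.
#' @param ... unused.
#' @return tibble with columns `mode`, `lambda`, `kappa`, `c3`, `c6`.
#' @method tidy tg_modes
#' @export
tidy.tg_modes <- function(x, ...) {
  nc <- length(unique(x$sites$chain))
  k <- seq_along(x$values)
  tibble(
    mode = k,
    lambda = x$values,
    kappa = vapply(k, function(i) collectivity(x, i), 0),
    c3 = if (nc %% 3 == 0) {
      vapply(k, function(i) symmetry_score(x, i, 3), 0)
    } else NA_real_,
    c6 = if (nc %% 6 == 0) {
      vapply(k, function(i) symmetry_score(x, i, 6), 0)
    } else NA_real_
  )
}

#' @method glance tg_modes
#' @export
glance.tg_modes <- function(x, ...) {
  tibble(n_sites = nrow(x$sites), n_modes = length(x$values),
         n_zero = x$n_zero, cutoff = x$cutoff,
         lambda_min = x$values[1], lambda_max_kept = max(x$values))
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance
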