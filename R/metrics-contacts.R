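BASIC_ATOMS <- list(ARG = c("NH1", "NH2", "NE"), LYS = "NZ")
ACIDIC_ATOMS <- list(GLU = c("OE1", "OE2"), ASP = c("OD1", "OD2"))

#' Salt-bridge detection
#'
#' A bridge is recorded when the minimum distance between a basic side-chain
#' nitrogen (Arg NH1/NH2/NE, Lys NZ) and an acidic side-chain oxygen (Glu
#' OE1/OE2, Asp OD1/OD2) is at most `cutoff` (default 4 Angstrom, the common
#' N--O criterion).
#'
#' @param x atom tibble.
#' @param cutoff N--O distance cutoff, Angstrom.
#' @param pairs optional restriction: data frame with columns
#'   `resseq_basic`, `resseq_acidic` (and optionally `chain_basic`,
#'   `chain_acidic`); only those residue pairs are tested.
#' @return tibble with one row per detected bridge: basic and acidic residue
#'   identity, `dist` (minimum N--O), `intra_chain`.
#' @export
salt_bridges <- function(x, cutoff = 4.0, pairs = NULL) {
  bas <- x[x$resname %in% names(BASIC_ATOMS) &
             mapply(function(n, r) n %in% BASIC_ATOMS[[r]], x$name,
                    x$resname), ]
  aci <- x[x$resname %in% names(ACIDIC_ATOMS) &
             mapply(function(n, r) n %in% ACIDIC_ATOMS[[r]], x$name,
                    x$resname), ]
  empty <- tibble(chain_basic = character(), resseq_basic = integer(),
                  resname_basic = character(), chain_acidic = character(),
                  resseq_acidic = integer(), resname_acidic = character(),
                  dist = numeric(), intra_chain = logical())
  if (nrow(bas) == 0 || nrow(aci) == 0) return(empty)
  bxyz <- coords(bas); axyz <- coords(aci)
  dd <- sqrt(outer(rowSums(bxyz^2), rowSums(axyz^2), "+") -
               2 * bxyz %*% t(axyz))
  bkey <- paste(bas$chain, bas$resseq)
  akey <- paste(aci$chain, aci$resseq)
  out <- tibble(
    i = rep(seq_len(nrow(bas)), times = nrow(aci)),
    j = rep(seq_len(nrow(aci)), each = nrow(bas)),
    dist = as.vector(dd)
  ) |>
    dplyr::mutate(bk = bkey[.data$i], ak = akey[.data$j]) |>
    dplyr::group_by(.data$bk, .data$ak) |>
    dplyr::summarise(i = .data$i[which.min(.data$dist)],
                     j = .data$j[which.min(.data$dist)],
                     dist = min(.data$dist), .groups = "drop") |>
    dplyr::filter(.data$dist <= cutoff)
  if (nrow(out) == 0) return(empty)
  res <- tibble(
    chain_basic = bas$chain[out$i], resseq_basic = bas$resseq[out$i],
    resname_basic = bas$resname[out$i],
    chain_acidic = aci$chain[out$j], resseq_acidic = aci$resseq[out$j],
    resname_acidic = aci$resname[out$j],
    dist = out$dist,
    intra_chain = bas$chain[out$i] == aci$chain[out$j]
  )
  if (!is.null(pairs)) {
    keep <- rep(FALSE, nrow(res))
    for (p in seq_len(nrow(pairs))) {
      m <- res$resseq_basic == pairs$resseq_basic[p] &
        res$resseq_acidic == pairs$resseq_acidic[p]
      if (!is.null(pairs$chain_basic)) {
        m <- m & res$chain_basic == pairs$chain_basic[p] &
          res$chain_acidic == pairs$chain_acidic[p]
      }
      keep <- keep | m
    }
    res <- res[keep, ]
  }
  dplyr::arrange(res, .data$chain_basic, .data$resseq_basic)
}

#' Contact persistence between two structures
#'
#' For each residue pair, reports whether the minimum heavy-atom distance is
#' within `cutoff` in the reference and in the alternate structure. Used for
#' coiled-coil unpairing, hydrophobic packing, and hydrogen-bond level
#' contacts.
#'
#' @param ref,alt atom tibbles.
#' @param pairs data frame with columns `chain1`, `resseq1`, `chain2`,
#'   `resseq2`.
#' @param cutoff heavy-atom minimum distance cutoff, Angstrom (default 4.5).
#' @return `pairs` with added columns `dist_ref`, `dist_alt`,
#'   `present_ref`, `present_alt`.
#' @export
contact_persistence <- function(ref, alt, pairs, cutoff = 4.5) {
  min_dist <- function(x, ch1, r1, ch2, r2) {
    a <- x[x$chain == ch1 & x$resseq == r1 & x$element != "H", ]
    b <- x[x$chain == ch2 & x$resseq == r2 & x$element != "H", ]
    if (nrow(a) == 0 || nrow(b) == 0) {
      stop("pair unresolvable: ", ch1, r1, " / ", ch2, r2, call. = FALSE)
    }
    A <- coords(a); B <- coords(b)
    sqrt(min(outer(rowSums(A^2), rowSums(B^2), "+") - 2 * A %*% t(B)))
  }
  pairs <- as_tibble(pairs)
  pairs$dist_ref <- purrr::pmap_dbl(
    pairs[, c("chain1", "resseq1", "chain2", "resseq2")],
    function(chain1, resseq1, chain2, resseq2) {
      min_dist(ref, chain1, resseq1, chain2, resseq2)
    })
  pairs$dist_alt <- purrr::pmap_dbl(
    pairs[, c("chain1", "resseq1", "chain2", "resseq2")],
    function(chain1, resseq1, chain2, resseq2) {
      min_dist(alt, chain1, resseq1, chain2, resseq2)
    })
  pairs$present_ref <- pairs$dist_ref <= cutoff
  pairs$present_alt <- pairs$dist_alt <= cutoff
  pairs
}
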