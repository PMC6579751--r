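#' @importFrom rlang .data
#' @import tibble
NULL

AA3 <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS",
         "ILE", "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP",
         "TYR", "VAL")

STRUCTURE_COLS <- c("serial", "name", "element", "resname", "resseq",
                    "chain", "x", "y", "z", "occupancy", "bfactor", "het")

#' Assemble an atom table
#'
#' The package's universal structure container is a plain tibble with one row
#' per atom and columns `serial`, `name`, `element`, `resname`, `resseq`,
#' `chain`, `x`, `y`, `z` (Angstrom), `occupancy`, `bfactor` and `het`
#' (logical, TRUE for waters/ligands). Author (PDB) residue numbering is used
#' throughout; there is no renumbering layer.
#'
#' @param df data frame carrying at least `name`, `resname`, `resseq`,
#'   `chain`, `x`, `y`, `z`; missing bookkeeping columns are filled with
#'   defaults.
#' @return atom tibble.
#' @export
as_structure <- function(df) {
  df <- as_tibble(df)
  n <- nrow(df)
  if (!all(c("name", "resname", "resseq", "chain", "x", "y", "z") %in%
           names(df))) {
    stop("atom table needs name/resname/resseq/chain/x/y/z columns",
         call. = FALSE)
  }
  if (!"serial" %in% names(df)) df$serial <- seq_len(n)
  if (!"element" %in% names(df)) df$element <- substr(trimws(df$name), 1, 1)
  if (!"occupancy" %in% names(df)) df$occupancy <- 1
  if (!"bfactor" %in% names(df)) df$bfactor <- 0
  if (!"het" %in% names(df)) df$het <- !(df$resname %in% AA3)
  df$resseq <- as.integer(df$resseq)
  stopifnot(all(is.finite(df$x)), all(is.finite(df$y)), all(is.finite(df$z)))
  df[, STRUCTURE_COLS]
}

coords <- function(x) as.matrix(x[, c("x", "y", "z")])

set_coords <- function(x, xyz) {
  x$x <- xyz[, 1]; x$y <- xyz[, 2]; x$z <- xyz[, 3]
  x
}

#' Read a structure from PDB or mmCIF
#'
#' Parsing is delegated to \pkg{bio3d}; the result is normalized into the
#' package's atom tibble. Alternate locations are resolved by keeping the
#' highest-occupancy record (ties: first occurrence). Waters and other
#' heteroatoms are retained and flagged via `het`.
#'
#' @param path file path.
#' @param format `"pdb"`, `"cif"` or `"auto"` (by extension, default).
#' @return atom tibble (see [as_structure()]).
#' @export
read_structure <- function(path, format = c("auto", "pdb", "cif")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (format == "auto") {
    format <- if (grepl("\\.cif$", path, ignore.case = TRUE)) "cif" else "pdb"
  }
  pdb <- tryCatch(
    if (format == "pdb") {
      suppressWarnings(bio3d::read.pdb(path, verbose = FALSE))
    } else {
      suppressWarnings(bio3d::read.cif(path, verbose = FALSE))
    },
    error = function(e) {
      stop("failed to parse ", path, " as ", format, ": ",
           conditionMessage(e), call. = FALSE)
    }
  )
  at <- pdb$atom
  if (is.null(at) || nrow(at) == 0) {
    stop("no atoms parsed from ", path, " (", format, ")", call. = FALSE)
  }
  if (!is.null(at$insert) && any(!is.na(at$insert) & at$insert != "")) {
    stop("insertion codes are not supported", call. = FALSE)
  }
  x <- tibble(
    serial = as.integer(at$eleno),
    name = trimws(at$elety),
    element = if (!is.null(at$elesy)) trimws(at$elesy) else
      substr(trimws(at$elety), 1, 1),
    resname = trimws(at$resid),
    resseq = as.integer(at$resno),
    chain = as.character(at$chain),
    x = at$x, y = at$y, z = at$z,
    occupancy = ifelse(is.na(at$o), 1, at$o),
    bfactor = ifelse(is.na(at$b), 0, at$b),
    het = at$type == "HETATM",
    alt = if (!is.null(at$alt)) ifelse(is.na(at$alt), "", at$alt) else ""
  )
  # altloc resolution: highest occupancy, ties by first occurrence
  x <- x |>
    dplyr::mutate(.row = dplyr::row_number()) |>
    dplyr::group_by(.data$chain, .data$resseq, .data$name) |>
    dplyr::arrange(dplyr::desc(.data$occupancy), .data$.row, .by_group = TRUE) |>
    dplyr::slice(1) |>
    dplyr::ungroup() |>
    dplyr::arrange(.data$.row) |>
    dplyr::select(-".row", -"alt")
  as_structure(x)
}

#' Write a structure to PDB or mmCIF
#'
#' PDB output uses fixed-width v3.3 records (3-decimal coordinates) through
#' \pkg{bio3d}; coordinates outside the 8.3 field are an explicit error, never
#' silently truncated. mmCIF output writes a minimal `atom_site` loop at full
#' precision.
#'
#' @param x atom tibble.
#' @param path output path.
#' @param format `"pdb"` or `"cif"`.
#' @export
write_structure <- function(x, path, format = c("pdb", "cif")) {
  format <- match.arg(format)
  x <- as_structure(x)
  if (format == "pdb") {
    xyz <- coords(x)
    if (any(xyz >= 10000 - 1e-9 | xyz <= -1000 + 1e-9)) {
      stop("coordinates exceed the fixed-width PDB coordinate field; ",
           "use format = \"cif\"", call. = FALSE)
    }
    bio3d::write.pdb(
      pdb = NULL, file = path,
      xyz = as.vector(t(xyz)),
      type = ifelse(x$het, "HETATM", "ATOM"),
      resno = x$resseq, resid = x$resname, eleno = x$serial,
      elety = x$name, chain = x$chain, o = x$occupancy, b = x$bfactor,
      elesy = x$element
    )
  } else {
    hdr <- c(
      "data_twistgate",
      "#",
      "loop_",
      "_atom_site.group_PDB",
      "_atom_site.id",
      "_atom_site.type_symbol",
      "_atom_site.label_atom_id",
      "_atom_site.label_alt_id",
      "_atom_site.label_comp_id",
      "_atom_site.label_asym_id",
      "_atom_site.label_entity_id",
      "_atom_site.label_seq_id",
      "_atom_site.pdbx_PDB_ins_code",
      "_atom_site.Cartn_x",
      "_atom_site.Cartn_y",
      "_atom_site.Cartn_z",
      "_atom_site.occupancy",
      "_atom_site.B_iso_or_equiv",
      "_atom_site.auth_seq_id",
      "_atom_site.auth_comp_id",
      "_atom_site.auth_asym_id",
      "_atom_site.auth_atom_id",
      "_atom_site.pdbx_PDB_model_num"
    )
    rows <- sprintf(
      "%s %d %s %s . %s %s 1 %d ? %.6f %.6f %.6f %.3f %.3f %d %s %s %s 1",
      ifelse(x$het, "HETATM", "ATOM"), x$serial, x$element, x$name,
      x$resname, x$chain, x$resseq, x$x, x$y, x$z, x$occupancy, x$bfactor,
      x$resseq, x$resname, x$chain, x$name
    )
    writeLines(c(hdr, rows, "#"), path)
  }
  invisible(path)
}

#' Subset a structure by chains, residues and atom names
#'
#' All given criteria are combined with AND; `NULL` criteria select
#' everything. Requesting residues absent from the structure is an error that
#' lists the absentees -- unresolved loops (such as loop2 in the closed-state
#' crystal of the reference channel) must surface explicitly, never silently.
#'
#' @param x atom tibble.
#' @param chains character vector of chain ids, or NULL.
#' @param residues integer vector of residue numbers (any chain) or a data
#'   frame with columns `chain` and `resseq`, or NULL.
#' @param atom_names character vector of atom names, or NULL.
#' @return atom tibble containing the matching atoms (original order).
#' @export
select_atoms <- function(x, chains = NULL, residues = NULL,
                         atom_names = NULL) {
  keep <- rep(TRUE, nrow(x))
  if (!is.null(chains)) keep <- keep & x$chain %in% chains
  if (!is.null(residues)) {
    if (is.data.frame(residues)) {
      want <- paste(residues$chain, residues$resseq)
      have <- unique(paste(x$chain, x$resseq))
      missing <- setdiff(want, have)
      if (length(missing) > 0) {
        stop("residues absent from structure: ",
             paste(missing, collapse = ", "), call. = FALSE)
      }
      keep <- keep & paste(x$chain, x$resseq) %in% want
    } else {
      residues <- as.integer(residues)
      missing <- setdiff(residues, unique(x$resseq))
      if (length(missing) > 0) {
        stop("residues absent from structure: ",
             paste(missing, collapse = ", "), call. = FALSE)
      }
      keep <- keep & x$resseq %in% residues
    }
  }
  if (!is.null(atom_names)) keep <- keep & x$name %in% atom_names
  x[keep, ]
}

#' Coarse-grain a structure to one site per residue
#'
#' Extracts the site atom (default C-alpha) of every protein residue, ordered
#' by chain then ascending residue number. The Cn metrics and the elastic
#' network all operate on this representation.
#'
#' @param x atom tibble.
#' @param site_atom atom name to keep per residue.
#' @param skip_missing if FALSE (default), a protein residue lacking the site
#'   atom is an error naming the residue; if TRUE it is dropped.
#' @return tibble with columns `chain`, `resseq`, `resname`, `x`, `y`, `z`.
#' @export
to_coarse <- function(x, site_atom = "CA", skip_missing = FALSE) {
  prot <- x[!x$het & x$resname %in% AA3, ]
  res <- prot |>
    dplyr::distinct(.data$chain, .data$resseq, .data$resname) |>
    dplyr::arrange(.data$chain, .data$resseq)
  sites <- prot[prot$name == site_atom,
                c("chain", "resseq", "resname", "x", "y", "z")]
  out <- dplyr::left_join(res, sites,
                          by = c("chain", "resseq", "resname"))
  miss <- is.na(out$x)
  if (any(miss)) {
    if (!skip_missing) {
      stop("residues lacking site atom ", site_atom, ": ",
           paste(paste0(out$chain[miss], out$resseq[miss]), collapse = ", "),
           call. = FALSE)
    }
    out <- out[!miss, ]
  }
  as_tibble(out)
}

# Promote a coarse site table back to a minimal atom tibble (CA records).
coarse_as_structure <- function(sites) {
  as_structure(tibble(
    name = "CA", resname = sites$resname, resseq = sites$resseq,
    chain = sites$chain, x = sites$x, y = sites$y, z = sites$z,
    element = "C"
  ))
}
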