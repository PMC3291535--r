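# Structure input and tabular artifact I/O.

.STD_RESIDUES <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY",
                   "HIS", "ILE", "LEU", "LYS", "MET", "PHE", "PRO", "SER",
                   "THR", "TRP", "TYR", "VAL")

.VDW_RADII <- c(C = 1.70, N = 1.55, O = 1.52, S = 1.80, H = 1.20, P = 1.80)

# Theoretical maximum accessible surface areas per residue type (Tien et
# al.-style reference values, Angstrom^2), used to express SASA as a
# relative accessibility.
.MAX_SASA <- c(ALA = 129, ARG = 274, ASN = 195, ASP = 193, CYS = 167,
               GLN = 225, GLU = 223, GLY = 104, HIS = 224, ILE = 197,
               LEU = 201, LYS = 236, MET = 224, PHE = 240, PRO = 159,
               SER = 155, THR = 172, TRP = 285, TYR = 263, VAL = 174)

#' Read a prepared all-atom structure from a PDB file
#'
#' Reads the coordinate records of the first MODEL.  HETATM records
#' (including crystallographic waters) are dropped; for alternate locations
#' the highest-occupancy conformer is kept (ties resolved in favour of
#' altloc `A`); insertion codes are rejected.  Residues are renumbered
#' 1-based in order of appearance per chain (the author numbering is kept
#' in `resno_author`).  Hydrogens must be present on every standard
#' residue — hydrogen-bond detection needs explicit donors.
#'
#' @param path Path to a PDB file.
#' @return Atom tibble: `atom_id`, `serial`, `name`, `element`,
#'   `residue_index`, `residue_name`, `chain`, `x`, `y`, `z`, `bfactor`,
#'   `occupancy`, `resno_author`.
#' @export
read_structure <- function(path) {
  stopifnot(file.exists(path))
  pdb <- suppressWarnings(bio3d::read.pdb(path, multi = FALSE,
                                          rm.alt = FALSE, verbose = FALSE))
  at <- pdb$atom
  at <- at[at$type == "ATOM", , drop = FALSE]
  if (nrow(at) == 0) stop("no ATOM records in ", path)
  at$chain[is.na(at$chain)] <- "A"
  if (any(!is.na(at$insert) & at$insert != "")) {
    bad <- unique(at$resno[!is.na(at$insert) & at$insert != ""])
    stop("insertion codes are not supported (residue(s) ",
         paste(bad, collapse = ", "), ")")
  }
  # altloc: keep the highest occupancy per (chain, resno, name); ties -> 'A'
  alt <- ifelse(is.na(at$alt), "", at$alt)
  key <- paste(at$chain, at$resno, at$elety)
  ord <- order(key, -at$o, alt)
  at <- at[ord, , drop = FALSE]
  at <- at[!duplicated(paste(at$chain, at$resno, at$elety)), , drop = FALSE]
  at <- at[order(at$eleno), , drop = FALSE]

  elem <- at$elesy
  miss <- is.na(elem) | elem == ""
  elem[miss] <- substr(gsub("[0-9]", "", at$elety[miss]), 1, 1)
  elem <- toupper(elem)

  # renumber residues 1-based per chain, in order of appearance
  ridx <- integer(nrow(at))
  for (ch in unique(at$chain)) {
    sel <- at$chain == ch
    ridx[sel] <- match(at$resno[sel], unique(at$resno[sel]))
  }

  atoms <- tibble::tibble(
    atom_id = seq_len(nrow(at)), serial = at$eleno, name = at$elety,
    element = elem, residue_index = ridx, residue_name = at$resid,
    chain = at$chain, x = at$x, y = at$y, z = at$z,
    bfactor = at$b, occupancy = at$o, resno_author = at$resno)

  std <- atoms$residue_name %in% .STD_RESIDUES
  has_h <- tapply(atoms$element[std] == "H",
                  atoms$residue_index[std], any)
  if (length(has_h) > 0 && any(!has_h)) {
    bad <- names(has_h)[!has_h]
    stop("missing hydrogens on standard residue(s) ",
         paste(bad, collapse = ", "),
         "; hydrogen-bond detection requires explicit hydrogens")
  }
  stopifnot(all(is.finite(atoms$x)), all(is.finite(atoms$y)),
            all(is.finite(atoms$z)))
  atoms
}

#' Write an atom tibble as a PDB file
#'
#' Counterpart of [read_structure()] for fixtures and round trips.
#'
#' @param atoms Atom tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_structure <- function(atoms, path) {
  nm <- ifelse(nchar(atoms$name) < 4, paste0(" ", atoms$name), atoms$name)
  lines <- sprintf(
    "ATOM  %5d %-4s %3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
    atoms$serial %||% seq_len(nrow(atoms)), nm, atoms$residue_name,
    atoms$chain %||% "A", atoms$residue_index,
    atoms$x, atoms$y, atoms$z,
    atoms$occupancy %||% 1, atoms$bfactor %||% 0, atoms$element)
  writeLines(c(lines, "END"), path)
  invisible(path)
}

# Fibonacci sphere points (deterministic, well-spread)
sphere_points <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

#' Relative solvent accessibility per residue (Shrake-Rupley)
#'
#' Numeric accessible surface area with a rolling probe over a deterministic
#' sphere-point lattice, summed per residue and divided by a fixed
#' per-residue-type reference maximum; values are clipped to `[0, 1]`.
#'
#' @param atoms Atom tibble.
#' @param probe Probe radius, Angstrom.
#' @param n_points Sphere points per atom (increase to refine).
#' @return Tibble: `residue_index`, `residue_name`, `sasa`, `rel_sasa`.
#' @export
compute_relative_sasa <- function(atoms, probe = 1.4, n_points = 960) {
  atoms <- tibble::as_tibble(atoms)
  stopifnot(nrow(atoms) > 0)
  unknown <- setdiff(unique(atoms$residue_name), names(.MAX_SASA))
  unknown <- setdiff(unknown, NA)
  if (length(unknown) > 0) {
    stop("unknown residue type(s) for relative SASA: ",
         paste(unknown, collapse = ", "))
  }
  xyz <- as.matrix(atoms[, c("x", "y", "z")])
  rad <- .VDW_RADII[toupper(atoms$element)]
  rad[is.na(rad)] <- 1.70
  rr <- rad + probe
  pts <- sphere_points(n_points)
  n <- nrow(atoms)
  area <- numeric(n)
  for (i in seq_len(n)) {
    p <- pts * rr[i]
    p <- sweep(p, 2, xyz[i, ], `+`)
    d2 <- rowSums(sweep(xyz, 2, xyz[i, ], `-`)^2)
    nbr <- which(d2 < (rr + rr[i])^2 & seq_len(n) != i)
    free <- rep(TRUE, n_points)
    for (j in nbr) {
      if (!any(free)) break
      dj <- (p[, 1] - xyz[j, 1])^2 + (p[, 2] - xyz[j, 2])^2 +
        (p[, 3] - xyz[j, 3])^2
      free <- free & dj > rr[j]^2
    }
    area[i] <- 4 * pi * rr[i]^2 * mean(free)
  }
  per_res <- rowsum(area, atoms$residue_index)
  ridx <- as.integer(rownames(per_res))
  rname <- atoms$residue_name[match(ridx, atoms$residue_index)]
  tibble::tibble(
    residue_index = ridx, residue_name = rname,
    sasa = as.vector(per_res),
    rel_sasa = pmin(1, pmax(0, as.vector(per_res) / .MAX_SASA[rname])))
}

#' Split per-residue values into accessibility tertiles
#'
#' Ranks are split into three contiguous groups (buried = lowest third,
#' exposed = highest) whose sizes differ by at most one; the lowest group
#' takes any remainder first.  Ties are broken by residue index, so the
#' classification is deterministic.
#'
#' @param values Per-residue numeric values (e.g. `rel_sasa`).
#' @return Factor with levels `buried`, `moderate`, `exposed`.
#' @export
tertile_classes <- function(values) {
  n <- length(values)
  stopifnot(n >= 3)
  ord <- order(values, seq_len(n))
  s1 <- ceiling(n / 3)
  s3 <- floor(n / 3)
  s2 <- n - s1 - s3
  cls <- character(n)
  cls[ord] <- rep(c("buried", "moderate", "exposed"), times = c(s1, s2, s3))
  factor(cls, levels = c("buried", "moderate", "exposed"))
}

# --- tabular artifacts ------------------------------------------------------

#' Read a per-residue annotation table
#'
#' Tab-separated columns: `residue_index`, optional `rel_sasa`, `ss_class`
#' (helix/strand/coil), `subdomain` (alpha/beta).
#'
#' @param path TSV path.
#' @export
read_annotations <- function(path) {
  tab <- readr::read_tsv(path, show_col_types = FALSE)
  need <- c("residue_index", "ss_class", "subdomain")
  miss <- setdiff(need, names(tab))
  if (length(miss) > 0) {
    stop("annotation file lacks column(s): ", paste(miss, collapse = ", "))
  }
  if (anyDuplicated(tab$residue_index)) {
    stop("each residue must be annotated exactly once")
  }
  stopifnot(all(tab$ss_class %in% c("helix", "strand", "coil")),
            all(tab$subdomain %in% c("alpha", "beta")))
  tab
}

#' @rdname read_annotations
#' @param annotations Annotation tibble.
#' @export
write_annotations <- function(annotations, path) {
  readr::write_tsv(annotations, path)
  invisible(path)
}

#' Read/write a flexibility-index profile
#'
#' TSV with columns `residue_index` (or `bond_id`) and `FI`.
#'
#' @param path TSV path.
#' @export
read_fi_tsv <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE)
}

#' @rdname read_fi_tsv
#' @param fi Profile tibble.
#' @export
write_fi_tsv <- function(fi, path) {
  readr::write_tsv(fi, path)
  invisible(path)
}

#' Read/write a square cooperativity-correlation matrix
#'
#' TSV with a leading index column; row and column order are the residue
#' (or bond) indices.
#'
#' @param path TSV path.
#' @export
read_cc_tsv <- function(path) {
  tab <- readr::read_tsv(path, show_col_types = FALSE)
  m <- as.matrix(tab[, -1])
  rownames(m) <- tab[[1]]
  storage.mode(m) <- "double"
  m
}

#' @rdname read_cc_tsv
#' @param cc Square matrix.
#' @export
write_cc_tsv <- function(cc, path) {
  tab <- tibble::as_tibble(cc, .name_repair = "minimal")
  names(tab) <- colnames(cc) %||% as.character(seq_len(ncol(cc)))
  tab <- dplyr::bind_cols(
    tibble::tibble(index = rownames(cc) %||%
                     as.character(seq_len(nrow(cc)))), tab)
  readr::write_tsv(tab, path)
  invisible(path)
}

#' Read a heat-capacity curve
#'
#' TSV with columns `T_K` and `Cp_kcal_per_mol_K` (or any two first
#' columns in that order).
#'
#' @param path TSV path.
#' @export
read_cp_tsv <- function(path) {
  tab <- readr::read_tsv(path, show_col_types = FALSE)
  stopifnot(ncol(tab) >= 2)
  tab
}

#' Read/write a per-residue B-factor table
#'
#' TSV with columns `residue_index` and `bfactor` (alpha-carbon values).
#'
#' @param path TSV path.
#' @export
read_bfactors_tsv <- function(path) {
  tab <- readr::read_tsv(path, show_col_types = FALSE)
  stopifnot(all(c("residue_index", "bfactor") %in% names(tab)))
  tab
}

#' @rdname read_bfactors_tsv
#' @param bfactors Tibble with `residue_index` and `bfactor`.
#' @export
write_bfactors_tsv <- function(bfactors, path) {
  readr::write_tsv(bfactors, path)
  invisible(path)
}

#' Write a hydrogen-bond list as TSV
#'
#' @param hbonds Output of [detect_hbonds()].
#' @param path TSV path.
#' @export
write_hbonds_tsv <- function(hbonds, path) {
  readr::write_tsv(hbonds, path)
  invisible(path)
}

#' Write run metadata as JSON
#'
#' @param meta Named list (parameters, seeds, grid specification, ...).
#' @param path Output path.
#' @export
write_run_metadata <- function(meta, path) {
  jsonlite::write_json(meta, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(path)
}

#' Heuristic secondary-structure assignment from backbone hydrogen bonds
#'
#' Clearly labelled heuristic (annotation files are the primary source):
#' residues whose backbone N-H donates to a backbone O three-to-five
#' residues away are called helix; residues donating to a backbone O at
#' least six residues away (or on another strand) are called strand;
#' everything else is coil.
#'
#' @param atoms Atom tibble.
#' @param hbonds Optional [detect_hbonds()] output.
#' @return Tibble `residue_index`, `ss_class`.
#' @export
guess_ss_classes <- function(atoms, hbonds = NULL) {
  if (is.null(hbonds)) hbonds <- detect_hbonds(atoms)
  n_res <- max(atoms$residue_index)
  ss <- rep("coil", n_res)
  if (nrow(hbonds) > 0) {
    bb <- hbonds[atoms$name[hbonds$donor] == "N" &
                   atoms$name[hbonds$acceptor] == "O", , drop = FALSE]
    if (nrow(bb) > 0) {
      di <- atoms$residue_index[bb$donor]
      ai <- atoms$residue_index[bb$acceptor]
      sep <- abs(di - ai)
      for (r in seq_len(nrow(bb))) {
        lab <- if (sep[r] >= 3 && sep[r] <= 5) "helix" else
          if (sep[r] >= 6) "strand" else NA
        if (!is.na(lab)) ss[c(di[r], ai[r])] <- lab
      }
    }
  }
  tibble::tibble(residue_index = seq_len(n_res), ss_class = ss)
}

# --- shipped example tables -------------------------------------------------

#' Published lysozyme mutant response-count and dataset tables
#'
#' Small plain-text tables shipped with the package: per-stratum residue
#' response counts for a published set of 14 human lysozyme point mutants
#' (five response bins by distance/accessibility/secondary structure
#' strata), and the structural/thermodynamic characterization of the 7
#' wild-type and 14 mutant structures (PDB id, resolution, melting
#' temperature, Cp maximum, H-bond count, fitted `u_sol`, `v_nat`).  Used
#' by the worked examples and the arithmetic consistency checks.
#'
#' @return A tibble.
#' @export
lysozyme_response_counts <- function() {
  readr::read_tsv(system.file("extdata", "lysozyme_response_counts.tsv",
                              package = "mdcm"),
                  show_col_types = FALSE)
}

#' @rdname lysozyme_response_counts
#' @export
lysozyme_dataset <- function() {
  readr::read_tsv(system.file("extdata", "lysozyme_dataset.tsv",
                              package = "mdcm"),
                  show_col_types = FALSE)
}
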