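# Fixed-column parsing of PDB / PDBQT atom records into typed heavy-atom
# tables, plus the atom typing (hydrophobic / H-bond donor / acceptor /
# van der Waals radius) that the Vina terms require.

# canonical column layout of a typed-atom table
.atom_cols <- c("element", "x", "y", "z", "pdbqt_type",
                "is_hydrophobic", "is_hbond_donor", "is_hbond_acceptor",
                "vdw_radius", "role")

# AutoDock atom type -> element (types not listed fall through to a
# title-cased copy of themselves, covering metal types like ZN, MG)
.pdbqt_type_element <- c(
  C = "C", A = "C", N = "N", NA. = "N", NS = "N",
  O = "O", OA = "O", OS = "O", S = "S", SA = "S",
  P = "P", F = "F", CL = "Cl", BR = "Br", I = "I",
  H = "H", HD = "H", HS = "H"
)

.type_to_element <- function(type) {
  key <- toupper(type)
  key[key == "NA"] <- "NA."   # guard against R's NA name lookup
  out <- .pdbqt_type_element[key]
  miss <- is.na(out)
  out[miss] <- paste0(substr(key[miss], 1, 1),
                      tolower(substr(key[miss], 2, 2)))
  unname(out)
}

.element_radius <- function(element, config) {
  r <- config$radii[element]
  r[is.na(r)] <- config$default_radius
  unname(r)
}

#' Typed-atom tables
#'
#' Constructs the canonical heavy-atom table used throughout the package:
#' one row per atom with element symbol, Cartesian coordinates (Angstrom),
#' optional AutoDock atom type, interaction-class flags and van der Waals
#' radius. Hydrogens never appear in these tables.
#'
#' @param element character vector of element symbols.
#' @param x,y,z numeric coordinates in Angstrom.
#' @param role `"protein"` or `"ligand"`.
#' @param pdbqt_type AutoDock atom-type strings, or `NA`.
#' @param is_hydrophobic,is_hbond_donor,is_hbond_acceptor logical flags.
#' @param vdw_radius van der Waals radii in Angstrom; defaults to the
#'   per-element table in [vf_config()].
#' @param config configuration list from [vf_config()].
#' @return a `data.frame` with one row per heavy atom.
#' @export
typed_atoms <- function(element, x, y, z, role,
                        pdbqt_type = NA_character_,
                        is_hydrophobic = element == "C",
                        is_hbond_donor = FALSE,
                        is_hbond_acceptor = element %in% c("N", "O"),
                        vdw_radius = NULL,
                        config = vf_config()) {
  n <- length(element)
  stopifnot(length(x) == n, length(y) == n, length(z) == n)
  if (any(!is.finite(x)) || any(!is.finite(y)) || any(!is.finite(z)))
    stop("atom coordinates must be finite", call. = FALSE)
  if (is.null(vdw_radius)) vdw_radius <- .element_radius(element, config)
  if (any(vdw_radius <= 0)) stop("vdw_radius must be positive", call. = FALSE)
  df <- data.frame(
    element = as.character(element), x = x, y = y, z = z,
    pdbqt_type = rep_len(as.character(pdbqt_type), n),
    is_hydrophobic = rep_len(is_hydrophobic, n),
    is_hbond_donor = rep_len(is_hbond_donor, n),
    is_hbond_acceptor = rep_len(is_hbond_acceptor, n),
    vdw_radius = vdw_radius,
    role = rep_len(role, n),
    stringsAsFactors = FALSE
  )
  if (any(df$is_hydrophobic & df$element != "C"))
    stop("is_hydrophobic is only defined for carbon atoms", call. = FALSE)
  df
}

#' Protein-ligand complex container
#'
#' Bundles a protein atom table, a ligand atom table and the ligand
#' rotatable-bond count; this is the unit of featurization.
#'
#' @param id identifier (e.g. a PDB code).
#' @param protein,ligand typed-atom tables (see [typed_atoms()]).
#' @param n_rotatable_bonds non-negative integer, the ligand's active
#'   rotatable bonds (Nrot).
#' @return an object of class `molecular_complex`.
#' @export
molecular_complex <- function(id, protein, ligand, n_rotatable_bonds = 0L) {
  stopifnot(is.data.frame(protein), is.data.frame(ligand))
  if (nrow(protein) == 0L || nrow(ligand) == 0L)
    stop("a scoreable complex needs non-empty protein and ligand atom lists",
         call. = FALSE)
  if (n_rotatable_bonds < 0) stop("n_rotatable_bonds must be >= 0", call. = FALSE)
  protein$role <- "protein"
  ligand$role <- "ligand"
  structure(
    list(id = as.character(id), protein = protein, ligand = ligand,
         n_rotatable_bonds = as.integer(n_rotatable_bonds)),
    class = "molecular_complex"
  )
}

#' @export
print.molecular_complex <- function(x, ...) {
  cat(sprintf("<molecular_complex %s: %d protein atoms, %d ligand atoms, Nrot = %d>\n",
              x$id, nrow(x$protein), nrow(x$ligand), x$n_rotatable_bonds))
  invisible(x)
}

.as_lines <- function(text) {
  if (length(text) == 1L && grepl("\n", text, fixed = TRUE))
    text <- strsplit(text, "\n", fixed = TRUE)[[1]]
  text
}

.parse_coords <- function(lines, lineno, source) {
  xs <- substr(lines, 31, 38); ys <- substr(lines, 39, 46); zs <- substr(lines, 47, 54)
  x <- suppressWarnings(as.numeric(xs))
  y <- suppressWarnings(as.numeric(ys))
  z <- suppressWarnings(as.numeric(zs))
  bad <- which(!is.finite(x) | !is.finite(y) | !is.finite(z))
  if (length(bad)) {
    stop(sprintf("%s: malformed coordinate field at line %d: '%s'",
                 source, lineno[bad[1]], trimws(lines[bad[1]])), call. = FALSE)
  }
  cbind(x = x, y = y, z = z)
}

# Flags derived without connectivity: a carbon is hydrophobic unless a
# polar heavy atom (N/O/S) of the same molecule sits within bonding range;
# an N/O is a donor if a polar hydrogen sits within bonding range.
.derive_flags <- function(df, h_coords, config) {
  n <- nrow(df)
  hydrophobic <- rep(FALSE, n)
  donor <- rep(FALSE, n)
  carbon <- df$element == "C"
  polar <- df$element %in% c("N", "O", "S")
  if (any(carbon)) {
    if (any(polar)) {
      pc <- as.matrix(df[polar, c("x", "y", "z")])
      cc <- as.matrix(df[carbon, c("x", "y", "z")])
      d2 <- .cross_dist2(cc, pc)
      hydrophobic[carbon] <- apply(d2, 1, min) > config$hydrophobic_fallback_dist^2
    } else hydrophobic[carbon] <- TRUE
  }
  no <- df$element %in% c("N", "O")
  if (any(no) && !is.null(h_coords) && nrow(h_coords) > 0L) {
    d2 <- .cross_dist2(as.matrix(df[no, c("x", "y", "z")]), h_coords)
    donor[no] <- apply(d2, 1, min) <= config$polar_h_dist^2
  }
  acceptor <- if (all(is.na(df$pdbqt_type)))
    df$element %in% c("N", "O")
  else
    toupper(df$pdbqt_type) %in% c("NA", "OA")
  list(is_hydrophobic = hydrophobic, is_hbond_donor = donor,
       is_hbond_acceptor = acceptor)
}

# squared cross-distance matrix between two coordinate matrices
.cross_dist2 <- function(a, b) {
  ra <- rowSums(a^2); rb <- rowSums(b^2)
  d2 <- outer(ra, rb, "+") - 2 * tcrossprod(a, b)
  d2[d2 < 0] <- 0
  d2
}

.finish_atoms <- function(df, h_coords, role, source, config) {
  if (nrow(df) == 0L)
    stop(sprintf("%s: no heavy atoms (only hydrogens/waters present)", source),
         call. = FALSE)
  flags <- .derive_flags(df, h_coords, config)
  typed_atoms(df$element, df$x, df$y, df$z, role = role,
              pdbqt_type = df$pdbqt_type,
              is_hydrophobic = flags$is_hydrophobic,
              is_hbond_donor = flags$is_hbond_donor,
              is_hbond_acceptor = flags$is_hbond_acceptor,
              config = config)
}

#' Parse a PDBQT file into typed heavy atoms and torsion metadata
#'
#' Reads ATOM/HETATM records at the fixed PDB columns, taking the element
#' from the trailing AutoDock atom-type field. Hydrogens (types H/HD/HS)
#' are stripped after being used to mark N/O donors; waters are excluded.
#' Torsion metadata records the REMARK-declared active-torsion count and
#' the number of BRANCH records.
#'
#' @param text file content: a single string or a character vector of lines.
#' @param role `"protein"` or `"ligand"`.
#' @param source label used in error messages (e.g. the file name).
#' @param config configuration list from [vf_config()].
#' @return a list with elements `atoms` (typed-atom table) and `torsions`
#'   (list with `n_active_torsions`, possibly `NA`, and `n_branch`).
#' @export
parse_pdbqt <- function(text, role = c("ligand", "protein"),
                        source = "pdbqt", config = vf_config()) {
  role <- match.arg(role)
  lines <- .as_lines(text)
  is_atom <- grepl("^(ATOM|HETATM)", lines)
  remark <- regmatches(lines, regexec("^REMARK\\s+(\\d+)\\s+active torsions", lines))
  n_active <- NA_integer_
  hit <- which(lengths(remark) == 2L)
  if (length(hit)) n_active <- as.integer(remark[[hit[1]]][2])
  n_branch <- sum(grepl("^BRANCH", lines))
  if (!any(is_atom))
    stop(sprintf("%s: no atom records", source), call. = FALSE)
  lineno <- which(is_atom)
  al <- lines[is_atom]
  xyz <- .parse_coords(al, lineno, source)
  resname <- toupper(trimws(substr(al, 18, 20)))
  type <- trimws(substr(al, 78, 79))
  blank <- type == ""
  if (any(blank)) {  # fall back to the last whitespace token
    toks <- strsplit(trimws(al[blank]), "\\s+")
    type[blank] <- vapply(toks, function(t) t[length(t)], character(1))
  }
  element <- .type_to_element(type)
  keep <- !(resname %in% c("HOH", "WAT"))
  if (role == "protein") keep <- keep & grepl("^ATOM", al)
  h <- element == "H"
  h_coords <- xyz[keep & h, , drop = FALSE]
  sel <- keep & !h
  df <- data.frame(element = element[sel], x = xyz[sel, "x"],
                   y = xyz[sel, "y"], z = xyz[sel, "z"],
                   pdbqt_type = type[sel], stringsAsFactors = FALSE)
  atoms <- .finish_atoms(df, h_coords, role, source, config)
  list(atoms = atoms,
       torsions = list(n_active_torsions = n_active, n_branch = n_branch))
}

# standard amino-acid residue names, used by the element heuristic
.aa3 <- c("ALA","ARG","ASN","ASP","CYS","GLN","GLU","GLY","HIS","ILE",
          "LEU","LYS","MET","PHE","PRO","SER","THR","TRP","TYR","VAL",
          "MSE","SEC","PYL")

#' Parse a PDB file into typed heavy atoms
#'
#' Reads ATOM/HETATM records at the fixed PDB 3.3 columns. The element is
#' taken from columns 77-78, falling back to atom-name heuristics (for
#' atoms in standard amino-acid residues the first letter of the name;
#' otherwise a two-letter element match is attempted first). Hydrogens are
#' stripped after donor marking; waters (HOH/WAT) are always excluded, and
#' for `role = "protein"` all HETATM records (cofactors) are too.
#'
#' @inheritParams parse_pdbqt
#' @return a typed-atom table.
#' @export
parse_pdb <- function(text, role = c("ligand", "protein"),
                      source = "pdb", config = vf_config()) {
  role <- match.arg(role)
  lines <- .as_lines(text)
  is_atom <- grepl("^(ATOM|HETATM)", lines)
  if (!any(is_atom))
    stop(sprintf("%s: no atom records", source), call. = FALSE)
  lineno <- which(is_atom)
  al <- lines[is_atom]
  xyz <- .parse_coords(al, lineno, source)
  name <- substr(al, 13, 16)
  resname <- toupper(trimws(substr(al, 18, 20)))
  elem_col <- trimws(substr(al, 77, 78))
  element <- ifelse(elem_col == "", NA_character_,
                    paste0(toupper(substr(elem_col, 1, 1)),
                           tolower(substr(elem_col, 2, 2))))
  known <- c(names(.vf_default_config()$radii), "H", "D",
             names(.vf_default_config()$masses))
  need <- which(is.na(element))
  for (i in need) {
    letters_only <- gsub("[^A-Za-z]", "", name[i])
    if (resname[i] %in% .aa3) {
      element[i] <- toupper(substr(letters_only, 1, 1))
    } else {
      two <- paste0(toupper(substr(letters_only, 1, 1)),
                    tolower(substr(letters_only, 2, 2)))
      element[i] <- if (nchar(letters_only) >= 2 && two %in% known) two
                    else toupper(substr(letters_only, 1, 1))
    }
  }
  element[element == "D"] <- "H"
  keep <- !(resname %in% c("HOH", "WAT"))
  if (role == "protein") keep <- keep & grepl("^ATOM", al)
  h <- element == "H"
  h_coords <- xyz[keep & h, , drop = FALSE]
  sel <- keep & !h
  df <- data.frame(element = element[sel], x = xyz[sel, "x"],
                   y = xyz[sel, "y"], z = xyz[sel, "z"],
                   pdbqt_type = NA_character_, stringsAsFactors = FALSE)
  .finish_atoms(df, h_coords, role, source, config)
}

#' Atom interaction properties from element, type and neighbours
#'
#' Pure-function atom typing for a single atom: hydrophobic iff a carbon
#' bonded only to carbon or hydrogen; H-bond acceptor iff the AutoDock
#' type is NA/OA (element N/O heuristic when no type is given); H-bond
#' donor iff an N/O carries a polar hydrogen (an HD/H neighbour); van der
#' Waals radius from the per-element table.
#'
#' @param element element symbol.
#' @param pdbqt_type AutoDock atom type, or `NA`.
#' @param bonded_elements character vector (multiset) of bonded element
#'   symbols / types, e.g. `c("C", "C", "H")` or `"HD"`.
#' @param config configuration list from [vf_config()].
#' @return a list with `is_hydrophobic`, `is_hbond_donor`,
#'   `is_hbond_acceptor`, `vdw_radius`.
#' @export
assign_atom_properties <- function(element, pdbqt_type = NA_character_,
                                   bonded_elements = character(),
                                   config = vf_config()) {
  known <- c(names(config$radii), names(config$masses), "H")
  if (!element %in% known) {
    stop(structure(class = c("vf_unknown_element", "error", "condition"),
                   list(message = paste0("unknown element: ", element),
                        call = sys.call(-1))))
  }
  bonded <- .type_to_element(bonded_elements)
  polar_h <- toupper(bonded_elements) == "HD" | bonded == "H"
  hydrophobic <- element == "C" &&
    (length(bonded) == 0L || all(bonded %in% c("C", "H")))
  acceptor <- if (!is.na(pdbqt_type)) toupper(pdbqt_type) %in% c("NA", "OA")
              else element %in% c("N", "O")
  donor <- element %in% c("N", "O") && any(polar_h)
  list(is_hydrophobic = hydrophobic,
       is_hbond_donor = donor,
       is_hbond_acceptor = acceptor,
       vdw_radius = .element_radius(element, config))
}

#' Ligand rotatable-bond count from torsion metadata
#'
#' Returns the REMARK-declared active-torsion count when present, else the
#' BRANCH-record count; warns when both are present and disagree (the
#' REMARK value wins). Rigid ligands give 0.
#'
#' @param torsions torsion metadata from [parse_pdbqt()].
#' @return a non-negative integer.
#' @export
count_rotatable_bonds <- function(torsions) {
  n_act <- torsions$n_active_torsions
  n_br <- torsions$n_branch %||% 0L
  if (!is.na(n_act)) {
    if (n_br > 0L && n_br != n_act) {
      warning(sprintf("REMARK active torsions (%d) != BRANCH count (%d); using REMARK",
                      n_act, n_br), call. = FALSE)
    }
    return(as.integer(n_act))
  }
  as.integer(n_br)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a typed-atom table as PDBQT text
#'
#' Emits a REMARK active-torsions line followed by ATOM records at the
#' fixed PDBQT columns. Atom types are taken from the `pdbqt_type` column
#' when present, otherwise derived from element and flags (acceptor N/O
#' become NA/OA). For every H-bond donor a marker polar hydrogen (type HD)
#' is written 0.6 Angstrom away so that donor flags survive a re-parse.
#'
#' @param atoms a typed-atom table.
#' @param n_rotatable_bonds active-torsion count for the REMARK line.
#' @param path optional file path; when `NULL` the text is returned.
#' @return invisibly (path given) or visibly, the PDBQT text lines.
#' @export
write_pdbqt <- function(atoms, n_rotatable_bonds = 0L, path = NULL) {
  type <- atoms$pdbqt_type
  derive <- is.na(type) | type == ""
  dt <- ifelse(atoms$element == "N" & atoms$is_hbond_acceptor, "NA",
        ifelse(atoms$element == "O" & atoms$is_hbond_acceptor, "OA",
               atoms$element))
  type[derive] <- dt[derive]
  fmt <- "ATOM  %5d %-4s %-3s A%4d    %8.3f%8.3f%8.3f  0.00  0.00    %+6.3f %-2s"
  res <- if (all(atoms$role == "ligand")) "LIG" else "PRO"
  lines <- sprintf(fmt, seq_len(nrow(atoms)),
                   substr(paste0(atoms$element, seq_len(nrow(atoms))), 1, 4),
                   res, 1L, atoms$x, atoms$y, atoms$z, 0,
                   substr(type, 1, 2))
  don <- which(atoms$is_hbond_donor)
  if (length(don)) {
    hd <- sprintf(fmt, nrow(atoms) + seq_along(don),
                  substr(paste0("H", don), 1, 4), res, 1L,
                  atoms$x[don] + 0.6, atoms$y[don], atoms$z[don], 0, "HD")
    lines <- c(lines, hd)
  }
  out <- c(sprintf("REMARK  %d active torsions", as.integer(n_rotatable_bonds)),
           lines, "TER")
  if (!is.null(path)) {
    writeLines(out, path)
    return(invisible(out))
  }
  out
}

#' Read a protein-ligand complex from structure files
#'
#' Convenience wrapper: dispatches on the `.pdbqt` / `.pdb` extension,
#' parses both files and assembles a [molecular_complex()] with the
#' ligand's rotatable-bond count taken from its PDBQT torsion metadata
#' (0 for plain PDB ligands).
#'
#' @param protein_file,ligand_file paths to PDB or PDBQT files.
#' @param id complex identifier; defaults to the ligand file stem.
#' @param config configuration list from [vf_config()].
#' @return a `molecular_complex`.
#' @export
read_complex <- function(protein_file, ligand_file, id = NULL,
                         config = vf_config()) {
  if (is.null(id)) id <- sub("\\.[^.]*$", "", basename(ligand_file))
  read_one <- function(path, role) {
    text <- readLines(path, warn = FALSE)
    if (grepl("\\.pdbqt$", path, ignore.case = TRUE)) {
      parse_pdbqt(text, role = role, source = basename(path), config = config)
    } else {
      list(atoms = parse_pdb(text, role = role, source = basename(path),
                             config = config),
           torsions = list(n_active_torsions = NA_integer_, n_branch = 0L))
    }
  }
  prot <- read_one(protein_file, "protein")
  lig <- read_one(ligand_file, "ligand")
  molecular_complex(id, prot$atoms, lig$atoms,
                    count_rotatable_bonds(lig$torsions))
}
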