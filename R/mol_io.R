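# Molecule and structure input/output.
#
# Small-molecule parsing (SMILES/SDF/MOL2) delegates to ChemmineR/ChemmineOB
# (openbabel); receptor structures are read with bio3d. Internally everything
# is in Angstrom; pocket cutoffs are accepted in nm to match the common
# "within 1 nm of the ligand" pocket convention.

HALOGENS <- c("F", "Cl", "Br", "I", "At")

#' Create a molecule record
#'
#' A molecule record holds an identifier, a SMILES string, optional 3D
#' coordinates and the source it was read from. Records are the unit the
#' screening pipeline iterates over.
#'
#' @param id Compound identifier (non-empty string).
#' @param smiles SMILES string.
#' @param coords Optional data.frame with columns `element`, `x`, `y`, `z`
#'   (Angstrom).
#' @param source Free-text provenance tag.
#' @return An object of class `molecule_record`.
#' @export
molecule_record <- function(id, smiles, coords = NULL, source = "user") {
  if (!is.character(id) || length(id) != 1L || !nzchar(id)) {
    stopf("molecule id must be a non-empty string")
  }
  if (!is.character(smiles) || length(smiles) != 1L) {
    stopf("smiles must be a single string")
  }
  if (!is.null(coords)) {
    stopifnot(is.data.frame(coords),
              all(c("element", "x", "y", "z") %in% names(coords)))
    if (!all(is.finite(as.matrix(coords[, c("x", "y", "z")])))) {
      stopf("molecule coordinates must be finite")
    }
  }
  structure(list(id = id, smiles = smiles, coords = coords, source = source),
            class = "molecule_record")
}

#' @export
print.molecule_record <- function(x, ...) {
  cat(sprintf("<molecule %s> %s%s\n", x$id, x$smiles,
              if (is.null(x$coords)) "" else sprintf(" [%d atoms 3D]",
                                                     nrow(x$coords))))
  invisible(x)
}

#' Canonicalize a SMILES string
#'
#' Converts to openbabel canonical SMILES so that different spellings of the
#' same molecule map to one representation. Returns `NA` for unparseable
#' input instead of raising, so callers can implement skip-with-warning
#' semantics.
#'
#' @param smiles Character vector of SMILES.
#' @return Character vector of canonical SMILES (`NA` where parsing failed).
#' @export
canonical_smiles <- function(smiles) {
  vapply(smiles, function(s) {
    if (!nzchar(trimws(s))) return(NA_character_)
    out <- tryCatch(
      suppressWarnings(ChemmineOB::convertFormat("SMI", "CAN",
                                                 paste0(s, "\n"))),
      error = function(e) ""
    )
    out <- trimws(strsplit(out, "[\t\n]")[[1]][1] %||% "")
    if (is.na(out) || !nzchar(out)) NA_character_ else out
  }, character(1), USE.NAMES = FALSE)
}

#' Read a compound library
#'
#' Reads molecules from SMILES (one per line, optional whitespace-separated
#' id), SDF or MOL2 files. Malformed entries are skipped with a warning and
#' counted in the `n_skipped` attribute of the result.
#'
#' @param path Input file.
#' @param format One of `"smiles"`, `"sdf"`, `"mol2"`.
#' @return List of [molecule_record()]s, with attribute `n_skipped`.
#' @export
read_library <- function(path, format = c("smiles", "sdf", "mol2")) {
  format <- match.arg(format)
  if (!file.exists(path)) stopf("cannot read library: no such file '%s'", path)
  records <- switch(format,
    smiles = read_library_smiles(path),
    sdf = read_library_sdf(path),
    mol2 = read_library_mol2(path)
  )
  if (length(records) == 0L) {
    stopf("library '%s' contains no parseable molecules", path)
  }
  ids <- vapply(records, `[[`, character(1), "id")
  if (anyDuplicated(ids)) {
    stopf("duplicate molecule ids in library: %s",
          paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  records
}

read_library_smiles <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  records <- list()
  skipped <- 0L
  for (k in seq_along(lines)) {
    parts <- strsplit(trimws(lines[k]), "[ \t]+")[[1]]
    smi <- parts[1]
    id <- if (length(parts) >= 2) parts[2] else sprintf("mol%04d", k)
    can <- canonical_smiles(smi)
    if (is.na(can)) {
      skipped <- skipped + 1L
      warnf("skipping unparseable SMILES on line %d: '%s'", k, smi)
      next
    }
    records[[length(records) + 1L]] <- molecule_record(id, smi, source = path)
  }
  structure(records, n_skipped = skipped)
}

# Minimal V2000 connection-table parser. Used instead of a full SDF
# toolkit because legitimate bond-less molecules (single heavy atom) must
# parse; chemistry (canonicalization, 3D) still goes through openbabel.
parse_sdf_records <- function(text) {
  lines <- if (length(text) == 1L) strsplit(text, "\n", fixed = TRUE)[[1]]
           else text
  breaks <- c(0L, which(trimws(lines) == "$$$$"))
  records <- list()
  for (b in seq_len(length(breaks) - 1L)) {
    if (breaks[b + 1L] - breaks[b] < 2L) next
    block <- lines[(breaks[b] + 1L):(breaks[b + 1L] - 1L)]
    if (all(!nzchar(trimws(block)))) next  # blank stretch, not a record
    rec <- tryCatch(parse_sdf_block(block), error = function(e) NULL)
    records[[length(records) + 1L]] <- rec
  }
  records
}

parse_sdf_block <- function(block) {
  if (length(block) < 4L) stop("truncated SDF block")
  counts <- block[4]
  natoms <- as.integer(substr(counts, 1, 3))
  nbonds <- as.integer(substr(counts, 4, 6))
  if (is.na(natoms) || natoms < 1L) stop("bad counts line")
  atom_lines <- block[4L + seq_len(natoms)]
  atoms <- data.frame(
    element = trimws(substr(atom_lines, 32, 34)),
    x = as.numeric(substr(atom_lines, 1, 10)),
    y = as.numeric(substr(atom_lines, 11, 20)),
    z = as.numeric(substr(atom_lines, 21, 30)),
    stringsAsFactors = FALSE)
  if (anyNA(atoms$x) || any(!nzchar(atoms$element))) stop("bad atom block")
  bonds <- if (nbonds > 0L) {
    bl <- block[4L + natoms + seq_len(nbonds)]
    data.frame(i = as.integer(substr(bl, 1, 3)),
               j = as.integer(substr(bl, 4, 6)),
               order = as.integer(substr(bl, 7, 9)))
  } else {
    data.frame(i = integer(0), j = integer(0), order = integer(0))
  }
  list(name = trimws(block[1]), atoms = atoms, bonds = bonds,
       text = paste(c(block, "$$$$", ""), collapse = "\n"))
}

read_library_sdf <- function(path) {
  recs <- parse_sdf_records(readLines(path, warn = FALSE))
  records <- list()
  skipped <- 0L
  for (k in seq_along(recs)) {
    rec <- recs[[k]]
    if (is.null(rec)) {
      skipped <- skipped + 1L
      warnf("skipping malformed SDF entry %d", k)
      next
    }
    id <- if (nzchar(rec$name)) rec$name else sprintf("mol%04d", k)
    smi <- tryCatch(
      trimws(strsplit(suppressWarnings(
        ChemmineOB::convertFormat("SDF", "CAN", rec$text)),
        "[\t\n]")[[1]][1]),
      error = function(e) NA_character_
    )
    if (is.na(smi) || !nzchar(smi)) {
      skipped <- skipped + 1L
      warnf("skipping SDF entry %d ('%s'): cannot derive SMILES", k, id)
      next
    }
    records[[length(records) + 1L]] <-
      molecule_record(id, smi, coords = rec$atoms, source = path)
  }
  structure(records, n_skipped = skipped)
}

read_library_mol2 <- function(path) {
  txt <- paste(readLines(path, warn = FALSE), collapse = "\n")
  sdftxt <- tryCatch(
    suppressWarnings(ChemmineOB::convertFormat("MOL2", "SDF",
                                               paste0(txt, "\n"))),
    error = function(e) stopf("cannot convert MOL2 file '%s'", path)
  )
  tf <- tempfile(fileext = ".sdf")
  on.exit(unlink(tf), add = TRUE)
  writeLines(sdftxt, tf)
  read_library_sdf(tf)
}

#' Write a compound library as a SMILES file
#'
#' One `SMILES<TAB>id` line per record; the inverse of
#' `read_library(format = "smiles")`.
#'
#' @param records List of [molecule_record()]s.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_library <- function(records, path) {
  lines <- vapply(records, function(r) paste(r$smiles, r$id, sep = "\t"),
                  character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Parse a molecule into an atom/bond graph
#'
#' Converts SMILES to an SDF connection table via openbabel and returns the
#' heavy-atom graph used for substructure sentences and fingerprints. The
#' SMILES is canonicalized first so atom order is a function of the molecule,
#' not of its spelling.
#'
#' @param smiles A single SMILES string.
#' @param gen3d If `TRUE`, generate 3D coordinates (adds explicit hydrogens
#'   during embedding; these are dropped from the returned graph but kept in
#'   `coords_all`).
#' @return List with `atoms` (data.frame: element, degree, order_sum),
#'   `bonds` (data.frame: i, j, order; heavy-atom indices), `coords`
#'   (heavy-atom coordinates) and `smiles_canonical`.
#' @export
molecule_graph <- function(smiles, gen3d = FALSE) {
  can <- canonical_smiles(smiles)
  if (is.na(can)) stopf("unparseable SMILES: '%s'", smiles)
  sdftxt <- suppressWarnings(
    if (gen3d) {
      ChemmineOB::convertFormat("SMI", "SDF", paste0(can, "\n"),
                                options = data.frame(names = "gen3D",
                                                     args = ""))
    } else {
      ChemmineOB::convertFormat("SMI", "SDF", paste0(can, "\n"))
    }
  )
  recs <- parse_sdf_records(sdftxt)
  if (length(recs) == 0L || is.null(recs[[1]])) {
    stopf("openbabel produced no valid structure for '%s'", smiles)
  }
  elements <- recs[[1]]$atoms$element
  coords_all <- recs[[1]]$atoms
  bonds_all <- recs[[1]]$bonds
  heavy <- which(elements != "H")
  remap <- integer(length(elements))
  remap[heavy] <- seq_along(heavy)
  keep <- bonds_all$i %in% heavy & bonds_all$j %in% heavy
  bonds <- bonds_all[keep, , drop = FALSE]
  bonds$i <- remap[bonds$i]
  bonds$j <- remap[bonds$j]
  n <- length(heavy)
  degree <- integer(n)
  order_sum <- integer(n)
  for (r in seq_len(nrow(bonds))) {
    degree[bonds$i[r]] <- degree[bonds$i[r]] + 1L
    degree[bonds$j[r]] <- degree[bonds$j[r]] + 1L
    order_sum[bonds$i[r]] <- order_sum[bonds$i[r]] + bonds$order[r]
    order_sum[bonds$j[r]] <- order_sum[bonds$j[r]] + bonds$order[r]
  }
  list(
    atoms = data.frame(element = elements[heavy], degree = degree,
                       order_sum = order_sum, stringsAsFactors = FALSE),
    bonds = bonds,
    coords = coords_all[heavy, , drop = FALSE],
    coords_all = coords_all,
    smiles_canonical = can
  )
}

#' Create a receptor structure model
#'
#' @param atoms data.frame with columns `element`, `name`, `resname`,
#'   `resno`, `chain`, `x`, `y`, `z` (Angstrom).
#' @return Object of class `structure_model`.
#' @export
structure_model <- function(atoms) {
  req <- c("element", "name", "resname", "resno", "chain", "x", "y", "z")
  stopifnot(is.data.frame(atoms), all(req %in% names(atoms)))
  if (nrow(atoms) == 0L) stopf("structure has no atoms")
  if (!all(is.finite(as.matrix(atoms[, c("x", "y", "z")])))) {
    stopf("structure coordinates must be finite")
  }
  for (ch in unique(atoms$chain)) {
    rn <- atoms$resno[atoms$chain == ch]
    if (is.unsorted(rn)) {
      stopf("residue numbers must be monotone within chain '%s'", ch)
    }
  }
  rownames(atoms) <- NULL
  structure(list(atoms = atoms), class = "structure_model")
}

#' @export
print.structure_model <- function(x, ...) {
  cat(sprintf("<structure: %d atoms, %d residues, chains %s>\n",
              nrow(x$atoms),
              nrow(unique(x$atoms[, c("chain", "resno")])),
              paste(unique(x$atoms$chain), collapse = ",")))
  invisible(x)
}

#' Read a receptor structure from a PDB file
#'
#' @param path PDB file.
#' @return A [structure_model()].
#' @export
read_structure <- function(path) {
  if (!file.exists(path)) stopf("no such PDB file: '%s'", path)
  pdb <- bio3d::read.pdb(path, verbose = FALSE)
  a <- pdb$atom
  element <- trimws(a$elesy)
  guess <- toupper(substr(trimws(a$elety), 1, 1))
  element[!nzchar(element) | is.na(element)] <-
    guess[!nzchar(element) | is.na(element)]
  structure_model(data.frame(
    element = element, name = trimws(a$elety), resname = trimws(a$resid),
    resno = a$resno, chain = ifelse(is.na(a$chain) | !nzchar(a$chain), "A",
                                    a$chain),
    x = a$x, y = a$y, z = a$z, stringsAsFactors = FALSE
  ))
}

#' Extract the binding pocket around a reference ligand
#'
#' A residue belongs to the pocket iff the minimum heavy-atom distance
#' between any of its atoms and any ligand atom is at most the cutoff
#' (boundary inclusive). The cutoff is given in nm; coordinates are Angstrom.
#' Hydrogens are ignored on both sides. The pocket mass center is the
#' unweighted mean of the included residues' heavy-atom coordinates.
#'
#' @param struct A [structure_model()].
#' @param ligand_coords Matrix or data.frame of ligand coordinates
#'   (columns x, y, z, Angstrom; a data.frame may carry an `element` column,
#'   in which case hydrogens are dropped).
#' @param cutoff_nm Distance cutoff in nm (default 1.0).
#' @return Object of class `pocket_definition`: `residues` (chain, resno),
#'   `cutoff_nm`, `mass_center` (Angstrom), `atoms` (the pocket heavy atoms).
#' @export
extract_pocket <- function(struct, ligand_coords, cutoff_nm = 1.0) {
  stopifnot(inherits(struct, "structure_model"))
  if (!is_scalar_number(cutoff_nm) || cutoff_nm <= 0) {
    stopf("cutoff_nm must be a positive number")
  }
  lig <- as_coord_matrix(ligand_coords, drop_h = TRUE)
  if (nrow(lig) == 0L) stopf("ligand has no (heavy-atom) coordinates")
  atoms <- struct$atoms[struct$atoms$element != "H", , drop = FALSE]
  if (nrow(atoms) == 0L) stopf("structure has no heavy atoms")
  cutoff <- nm_to_angstrom(cutoff_nm)
  pm <- as.matrix(atoms[, c("x", "y", "z")])
  # min distance of every protein atom to any ligand atom
  d2min <- rep(Inf, nrow(pm))
  for (k in seq_len(nrow(lig))) {
    d2 <- (pm[, 1] - lig[k, 1])^2 + (pm[, 2] - lig[k, 2])^2 +
      (pm[, 3] - lig[k, 3])^2
    d2min <- pmin(d2min, d2)
  }
  atoms$.mind <- sqrt(d2min)
  keyres <- unique(atoms[atoms$.mind <= cutoff, c("chain", "resno")])
  if (nrow(keyres) == 0L) {
    stopf("no residue within %.2f nm of the ligand (empty pocket)", cutoff_nm)
  }
  sel <- paste(atoms$chain, atoms$resno) %in% paste(keyres$chain, keyres$resno)
  pocket_atoms <- atoms[sel, setdiff(names(atoms), ".mind"), drop = FALSE]
  rownames(pocket_atoms) <- NULL
  rownames(keyres) <- NULL
  structure(list(
    residues = keyres,
    cutoff_nm = cutoff_nm,
    mass_center = colMeans(as.matrix(pocket_atoms[, c("x", "y", "z")])),
    atoms = pocket_atoms
  ), class = "pocket_definition")
}

as_coord_matrix <- function(x, drop_h = FALSE) {
  if (is.data.frame(x)) {
    if (drop_h && "element" %in% names(x)) x <- x[x$element != "H", ,
                                                  drop = FALSE]
    m <- as.matrix(x[, c("x", "y", "z")])
  } else {
    m <- as.matrix(x)
    colnames(m) <- c("x", "y", "z")
  }
  storage.mode(m) <- "double"
  m
}

#' Write docking input files in PDBQT format
#'
#' Writes a rigid receptor PDBQT and a ligand PDBQT. Ligand 3D coordinates
#' are generated (openbabel) when the record has none. The PDBQT dialect
#' written is the minimal one docking engines accept for rigid input:
#' ATOM/HETATM records with a zero partial charge column and the element as
#' AutoDock atom type.
#'
#' @param struct A [structure_model()] (receptor).
#' @param molecule A [molecule_record()] (ligand).
#' @param outdir Output directory (created if needed).
#' @return Named character vector with `receptor` and `ligand` paths.
#' @export
write_pdbqt_inputs <- function(struct, molecule, outdir) {
  stopifnot(inherits(struct, "structure_model"),
            inherits(molecule, "molecule_record"))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  coords <- molecule$coords
  if (is.null(coords)) {
    g <- tryCatch(molecule_graph(molecule$smiles, gen3d = TRUE),
                  error = function(e) NULL)
    if (is.null(g) || nrow(g$coords) == 0L) {
      stopf("cannot generate 3D coordinates for molecule '%s'", molecule$id)
    }
    coords <- g$coords
  }
  coords <- coords[coords$element != "H", , drop = FALSE]
  if (nrow(coords) == 0L) stopf("molecule '%s' has no heavy atoms",
                                molecule$id)
  rec_path <- file.path(outdir, "receptor.pdbqt")
  lig_path <- file.path(outdir, paste0(sanitize_filename(molecule$id),
                                       ".pdbqt"))
  writeLines(pdbqt_lines(struct$atoms, hetatm = FALSE), rec_path)
  lig_atoms <- data.frame(element = coords$element, name = coords$element,
                          resname = "LIG", resno = 1L, chain = "L",
                          x = coords$x, y = coords$y, z = coords$z,
                          stringsAsFactors = FALSE)
  writeLines(c("ROOT", pdbqt_lines(lig_atoms, hetatm = TRUE), "ENDROOT",
               "TORSDOF 0"), lig_path)
  c(receptor = rec_path, ligand = lig_path)
}

pdbqt_lines <- function(atoms, hetatm = FALSE) {
  rec <- if (hetatm) "HETATM" else "ATOM  "
  vapply(seq_len(nrow(atoms)), function(i) {
    a <- atoms[i, ]
    sprintf("%s%5d %-4s %-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f    %6.3f %-2s",
            rec, i %% 100000L, substr(a$name, 1, 4), substr(a$resname, 1, 3),
            substr(a$chain, 1, 1), a$resno %% 10000L, a$x, a$y, a$z,
            1.00, 0.00, 0.000, substr(a$element, 1, 2))
  }, character(1))
}

sanitize_filename <- function(x) gsub("[^A-Za-z0-9_.-]", "_", x)
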