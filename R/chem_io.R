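#' Construct a ligand pose
#'
#' A ligand pose is a small molecule with 3D coordinates in the protein
#' frame (pre-posed; no docking is performed here), an optional potency
#' label in pIC50 units, an optional assay timestamp and a crystal-reference
#' flag.  Bonds are kept for substructure (MCS) and fingerprint work.
#'
#' @param id ligand identifier (string).
#' @param elements character vector of element symbols; every symbol must be
#'   one of C, N, O, F, P, S, Cl, Br, I, H.
#' @param coords numeric matrix (n x 3) of coordinates in Angstrom.
#' @param bonds optional data frame / matrix with columns `a1`, `a2`,
#'   `order` (1-based atom indices).
#' @param pic50 potency as pIC50 (-log10 molar IC50), or `NA`.
#' @param timestamp optional ordinal assay timestamp.
#' @param is_crystal_reference logical crystal-structure flag.
#' @return an object of class `ligand_pose`.
#' @export
ligand_pose <- function(id, elements, coords, bonds = NULL, pic50 = NA_real_,
                        timestamp = NA_real_, is_crystal_reference = FALSE) {
  coords <- matrix(as.numeric(coords), ncol = 3,
                   dimnames = list(NULL, c("x", "y", "z")))
  elements <- normalize_element(elements)
  if (length(elements) != nrow(coords))
    stop("elements and coords disagree in length for ligand '", id, "'")
  bad <- setdiff(unique(elements), PP_ELEMENTS)
  if (length(bad))
    stop("ligand '", id, "' contains unsupported element(s): ",
         paste(bad, collapse = ", "))
  if (any(!is.finite(coords)))
    stop("ligand '", id, "' has non-finite coordinates")
  if (!is.null(bonds)) {
    bonds <- as.data.frame(bonds)
    names(bonds)[1:2] <- c("a1", "a2")
    if (is.null(bonds$order)) bonds$order <- 1L
  }
  structure(list(id = as.character(id), elements = elements, coords = coords,
                 bonds = bonds, pic50 = as.numeric(pic50),
                 timestamp = as.numeric(timestamp),
                 is_crystal_reference = isTRUE(is_crystal_reference)),
            class = "ligand_pose")
}

#' @export
print.ligand_pose <- function(x, ...) {
  cat(sprintf("<ligand_pose> %s: %d atoms (%d heavy), pIC50 %s%s%s\n",
              x$id, length(x$elements), sum(x$elements != "H"),
              ifelse(is.na(x$pic50), "NA", format(x$pic50, digits = 4)),
              ifelse(is.na(x$timestamp), "",
                     sprintf(", t=%g", x$timestamp)),
              ifelse(x$is_crystal_reference, ", crystal reference", "")))
  invisible(x)
}

n_heavy <- function(ligand) sum(ligand$elements != "H")

# Element symbols normalized to chemical case ("CL" -> "Cl").
normalize_element <- function(e) {
  e <- trimws(e)
  paste0(toupper(substr(e, 1, 1)), tolower(substr(e, 2, nchar(e))))
}

#' Bundle a protein and its congeneric ligand series
#'
#' @param protein a `protein_structure` from [read_protein()].
#' @param ligands list of [ligand_pose()] objects with unique ids; at most
#'   one may carry the crystal-reference flag.
#' @param pocket_center optional xyz (Angstrom).  Defaults to the heavy-atom
#'   centroid of the crystal-reference ligand (or of the first ligand when
#'   no crystal reference is flagged).
#' @return an object of class `congeneric_series`.
#' @export
congeneric_series <- function(protein, ligands, pocket_center = NULL) {
  stopifnot(inherits(protein, "protein_structure"))
  ids <- vapply(ligands, function(l) l$id, "")
  if (anyDuplicated(ids))
    stop("duplicate ligand ids in series: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  if (sum(vapply(ligands, function(l) l$is_crystal_reference, TRUE)) > 1)
    stop("a series can hold at most one crystal-reference ligand")
  names(ligands) <- ids
  if (is.null(pocket_center)) {
    ref <- Find(function(l) l$is_crystal_reference, ligands) %||% ligands[[1]]
    heavy <- ref$elements != "H"
    pocket_center <- colMeans(ref$coords[heavy, , drop = FALSE])
  }
  structure(list(protein = protein, ligands = ligands,
                 pocket_center = as.numeric(pocket_center)),
            class = "congeneric_series")
}

#' @export
print.congeneric_series <- function(x, ...) {
  n_aff <- sum(!is.na(series_pic50(x)))
  cat(sprintf(
    "<congeneric_series> %d ligands (%d with pIC50), %d protein atoms\n",
    length(x$ligands), n_aff, nrow(x$protein$atoms)))
  cat(sprintf("  pocket center: (%.2f, %.2f, %.2f) A\n",
              x$pocket_center[1], x$pocket_center[2], x$pocket_center[3]))
  invisible(x)
}

series_ids <- function(series) names(series$ligands)
series_pic50 <- function(series)
  vapply(series$ligands, function(l) l$pic50, 0.0)
series_timestamps <- function(series)
  vapply(series$ligands, function(l) l$timestamp, 0.0)

#' Read a protein structure from a PDB file
#'
#' Parses ATOM (and optionally HETATM) records, normalizes element symbols
#' and assigns the eight pharmacophoric channel flags via
#' [assign_protein_channels()].  Waters, ions and cofactors are excluded by
#' default; the pocket description is protein-only.
#'
#' @param path PDB file.
#' @param include_hetero keep non-water HETATM records (ions, cofactors).
#' @param include_waters keep water molecules.
#' @param rules channel rule table, see [pp_channel_rules()].
#' @return an object of class `protein_structure` with `$atoms` (data frame:
#'   element, residue, atom, x, y, z) and `$channels` (logical n x 8 matrix
#'   over hydrophobic, aromatic, acceptor, donor, positive, negative, metal,
#'   excluded).
#' @export
read_protein <- function(path, include_hetero = FALSE,
                         include_waters = FALSE,
                         rules = pp_channel_rules()) {
  if (!file.exists(path)) stop("PDB file not found: ", path)
  pdb <- tryCatch(bio3d::read.pdb(path, verbose = FALSE),
                  error = function(e)
                    stop("failed to parse PDB '", path, "': ",
                         conditionMessage(e), call. = FALSE))
  at <- pdb$atom
  waters <- c("HOH", "WAT", "H2O", "DOD", "TIP3", "TIP", "SOL")
  keep <- at$type == "ATOM"
  if (include_hetero) keep <- keep | (at$type == "HETATM" &
                                        !(at$resid %in% waters))
  if (include_waters) keep <- keep | (at$resid %in% waters)
  at <- at[keep, , drop = FALSE]
  if (nrow(at) == 0)
    stop("no protein atoms in '", path,
         "' after filtering (empty structure)")
  ele <- normalize_element(at$elesy)
  miss <- is.na(ele) | !nzchar(ele)
  if (any(miss)) ele[miss] <- element_from_atom_name(at$elety[miss])
  atoms <- data.frame(element = ele, residue = toupper(at$resid),
                      atom = toupper(at$elety), resno = at$resno,
                      x = at$x, y = at$y, z = at$z,
                      stringsAsFactors = FALSE)
  if (any(!is.finite(as.matrix(atoms[, c("x", "y", "z")]))))
    stop("non-finite coordinates in '", path, "'")
  protein_structure(atoms, rules)
}

# Fallback element perception from the PDB atom-name column.
element_from_atom_name <- function(name) {
  name <- toupper(gsub("[0-9' ]", "", name))
  two <- substr(name, 1, 2)
  ele <- substr(name, 1, 1)
  known2 <- toupper(c(PP_METALS, "Cl", "Br"))
  ele[two %in% known2] <- two[two %in% known2]
  normalize_element(ele)
}

#' @rdname read_protein
#' @param atoms data frame with columns element, residue, atom, x, y, z.
#' @export
protein_structure <- function(atoms, rules = pp_channel_rules()) {
  structure(list(atoms = atoms,
                 channels = assign_protein_channels(atoms, rules)),
            class = "protein_structure")
}

#' @export
print.protein_structure <- function(x, ...) {
  heavy <- x$atoms$element != "H"
  cat(sprintf("<protein_structure> %d atoms (%d heavy), %d residues\n",
              nrow(x$atoms), sum(heavy),
              length(unique(paste(x$atoms$residue, cumsum(!duplicated(x$atoms$residue)))))))
  counts <- colSums(x$channels)
  cat("  channel atoms:",
      paste(sprintf("%s=%d", colnames(x$channels), counts), collapse = " "),
      "\n")
  invisible(x)
}

#' The pharmacophore channel rule table
#'
#' Residue/atom-name lookup rules mapping protein atoms to the eight
#' pharmacophoric channels.  The table ships as a plain-text file
#' (`inst/extdata/protein_channels.tsv`) and can be replaced by any file in
#' the same format.  Carbon atoms of standard residues default to
#' hydrophobic, metal elements to metallic, and every heavy atom carries the
#' excluded-volume flag.
#'
#' @param path rule file; defaults to the table shipped with the package.
#' @return data frame with columns residue, atom, channels.
#' @export
pp_channel_rules <- function(path = system.file("extdata",
                                                "protein_channels.tsv",
                                                package = "pairpot")) {
  read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
}

#' Assign pharmacophoric channel flags to protein atoms
#'
#' @param atoms data frame with columns element, residue, atom.
#' @param rules rule table from [pp_channel_rules()].
#' @return logical matrix (n atoms x 8 channels).  Hydrogens carry no flag;
#'   every heavy atom carries the excluded-volume flag; atoms of residues
#'   absent from the rule table get only excluded volume, with a warning.
#' @export
assign_protein_channels <- function(atoms, rules = pp_channel_rules()) {
  n <- nrow(atoms)
  m <- matrix(FALSE, n, 8, dimnames = list(NULL, PP_PROTEIN_CHANNELS))
  if (n == 0) return(m)
  ele <- normalize_element(atoms$element)
  res <- toupper(atoms$residue)
  nm <- toupper(atoms$atom)
  heavy <- ele != "H"
  m[, "excluded"] <- heavy
  is_metal <- ele %in% PP_METALS
  m[is_metal, "metal"] <- TRUE
  known <- res %in% c(PP_STANDARD_RESIDUES,
                      toupper(rules$residue[rules$residue != "*"]))
  unknown <- heavy & !known & !is_metal
  if (any(unknown))
    warning("unknown residue(s) ", paste(unique(res[unknown]), collapse = ", "),
            ": only the excluded-volume flag assigned")
  # carbons of known residues default to hydrophobic
  m[heavy & known & ele == "C", "hydrophobic"] <- TRUE
  key <- paste(res, nm)
  specific <- match(key, paste(toupper(rules$residue), toupper(rules$atom)))
  backbone <- match(nm, toupper(rules$atom[rules$residue == "*"]))
  bb_rows <- which(rules$residue == "*")
  for (i in which(heavy & known)) {
    hit <- specific[i]
    chans <- character()
    if (!is.na(hit) && rules$residue[hit] != "*")
      chans <- strsplit(rules$channels[hit], ",")[[1]]
    if (!is.na(backbone[i]))
      chans <- union(chans, strsplit(rules$channels[bb_rows[backbone[i]]],
                                     ",")[[1]])
    if (length(chans)) m[i, trimws(chans)] <- TRUE
  }
  m
}

#' Assign one-hot element channels to ligand atoms
#'
#' @param elements character vector of element symbols from the supported
#'   10-element set.
#' @return logical matrix (n atoms x 10 channels, columns in the order
#'   C, N, O, F, P, S, Cl, Br, I, H); exactly one `TRUE` per row.
#' @export
assign_ligand_channels <- function(elements) {
  elements <- normalize_element(elements)
  bad <- setdiff(unique(elements), PP_ELEMENTS)
  if (length(bad))
    stop("unsupported ligand element(s): ", paste(bad, collapse = ", "))
  m <- matrix(FALSE, length(elements), length(PP_ELEMENTS),
              dimnames = list(NULL, PP_ELEMENTS))
  m[cbind(seq_along(elements), match(elements, PP_ELEMENTS))] <- TRUE
  m
}

#' Read a congeneric ligand series from an SDF file
#'
#' One [ligand_pose()] per molecule block, in file order.  Affinities are
#' read from a named SD tag and converted to pIC50 with
#' [convert_affinity()].  Molecules containing elements outside the
#' supported 10-element set are skipped with a warning rather than aborting
#' the read.
#'
#' @param path SDF (V2000) file.
#' @param affinity_tag SD tag holding the affinity (default `"pIC50"`); set
#'   to `NA` to skip affinity parsing.
#' @param affinity_unit unit of that tag, see [convert_affinity()].
#' @param timestamp_tag,crystal_tag optional SD tags for the assay order and
#'   the crystal-reference flag (any of 1/true/yes marks the reference).
#' @return list of `ligand_pose` objects.
#' @export
read_ligands <- function(path, affinity_tag = "pIC50",
                         affinity_unit = "pIC50",
                         timestamp_tag = "timestamp",
                         crystal_tag = "crystal_reference") {
  if (!file.exists(path)) stop("SDF file not found: ", path)
  sdfs <- tryCatch(ChemmineR::read.SDFset(path),
                   error = function(e)
                     stop("failed to parse SDF '", path, "': ",
                          conditionMessage(e), call. = FALSE))
  out <- list()
  for (i in seq_along(ChemmineR::cid(sdfs))) {
    sdf <- sdfs[[i]]
    hdr <- ChemmineR::header(sdf)
    id <- trimws(hdr[["Molecule_Name"]])
    if (!nzchar(id)) id <- sprintf("mol_%03d", i)
    ab <- ChemmineR::atomblock(sdf)
    if (nrow(ab) == 0 || is.null(rownames(ab))) {
      warning("skipping ligand '", id, "': unparseable molecule block")
      next
    }
    elements <- normalize_element(sub("_.*$", "", rownames(ab)))
    bad <- setdiff(unique(elements), PP_ELEMENTS)
    if (length(bad)) {
      warning("skipping ligand '", id, "': unsupported element(s) ",
              paste(bad, collapse = ", "))
      next
    }
    bb <- ChemmineR::bondblock(sdf)
    bonds <- if (length(bb))
      data.frame(a1 = as.integer(bb[, 1]), a2 = as.integer(bb[, 2]),
                 order = as.integer(bb[, 3]))
    db <- ChemmineR::datablock(sdf)
    pic50 <- NA_real_
    if (!is.na(affinity_tag) && affinity_tag %in% names(db))
      pic50 <- convert_affinity(as.numeric(db[[affinity_tag]]),
                                affinity_unit)
    ts <- if (timestamp_tag %in% names(db))
      as.numeric(db[[timestamp_tag]]) else NA_real_
    cry <- crystal_tag %in% names(db) &&
      tolower(trimws(db[[crystal_tag]])) %in% c("1", "true", "yes")
    out[[length(out) + 1L]] <- ligand_pose(
      id = id, elements = elements, coords = ab[, 1:3, drop = FALSE],
      bonds = bonds, pic50 = pic50, timestamp = ts,
      is_crystal_reference = cry)
  }
  out
}

#' Write ligand poses to an SDF (V2000) file
#'
#' Inverse of [read_ligands()]: coordinates at the standard four decimals,
#' affinity/timestamp/crystal flags emitted as SD tags.
#'
#' @param ligands list of `ligand_pose` objects.
#' @param path output file.
#' @param affinity_tag SD tag to store the pIC50 under.
#' @export
write_ligands <- function(ligands, path, affinity_tag = "pIC50") {
  sdfs <- lapply(ligands, function(lig) {
    n <- length(lig$elements)
    nb <- if (is.null(lig$bonds)) 0L else nrow(lig$bonds)
    ab <- cbind(round(lig$coords, 4),
                matrix(0, n, 12, dimnames = list(NULL, paste0("C", 5:16))))
    colnames(ab)[1:3] <- c("C1", "C2", "C3")
    rownames(ab) <- paste(lig$elements, seq_len(n), sep = "_")
    bb <- if (nb) cbind(C1 = lig$bonds$a1, C2 = lig$bonds$a2,
                        C3 = lig$bonds$order, C4 = 0, C5 = 0, C6 = 0, C7 = 0)
      else matrix(0, 0, 7, dimnames = list(NULL, paste0("C", 1:7)))
    hdr <- c(Molecule_Name = lig$id, Source = "  pairpot", Comment = "",
             Counts_Line = sprintf(
               "%3d%3d  0  0  0  0  0  0  0  0999 V2000", n, nb))
    db <- character()
    if (!is.na(lig$pic50)) db[affinity_tag] <- format(lig$pic50, digits = 10)
    if (!is.na(lig$timestamp)) db["timestamp"] <- format(lig$timestamp)
    if (lig$is_crystal_reference) db["crystal_reference"] <- "1"
    if (!length(db)) db <- c(pairpot = "1")
    methods::new("SDF", header = hdr, atomblock = ab, bondblock = bb,
                 datablock = db)
  })
  names(sdfs) <- vapply(ligands, function(l) l$id, "")
  ChemmineR::write.SDF(methods::as(sdfs, "SDFset"), path)
  invisible(path)
}

#' Write a protein structure to a PDB file
#'
#' Pseudo-atoms keep their residue and atom names so the channel assignment
#' round-trips through the file.
#'
#' @param protein a `protein_structure`.
#' @param path output file.
#' @export
write_protein <- function(protein, path) {
  at <- protein$atoms
  n <- nrow(at)
  resno <- at$resno %||% seq_len(n)
  lines <- sprintf(
    "ATOM  %5d %-4s %-3s A%4d    %8.3f%8.3f%8.3f  1.00  0.00          %2s",
    seq_len(n), substr(at$atom, 1, 4), at$residue, resno,
    at$x, at$y, at$z, toupper(at$element))
  writeLines(c(lines, "END"), path)
  invisible(path)
}
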