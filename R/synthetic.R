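# Self-contained toy congeneric series: a pseudo-atom pocket, a
# scaffold-plus-substituents ligand family, and a deterministic
# structure-activity oracle.  The oracle rewards pocket-proximal polar
# substituents specifically, so the joint protein-ligand voxel descriptor
# carries signal that ligand composition alone does not.

# Fixed pocket-floor anchor atoms lining the four substituent sites; the
# rest of the pocket is a seed-dependent hemispherical shell.
toy_anchors <- function() {
  data.frame(
    element = c("N", "O", "C", "Zn"),
    residue = c("LYS", "ASP", "PHE", "ZN"),
    atom = c("NZ", "OD1", "CZ", "ZN"),
    resno = 1:4,
    x = c(-2.25, -0.75, 2.25, 0.75),
    y = c(0.5, -0.5, -0.5, 0.5),
    z = c(-4.0, -4.0, -4.0, -4.3),
    stringsAsFactors = FALSE)
}

#' Generate a toy protein pocket
#'
#' Four fixed anchor atoms (a lysine donor, an aspartate acceptor, an
#' aromatic carbon and a zinc) line the pocket floor below the ligand
#' scaffold; 26--56 further pseudo-atoms are placed on the lower
#' hemispherical shell of radius about 8 Angstrom around the origin, with
#' residue/atom identities drawn from a small palette so that the standard
#' channel rules apply.  Deterministic given the seed; the origin is the
#' pocket center.
#'
#' @param seed integer seed.
#' @return a `protein_structure`; every atom lies within 10 Angstrom of the
#'   origin and no two atoms come closer than 0.8 Angstrom.
#' @export
make_toy_pocket <- function(seed = 1) {
  palette <- data.frame(
    element = c("C", "C", "C", "C", "O", "O", "N"),
    residue = c("LEU", "VAL", "ALA", "PHE", "SER", "ASN", "ARG"),
    atom = c("CD1", "CG1", "CB", "CZ", "OG", "OD1", "NH1"),
    stringsAsFactors = FALSE)
  anchors <- toy_anchors()
  with_seed(derive_seed(seed, "pocket"), {
    n_fill <- sample(26:56, 1)
    placed <- as.matrix(anchors[, c("x", "y", "z")])
    rows <- vector("list", n_fill)
    for (i in seq_len(n_fill)) {
      repeat {
        u <- rnorm(3)
        u <- u / sqrt(sum(u^2))
        u[3] <- -abs(u[3])
        r <- min(max(rnorm(1, 8, 0.5), 6.5), 9.5)
        p <- u * r
        if (min(sqrt(colSums((t(placed) - p)^2))) > 1.5) break
      }
      placed <- rbind(placed, p)
      k <- sample(nrow(palette), 1)
      rows[[i]] <- data.frame(element = palette$element[k],
                              residue = palette$residue[k],
                              atom = palette$atom[k], resno = 4L + i,
                              x = p[1], y = p[2], z = p[3],
                              stringsAsFactors = FALSE)
    }
    protein_structure(rbind(anchors, do.call(rbind, rows)))
  })
}

#' Specification of a synthetic congeneric series
#'
#' Defines the generator's conditions: series size, scaffold length, the
#' substituent element palette with its per-element potency weights (pIC50
#' units at proximity factor 1), the label noise, and the seed.  Generated
#' potencies are fully reproducible from the seed.
#'
#' @param n_ligands number of ligands.
#' @param scaffold_size heavy atoms in the linear carbon scaffold.
#' @param palette substituent element palette (subset of C, N, O, F, Cl).
#' @param weights named per-element potency contribution at proximity
#'   factor 1 (pIC50 units); unnamed elements contribute 0.
#' @param noise_sigma Gaussian label noise (pIC50).
#' @param seed generator seed.
#' @return an object of class `toy_series_spec`.
#' @export
toy_series_spec <- function(n_ligands = 50, scaffold_size = 6,
                            palette = c("C", "N", "O", "F", "Cl"),
                            weights = c(C = 0, N = 1.2, O = 0.9, F = 0.5,
                                        Cl = -0.6),
                            noise_sigma = 0.3, seed = 1) {
  stopifnot(n_ligands >= 1, scaffold_size >= 4)
  bad <- setdiff(palette, c("C", "N", "O", "F", "Cl"))
  if (length(bad))
    stop("palette element(s) outside the supported set: ",
         paste(bad, collapse = ", "))
  structure(list(n_ligands = as.integer(n_ligands),
                 scaffold_size = as.integer(scaffold_size),
                 palette = palette, weights = weights,
                 noise_sigma = noise_sigma, base = 5.0,
                 seed = as.integer(seed)),
            class = "toy_series_spec")
}

# Substituent attachment sites: up to four interior scaffold carbons.
toy_sites <- function(spec) {
  interior <- 2:(spec$scaffold_size - 1)
  interior[seq_len(min(4L, length(interior)))]
}

scaffold_x <- function(spec)
  (seq_len(spec$scaffold_size) - (spec$scaffold_size + 1) / 2) * 1.5

# Build one toy ligand: linear carbon scaffold through the pocket center
# with one single-atom substituent per site, pointing at the pocket floor,
# plus hydrogen caps on the terminal carbons.
toy_ligand <- function(spec, id, sub_elements, pic50 = NA_real_,
                       timestamp = NA_real_, crystal = FALSE) {
  m <- spec$scaffold_size
  sites <- toy_sites(spec)[seq_along(sub_elements)]
  xs <- scaffold_x(spec)
  elements <- c(rep("C", m), sub_elements, "H", "H")
  sub_xyz <- if (length(sites)) cbind(xs[sites], 0, -1.4)
    else matrix(0, 0, 3)
  coords <- rbind(cbind(xs, 0, 0), sub_xyz,
                  c(xs[1] - 1.09, 0, 0),
                  c(xs[m] + 1.09, 0, 0))
  bonds <- data.frame(
    a1 = c(seq_len(m - 1), sites, 1L, m),
    a2 = c(seq_len(m - 1) + 1L, m + seq_along(sites),
           m + length(sites) + 1L, m + length(sites) + 2L),
    order = 1L)
  ligand_pose(id, elements, coords, bonds = bonds, pic50 = pic50,
              timestamp = timestamp, is_crystal_reference = crystal)
}

#' Deterministic potency oracle of the toy series
#'
#' The noise-free part of the generator's potency: base 5.0 plus, for every
#' substituent atom (heavy atoms after the first `scaffold_size` scaffold
#' atoms), `weight(element) * pf(d)` where `d` is the distance to the
#' nearest hydrogen-bond donor or acceptor pocket atom and
#' `pf(d) = 1 / (1 + (d/3)^2)` (1 at the pocket atom itself).
#'
#' @param ligand a [ligand_pose()] following the toy convention (scaffold
#'   atoms first).
#' @param spec the [toy_series_spec()].
#' @param pocket optionally the already-generated pocket (regenerated from
#'   `spec$seed` otherwise).
#' @return noise-free pIC50.
#' @export
oracle_affinity <- function(ligand, spec, pocket = NULL) {
  if (is.null(pocket)) pocket <- make_toy_pocket(spec$seed)
  polar <- pocket$channels[, "donor"] | pocket$channels[, "acceptor"]
  pp <- as.matrix(pocket$atoms[polar, c("x", "y", "z"), drop = FALSE])
  heavy <- ligand$elements != "H"
  sub <- which(heavy & seq_along(ligand$elements) > spec$scaffold_size)
  contrib <- 0
  for (i in sub) {
    w <- spec$weights[ligand$elements[i]]
    if (is.na(w)) w <- 0
    d <- min(sqrt(rowSums(sweep(pp, 2, ligand$coords[i, ])^2)))
    contrib <- contrib + w / (1 + (d / 3)^2)
  }
  spec$base + unname(contrib)
}

#' Generate a synthetic congeneric series
#'
#' Every ligand shares a linear carbon scaffold threaded through the pocket
#' center and differs only in the single-atom substituents drawn per site
#' from the palette.  The recorded pIC50 is [oracle_affinity()] plus
#' Gaussian noise; timestamps follow generation order and the first ligand
#' carries the crystal-reference flag.
#'
#' @param spec a [toy_series_spec()].
#' @return a [congeneric_series()] whose pocket center is the origin.
#' @export
make_series <- function(spec) {
  stopifnot(inherits(spec, "toy_series_spec"))
  pocket <- make_toy_pocket(spec$seed)
  sites <- toy_sites(spec)
  ligands <- with_seed(derive_seed(spec$seed, "series"), {
    lapply(seq_len(spec$n_ligands), function(i) {
      subs <- sample(spec$palette, length(sites), replace = TRUE)
      lig <- toy_ligand(spec, sprintf("lig_%03d", i), subs,
                        timestamp = i, crystal = (i == 1L))
      lig$pic50 <- oracle_affinity(lig, spec, pocket) +
        rnorm(1, 0, spec$noise_sigma)
      lig
    })
  })
  congeneric_series(pocket, ligands, pocket_center = c(0, 0, 0))
}

#' Write / read a series as standard files
#'
#' `write_series()` emits exactly the input formats the readers consume --
#' a PDB pocket, an SDF V2000 ligand file with pIC50 / timestamp /
#' crystal-reference SD tags, and a tabular manifest -- so generated
#' fixtures double as format round-trip tests.  `read_series()` is the
#' inverse.
#'
#' @param series a [congeneric_series()].
#' @param dir output directory (created if missing).
#' @return `write_series()` returns the directory; `read_series()` the
#'   restored series.
#' @export
write_series <- function(series, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_protein(series$protein, file.path(dir, "protein.pdb"))
  write_ligands(series$ligands, file.path(dir, "ligands.sdf"))
  pic <- series_pic50(series)
  manifest <- data.frame(
    id = series_ids(series), sdf_index = seq_along(series$ligands),
    affinity = pic, unit = "pIC50",
    timestamp = series_timestamps(series),
    crystal = vapply(series$ligands, function(l) l$is_crystal_reference,
                     TRUE))
  write.table(manifest, file.path(dir, "manifest.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' @rdname write_series
#' @param protein_path,ligand_path file paths (defaults relative to `dir`).
#' @param config a [pairpot_config()] supplying the SD-tag names.
#' @export
read_series <- function(dir = NULL,
                        protein_path = file.path(dir, "protein.pdb"),
                        ligand_path = file.path(dir, "ligands.sdf"),
                        config = pairpot_config()) {
  protein <- read_protein(protein_path,
                          include_hetero = config$include_hetero,
                          include_waters = config$include_waters)
  ligands <- read_ligands(ligand_path,
                          affinity_tag = config$affinity_tag,
                          affinity_unit = config$affinity_unit,
                          timestamp_tag = config$timestamp_tag,
                          crystal_tag = config$crystal_tag)
  congeneric_series(protein, ligands)
}
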