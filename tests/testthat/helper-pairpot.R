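# Shared fixtures and independent oracles for the test suite.  Everything
# is generated in code; nothing is downloaded or read from outside the
# package.

# Reduced training configuration used by the desk-scale learning tests:
# 2 A voxels on the same 24 A box (12^3 grid), a slim encoder, moderate
# dropout and a learning rate suited to few-epoch runs.
tiny_config <- function(...) {
  args <- list(resolution = 2, filters1 = 8, filters2 = 16, latent = 32,
               dropout = 0.2, lr = 2e-3, batch_size = 32, augment = FALSE)
  override <- list(...)
  args[names(override)] <- override
  do.call(pairpot_config, args)
}

# Memoized toy series so expensive fixtures build once per run.
.series_cache <- new.env(parent = emptyenv())
cached_series <- function(n_ligands, noise_sigma = 0.3, seed = 1) {
  key <- sprintf("s_%d_%g_%d", n_ligands, noise_sigma, seed)
  if (is.null(.series_cache[[key]]))
    .series_cache[[key]] <- make_series(
      toy_series_spec(n_ligands = n_ligands, noise_sigma = noise_sigma,
                      seed = seed))
  .series_cache[[key]]
}

# Independent brute-force voxelizer: loops explicitly over atoms and
# channels and evaluates every voxel of the full grid (no spatial
# windowing), max-aggregating occupancies.  Shares only the published
# definition with the production code.
brute_voxelize <- function(protein, ligand, center, cfg) {
  D <- cfg$grid_dim
  out <- array(0, c(18, D, D, D))
  ax <- center[1] - cfg$box_edge / 2 + (seq_len(D) - 0.5) * cfg$resolution
  ay <- center[2] - cfg$box_edge / 2 + (seq_len(D) - 0.5) * cfg$resolution
  az <- center[3] - cfg$box_edge / 2 + (seq_len(D) - 0.5) * cfg$resolution
  paint <- function(slab, ch, p, rv) {
    for (iz in seq_len(D)) {
      for (iy in seq_len(D)) {
        r <- sqrt((ax - p[1])^2 + (ay[iy] - p[2])^2 + (az[iz] - p[3])^2)
        occ <- 1 - exp(-(rv / r)^12)
        occ[r > cfg$cutoff] <- 0
        slab[ch, , iy, iz] <- pmax(slab[ch, , iy, iz], occ)
      }
    }
    slab
  }
  if (nrow(protein$atoms)) {
    pr <- vdw_radius(protein$atoms$element)
    pc <- as.matrix(protein$atoms[, c("x", "y", "z")])
    for (ch in 1:8)
      for (i in which(protein$channels[, ch]))
        out <- paint(out, ch, pc[i, ], pr[i])
  }
  if (length(ligand$elements)) {
    lch <- assign_ligand_channels(ligand$elements)
    lr <- vdw_radius(ligand$elements)
    for (ch in 1:10)
      for (i in which(lch[, ch]))
        out <- paint(out, 8 + ch, ligand$coords[i, ], lr[i])
  }
  out
}

# Random small protein-ligand complex (at most `max_atoms` atoms in total)
# centered near the origin, for voxelizer oracle checks.
random_complex <- function(seed, max_atoms = 10) {
  set.seed(seed)
  types <- data.frame(
    element = c("N", "O", "C", "C", "O", "S"),
    residue = c("LYS", "ASP", "LEU", "PHE", "SER", "CYS"),
    atom = c("NZ", "OD1", "CD1", "CZ", "OG", "SG"),
    stringsAsFactors = FALSE)
  n_prot <- sample(1:5, 1)
  n_lig <- sample(1:min(5, max_atoms - n_prot), 1)
  k <- sample(nrow(types), n_prot, replace = TRUE)
  prot <- protein_structure(data.frame(
    element = types$element[k], residue = types$residue[k],
    atom = types$atom[k], resno = seq_len(n_prot),
    x = runif(n_prot, -8, 8), y = runif(n_prot, -8, 8),
    z = runif(n_prot, -8, 8), stringsAsFactors = FALSE))
  lig <- ligand_pose(
    "rnd", sample(c("C", "N", "O", "F", "Cl", "H"), n_lig, replace = TRUE),
    cbind(runif(n_lig, -6, 6), runif(n_lig, -6, 6), runif(n_lig, -6, 6)))
  list(protein = prot, ligand = lig,
       series = congeneric_series(prot, list(lig),
                                  pocket_center = c(0, 0, 0)))
}

# Minimal hand-written PDB / SDF fixtures.
write_mini_pdb <- function(lines, path = tempfile(fileext = ".pdb")) {
  writeLines(c(lines, "END"), path)
  path
}

pdb_atom_line <- function(serial, name, res, resno, x, y, z, element,
                          type = "ATOM  ") {
  sprintf("%s%5d %-4s %-3s A%4d    %8.3f%8.3f%8.3f  1.00  0.00          %2s",
          type, serial, name, res, resno, x, y, z, toupper(element))
}

# A tiny V2000 molecule block (single molecule; no bonds unless given).
sdf_block <- function(id, elements, coords, tags = character(),
                      bonds = NULL) {
  nb <- if (is.null(bonds)) 0L else nrow(bonds)
  lines <- c(id, "  test", "",
             sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000",
                     length(elements), nb))
  for (i in seq_along(elements))
    lines <- c(lines, sprintf(
      "%10.4f%10.4f%10.4f %-3s 0  0  0  0  0  0  0  0  0  0  0  0",
      coords[i, 1], coords[i, 2], coords[i, 3], elements[i]))
  if (nb) for (i in seq_len(nb))
    lines <- c(lines, sprintf("%3d%3d%3d  0  0  0  0",
                              bonds[i, 1], bonds[i, 2], bonds[i, 3]))
  lines <- c(lines, "M  END")
  for (tag in names(tags))
    lines <- c(lines, paste0("> <", tag, ">"), tags[[tag]], "")
  c(lines, "$$$$")
}

write_mini_sdf <- function(..., path = tempfile(fileext = ".sdf")) {
  writeLines(unlist(list(...)), path)
  path
}

# Simple chain molecules (ethanol-like toys) for MCS / dedup tests:
# a linear chain of the given heavy elements with unit bonds.
chain_ligand <- function(id, elements, pic50 = NA_real_, crystal = FALSE,
                         timestamp = NA_real_) {
  n <- length(elements)
  bonds <- if (n > 1)
    data.frame(a1 = seq_len(n - 1), a2 = seq_len(n - 1) + 1L, order = 1L)
  ligand_pose(id, elements, cbind(1.5 * seq_len(n), 0, 0), bonds = bonds,
              pic50 = pic50, timestamp = timestamp,
              is_crystal_reference = crystal)
}
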