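#' Van der Waals radius lookup
#'
#' Radii ship as a plain-text table (`inst/extdata/vdw_radii.tsv`; Bondi
#' values for the main-group elements) and can be replaced by any file in
#' the same two-column format.
#'
#' @param elements character vector of element symbols.
#' @param table optional data frame with columns element, radius.
#' @return numeric vector of radii in Angstrom.
#' @export
vdw_radius <- function(elements, table = pp_vdw_table()) {
  r <- table$radius[match(normalize_element(elements), table$element)]
  if (any(is.na(r)))
    stop("no van der Waals radius for element(s): ",
         paste(unique(elements[is.na(r)]), collapse = ", "))
  r
}

#' @rdname vdw_radius
#' @param path radius file.
#' @export
pp_vdw_table <- function(path = system.file("extdata", "vdw_radii.tsv",
                                            package = "pairpot")) {
  read.delim(path, stringsAsFactors = FALSE)
}

#' Occupancy contribution of one atom to one voxel
#'
#' Pair-correlation occupancy `1 - exp(-(r_vdw / r)^12)`: 1 at the atom
#' center, `1 - exp(-1)` at one van der Waals radius, and decaying as the
#' twelfth power beyond it.  Monotonically non-increasing in `r`.
#'
#' @param r distance between atom and voxel center (Angstrom, `>= 0`).
#' @param r_vdw van der Waals radius of the atom (Angstrom, `> 0`).
#' @return occupancy in `[0, 1]` (vectorized over both arguments).
#' @export
atom_contribution <- function(r, r_vdw) {
  if (any(r_vdw <= 0)) stop("r_vdw must be positive")
  if (any(r < 0)) stop("r must be non-negative")
  1 - exp(-(r_vdw / r)^12)
}

# Voxel-center offsets along one axis: box corner + (i + 0.5) * resolution.
voxel_axis <- function(center1, config)
  center1 - config$box_edge / 2 +
    (seq_len(config$grid_dim) - 0.5) * config$resolution

#' Uniform random rotation matrix
#'
#' Uniform over SO(3) (random unit quaternion), deterministic given the
#' seed, determinant +1.  The caller's RNG stream is left untouched.
#'
#' @param seed integer seed.
#' @return 3 x 3 orthonormal rotation matrix.
#' @export
random_rotation <- function(seed) {
  q <- with_seed(as.integer(seed), rnorm(4))
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y + w * z), 2 * (x * z - w * y),
           2 * (x * y - w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z + w * x),
           2 * (x * z + w * y), 2 * (y * z - w * x), 1 - 2 * (x^2 + y^2)),
         3, 3)
}

rotate_about <- function(coords, center, rotation) {
  sweep(sweep(coords, 2, center) %*% t(rotation), 2, center, `+`)
}

check_rotation <- function(rotation) {
  if (is.null(rotation)) return(invisible(NULL))
  stopifnot(is.matrix(rotation), all(dim(rotation) == c(3, 3)))
  if (max(abs(crossprod(rotation) - diag(3))) > 1e-6)
    stop("rotation matrix is not orthonormal (tolerance 1e-6)")
  invisible(NULL)
}

# Core occupancy rasterizer: max-aggregates atom contributions onto an
# (n_channels x D^3) matrix.  `membership` is a logical (n_atoms x
# n_channels) matrix saying which channels an atom populates.
rasterize_channels <- function(coords, radii, membership, center, config) {
  D <- config$grid_dim
  nc <- ncol(membership)
  grid <- array(0, c(nc, D, D, D))
  if (nrow(membership) == 0 || !any(membership)) return(grid)
  ax <- voxel_axis(center[1], config)
  ay <- voxel_axis(center[2], config)
  az <- voxel_axis(center[3], config)
  cut <- config$cutoff
  active <- which(rowSums(membership) > 0)
  for (i in active) {
    p <- coords[i, ]
    # axis index windows within the cutoff
    ix <- which(abs(ax - p[1]) <= cut)
    iy <- which(abs(ay - p[2]) <= cut)
    iz <- which(abs(az - p[3]) <= cut)
    if (!length(ix) || !length(iy) || !length(iz)) next
    dx2 <- (ax[ix] - p[1])^2
    dy2 <- (ay[iy] - p[2])^2
    dz2 <- (az[iz] - p[3])^2
    r <- sqrt(outer(outer(dx2, dy2, `+`), dz2, `+`))
    occ <- atom_contribution(r, radii[i])
    occ[r > cut] <- 0
    for (ch in which(membership[i, ])) {
      cur <- grid[ch, ix, iy, iz]
      grid[ch, ix, iy, iz] <- pmax(cur, occ)
    }
  }
  grid
}

# Protein half of the grid: 8 pharmacophoric channels.
voxelize_protein <- function(protein, center, config, rotation = NULL) {
  coords <- as.matrix(protein$atoms[, c("x", "y", "z")])
  if (!is.null(rotation)) coords <- rotate_about(coords, center, rotation)
  radii <- vdw_radius(protein$atoms$element)
  rasterize_channels(coords, radii, protein$channels, center, config)
}

# Ligand half of the grid: 10 one-hot element channels.
voxelize_ligand <- function(ligand, center, config, rotation = NULL) {
  coords <- ligand$coords
  if (!is.null(rotation)) coords <- rotate_about(coords, center, rotation)
  if (length(ligand$elements) == 0)
    return(array(0, c(length(PP_ELEMENTS), config$grid_dim,
                      config$grid_dim, config$grid_dim)))
  radii <- vdw_radius(ligand$elements)
  rasterize_channels(coords, radii, assign_ligand_channels(ligand$elements),
                     center, config)
}

#' Voxelize a protein--ligand complex
#'
#' Builds the 18-channel cubic occupancy grid describing one complex:
#' channels 1--8 are the protein pharmacophoric channels, channels 9--18
#' the ligand element channels.  Each voxel takes the maximum
#' [atom_contribution()] over the atoms populating its channel (so values
#' stay in `[0, 1]` for any atom count); atoms farther than the contribution
#' cutoff from a voxel center are skipped.  Voxel centers sit at
#' half-integer offsets from the box corner.
#'
#' @param series a [congeneric_series()] (supplies the protein and default
#'   center) or a `protein_structure`.
#' @param ligand a [ligand_pose()].
#' @param center box center (xyz, Angstrom); defaults to the series pocket
#'   center.
#' @param rotation optional 3 x 3 orthonormal matrix applied to all atom
#'   coordinates about `center` before gridding.
#' @param config a [pairpot_config()].
#' @return a `voxel_grid`: numeric array `[18, D, D, D]` (D = 24 at the
#'   default 24 A box and 1 A resolution) with attributes `center`, `edge`
#'   and `resolution`.
#' @export
voxelize <- function(series, ligand, center = NULL, rotation = NULL,
                     config = pairpot_config()) {
  protein <- if (inherits(series, "congeneric_series")) series$protein
    else series
  if (is.null(center) && inherits(series, "congeneric_series"))
    center <- series$pocket_center
  if (is.null(center)) stop("a box center is required")
  if (any(!is.finite(center))) stop("box center must be finite")
  check_rotation(rotation)
  gp <- voxelize_protein(protein, center, config, rotation)
  gl <- voxelize_ligand(ligand, center, config, rotation)
  g <- array(0, c(18, config$grid_dim, config$grid_dim, config$grid_dim))
  g[1:8, , , ] <- gp
  g[9:18, , , ] <- gl
  n_atoms <- nrow(protein$atoms) + length(ligand$elements)
  if (n_atoms > 0 && all(g == 0))
    warning("no atoms inside the voxel box; returning an all-zero grid")
  structure(g, center = center, edge = config$box_edge,
            resolution = config$resolution, class = "voxel_grid")
}

#' @export
print.voxel_grid <- function(x, ...) {
  d <- dim(x)
  cat(sprintf("<voxel_grid> [%s], %d voxels occupied, max %.3f\n",
              paste(d, collapse = ", "), sum(x > 0), max(x)))
  invisible(x)
}

# Flatten a voxel grid (or plain array) to the column layout the C++
# kernels use: c + C*(ix + D*iy + D^2*iz).
grid_column <- function(grid) as.numeric(grid)
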