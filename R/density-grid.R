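#' Construct a density grid
#'
#' A density grid is a 3D scalar field on a regular voxel lattice with a
#' physical voxel size and an origin, both in Angstrom. Voxel indices are
#' 0-based in all coordinate conversions: the world coordinate of voxel
#' `(i, j, k)` is `origin + c(i, j, k) * voxel_size`, i.e. indices address
#' voxel centers.
#'
#' @param values 3D numeric array of density values, axes in (x, y, z) order.
#' @param voxel_size Voxel edge length in Angstrom; scalar or length-3.
#' @param origin Map origin in Angstrom (world coordinate of voxel 0,0,0).
#' @return A `density_grid`: the array with `voxel_size` and `origin`
#'   attributes.
#' @export
#' @examples
#' g <- density_grid(array(0, c(8, 8, 8)), voxel_size = 1)
#' dim(g)
density_grid <- function(values, voxel_size = 1, origin = c(0, 0, 0)) {
  if (length(dim(values)) != 3L) {
    abort("`values` must be a 3D array.")
  }
  dimnames(values) <- NULL
  dim(values) <- unname(dim(values))
  voxel_size <- rep_len(unname(as.numeric(voxel_size)), 3L)
  if (any(voxel_size <= 0)) {
    abort("all `voxel_size` components must be > 0.")
  }
  if (length(unique(voxel_size)) > 1L) {
    warn("anisotropic voxel size; downstream geometry handles it, but check the map header.")
  }
  structure(values,
            voxel_size = voxel_size,
            origin = rep_len(as.numeric(origin), 3L),
            class = c("density_grid", "array"))
}

#' @export
print.density_grid <- function(x, ...) {
  cat(sprintf("<density_grid> %s voxels, voxel size %s A, origin (%s) A\n",
              paste(dim(x), collapse = " x "),
              paste(signif(attr(x, "voxel_size"), 4), collapse = ", "),
              paste(signif(attr(x, "origin"), 4), collapse = ", ")))
  invisible(x)
}

#' Convert between voxel indices and world coordinates
#'
#' `voxel_to_angstrom()` maps 0-based voxel indices to Angstrom coordinates
#' (`origin + index * voxel_size`); `angstrom_to_voxel()` is its inverse and
#' rounds to the nearest voxel.
#'
#' @param grid A [density_grid()].
#' @param index Integer matrix (n x 3) or length-3 vector of 0-based indices.
#' @param coord Numeric matrix (n x 3) or length-3 vector of Angstrom
#'   coordinates.
#' @return An n x 3 matrix (coordinates or 0-based indices).
#' @export
voxel_to_angstrom <- function(grid, index) {
  index <- rbind_coerce(index)
  sweep(sweep(index, 2L, attr(grid, "voxel_size"), "*"),
        2L, attr(grid, "origin"), "+")
}

#' @rdname voxel_to_angstrom
#' @export
angstrom_to_voxel <- function(grid, coord) {
  coord <- rbind_coerce(coord)
  out <- sweep(sweep(coord, 2L, attr(grid, "origin"), "-"),
               2L, attr(grid, "voxel_size"), "/")
  round(out)
}

rbind_coerce <- function(x) {
  if (is.null(dim(x))) matrix(as.numeric(x), ncol = 3L) else
    matrix(as.numeric(x), ncol = ncol(x))
}

#' Normalize a density grid to [0, 1]
#'
#' Negative densities are clamped to zero, then values are min-max scaled to
#' `[0, 1]`. A constant map maps to all zeros.
#'
#' @param grid A [density_grid()].
#' @return A [density_grid()] with values in `[0, 1]`.
#' @export
normalize_density <- function(grid) {
  v <- pmax(unclass(grid), 0)
  rng <- range(v)
  if (rng[2] > rng[1]) v <- (v - rng[1]) / (rng[2] - rng[1]) else v[] <- 0
  density_grid(array(v, dim(grid)),
               voxel_size = attr(grid, "voxel_size"),
               origin = attr(grid, "origin"))
}

# ---- MRC/CCP4 I/O -----------------------------------------------------------
# Binary MRC2014 reader/writer (mode 2, 32-bit float). Header fields follow
# the MRC2014 standard: NX/NY/NZ, MODE, NxSTART, MX/MY/MZ, CELLA, CELLB,
# MAPC/MAPR/MAPS, ORIGIN, "MAP " stamp. Only orthogonal cells are accepted.

#' Read a cryo-EM density map (MRC/CCP4)
#'
#' Reads a mode-2 (32-bit float) MRC/CCP4 map, permutes the data into
#' (x, y, z) axis order using the MAPC/MAPR/MAPS header fields, and derives
#' the voxel size from the cell dimensions. The origin is taken from the
#' MRC2014 ORIGIN record, falling back to `NxSTART * voxel_size` when ORIGIN
#' is all-zero (CCP4 convention).
#'
#' @param path Path to an MRC/CCP4 file.
#' @return A [density_grid()].
#' @export
read_density_map <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  nxyz <- readBin(con, "integer", 3L, size = 4L, endian = "little")
  mode <- readBin(con, "integer", 1L, size = 4L, endian = "little")
  if (any(nxyz <= 0) || any(nxyz > 4096L)) {
    abort(sprintf("malformed MRC header: NX/NY/NZ = (%s).", paste(nxyz, collapse = ", ")))
  }
  if (mode != 2L) {
    abort(sprintf("unsupported MRC MODE %d (field MODE); only mode 2 (float32) is supported.", mode))
  }
  nstart <- readBin(con, "integer", 3L, size = 4L, endian = "little")
  mxyz <- readBin(con, "integer", 3L, size = 4L, endian = "little")
  cella <- readBin(con, "numeric", 3L, size = 4L, endian = "little")
  cellb <- readBin(con, "numeric", 3L, size = 4L, endian = "little")
  mapcrs <- readBin(con, "integer", 3L, size = 4L, endian = "little")
  if (max(abs(cellb - 90)) > 1e-3) {
    abort(sprintf("non-orthogonal cell (field CELLB = %s); only 90-degree cells are supported.",
                  paste(signif(cellb, 5), collapse = ", ")))
  }
  if (!setequal(mapcrs, 1:3)) {
    abort(sprintf("malformed MRC header: MAPC/MAPR/MAPS = (%s) is not a permutation of 1..3.",
                  paste(mapcrs, collapse = ", ")))
  }
  seek(con, 49L * 4L)                      # words 50-52: ORIGIN (MRC2014)
  origin_rec <- readBin(con, "numeric", 3L, size = 4L, endian = "little")
  map_stamp <- readChar(con, 4L, useBytes = TRUE)
  if (!identical(substr(map_stamp, 1, 3), "MAP")) {
    warn("missing 'MAP ' stamp; attempting to read anyway.")
  }
  seek(con, 23L * 4L)
  nsymbt <- readBin(con, "integer", 1L, size = 4L, endian = "little")
  seek(con, 1024L + max(nsymbt, 0L))
  n <- prod(nxyz)
  vals <- readBin(con, "numeric", n, size = 4L, endian = "little")
  if (length(vals) < n) {
    abort("malformed MRC file: data section shorter than NX*NY*NZ.")
  }
  arr <- array(vals, dim = nxyz)           # file order: (columns, rows, sections)
  # axis f of the file array is spatial axis mapcrs[f]; permute to (x,y,z)
  perm <- match(1:3, mapcrs)
  arr <- aperm(arr, perm)
  voxel_size <- cella / mxyz               # CELLA and MX/MY/MZ are in x,y,z order
  nstart_xyz <- nstart[perm]               # NxSTART is in column/row/section order
  origin <- if (all(origin_rec == 0) && any(nstart_xyz != 0)) {
    nstart_xyz * voxel_size
  } else {
    origin_rec
  }
  density_grid(arr, voxel_size = voxel_size, origin = origin)
}

#' Write a density grid as an MRC2014 map
#'
#' Writes mode 2 (float32), axis order MAPC/MAPR/MAPS = 1/2/3, the grid's
#' voxel size encoded in CELLA, and the origin in the MRC2014 ORIGIN record.
#'
#' @param grid A [density_grid()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_density_map <- function(grid, path) {
  dims <- dim(grid)
  vs <- attr(grid, "voxel_size")
  org <- attr(grid, "origin")
  v <- as.numeric(grid)
  con <- file(path, "wb")
  on.exit(close(con))
  wint <- function(x) writeBin(as.integer(x), con, size = 4L, endian = "little")
  wflt <- function(x) writeBin(as.numeric(x), con, size = 4L, endian = "little")
  wint(dims)                               # NX NY NZ
  wint(2L)                                 # MODE
  wint(c(0L, 0L, 0L))                      # NXSTART..
  wint(dims)                               # MX MY MZ
  wflt(dims * vs)                          # CELLA
  wflt(c(90, 90, 90))                      # CELLB
  wint(1:3)                                # MAPC MAPR MAPS
  wflt(c(min(v), max(v), mean(v)))         # DMIN DMAX DMEAN
  wint(c(1L, 0L))                          # ISPG, NSYMBT
  wint(rep(0L, 25L))                       # EXTRA (words 26-49, incl. EXTTYP)
  wflt(org)                                # ORIGIN
  writeChar("MAP ", con, eos = NULL)       # MAP stamp
  writeBin(as.raw(c(0x44, 0x41, 0x00, 0x00)), con)  # little-endian machine stamp
  wflt(sd(v))                              # RMS
  wint(0L)                                 # NLABL
  writeBin(raw(800L), con)                 # labels
  stopifnot(seek(con) == 1024L)
  writeBin(as.numeric(v), con, size = 4L, endian = "little")
  invisible(path)
}

# ---- tiling -----------------------------------------------------------------

#' Tile a grid into 32^3 sub-grids
#'
#' Non-overlapping tiles covering the grid; boundary tiles are zero-padded.
#' Offsets (0-based voxel index of the tile corner in the parent grid) are
#' recorded for stitching.
#'
#' @param grid A [density_grid()] or plain 3D array.
#' @param size Tile edge length in voxels (default 32).
#' @return List of sub-grids, each `list(values = size^3 array, offset = int 3-vector)`.
#' @export
tile_into_subgrids <- function(grid, size = 32L) {
  dims <- dim(grid)
  if (is.null(dims) || any(dims < 1L)) abort("`grid` must be a non-empty 3D array.")
  ntile <- ceiling(dims / size)
  out <- vector("list", prod(ntile))
  idx <- 1L
  for (kz in seq_len(ntile[3])) for (ky in seq_len(ntile[2])) for (kx in seq_len(ntile[1])) {
    off <- c(kx - 1L, ky - 1L, kz - 1L) * size
    tile <- array(0, c(size, size, size))
    span <- pmin(dims - off, size)
    tile[seq_len(span[1]), seq_len(span[2]), seq_len(span[3])] <-
      unclass(grid)[off[1] + seq_len(span[1]),
                    off[2] + seq_len(span[2]),
                    off[3] + seq_len(span[3])]
    out[[idx]] <- list(values = tile, offset = as.integer(off))
    idx <- idx + 1L
  }
  out
}

#' Stitch per-tile probability grids back to the parent shape
#'
#' Inverse of [tile_into_subgrids()] for per-voxel probability fields:
#' zero-padding is discarded and every parent voxel receives exactly one
#' probability vector.
#'
#' @param tiles List of `list(values = size^3 x C array, offset = int 3-vector)`.
#' @param shape Parent grid dimensions (length 3).
#' @return 4D array `shape x C`.
#' @export
stitch_predictions <- function(tiles, shape) {
  if (length(tiles) == 0L) abort("no tiles supplied.")
  d4 <- dim(tiles[[1]]$values)
  size <- d4[1]
  nc <- if (length(d4) == 4L) d4[4] else 1L
  out <- array(NA_real_, c(shape, nc))
  seen <- array(FALSE, shape)
  for (t in tiles) {
    off <- t$offset
    span <- pmin(shape - off, size)
    if (any(span < 1L)) next
    vals <- array(t$values, c(size, size, size, nc))
    out[off[1] + seq_len(span[1]), off[2] + seq_len(span[2]),
        off[3] + seq_len(span[3]), ] <-
      vals[seq_len(span[1]), seq_len(span[2]), seq_len(span[3]), , drop = FALSE]
    seen[off[1] + seq_len(span[1]), off[2] + seq_len(span[2]),
         off[3] + seq_len(span[3])] <- TRUE
  }
  if (!all(seen)) {
    abort(sprintf("tiles do not cover the parent shape: %d voxels missing.", sum(!seen)))
  }
  out
}
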