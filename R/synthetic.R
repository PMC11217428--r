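#' Generate a synthetic multi-chain protein backbone
#'
#' Each chain is a self-avoiding random walk: consecutive C-alpha distances
#' are drawn from N(3.8047, 0.036) truncated to [3.6, 4.0] Angstrom (the
#' distribution the HMM transition model assumes), bond angles are uniform in
#' [80, 150] degrees, and no two atoms of any chain come closer than the
#' exclusion radius. Sequences are drawn from the background amino-acid
#' frequencies. The generator is a pure function of its seed.
#'
#' @param n_chains Number of chains.
#' @param residues_per_chain Residues per chain; scalar or length `n_chains`.
#' @param seed Integer seed.
#' @param exclusion Minimum inter-atom distance in Angstrom (default 3).
#' @param bond_mean,bond_sd Bond-length distribution (defaults 3.8047, 0.036).
#' @param retries Per-atom placement retry budget (default 200).
#' @return A `synthetic_protein` tibble: `chain_id`, `resno`, `aa`, `x`, `y`,
#'   `z`, with the generator parameters attached as attributes.
#' @export
#' @examples
#' p <- generate_protein(1, 10, seed = 7)
#' nrow(p)
generate_protein <- function(n_chains, residues_per_chain, seed,
                             exclusion = 3, bond_mean = 3.8047,
                             bond_sd = 0.036, retries = 200L) {
  if (n_chains < 1L || any(residues_per_chain < 1L)) abort("sizes must be positive.")
  lens <- rep_len(as.integer(residues_per_chain), n_chains)
  set.seed(seed)
  box <- bond_mean * sqrt(sum(lens)) * 1.2 + 10
  placed <- matrix(numeric(), 0, 3)
  rows <- vector("list", n_chains)
  draw_bond <- function() {
    repeat {
      d <- rnorm(1, bond_mean, bond_sd)
      if (d >= 3.6 && d <= 4.0) return(d)
    }
  }
  rand_dir <- function() {
    v <- rnorm(3)
    v / sqrt(sum(v^2))
  }
  # rotate `u` away from itself by angle alpha (deg), random azimuth
  turn <- function(u, alpha) {
    a <- alpha * pi / 180
    r <- rand_dir()
    perp <- r - sum(r * u) * u
    nrm <- sqrt(sum(perp^2))
    if (nrm < 1e-8) return(turn(u, alpha))
    perp <- perp / nrm
    cos(a) * u + sin(a) * perp
  }
  min_dist2 <- function(pt, pts) {
    if (nrow(pts) == 0L) return(Inf)
    min(colSums((t(pts) - pt)^2))
  }
  for (ci in seq_len(n_chains)) {
    n <- lens[ci]
    coords <- matrix(NA_real_, n, 3)
    ok_start <- FALSE
    for (r in seq_len(retries)) {
      start <- runif(3, 0, box)
      if (min_dist2(start, placed) >= exclusion^2) { ok_start <- TRUE; break }
    }
    if (!ok_start) abort("could not place a chain start; increase the box by lowering chain sizes.")
    coords[1, ] <- start
    dir <- rand_dir()
    i <- 2L
    while (i <= n) {
      placed_ok <- FALSE
      for (r in seq_len(retries)) {
        # bond angle in [80, 150] deg => direction change 180 - angle
        ang <- runif(1, 80, 150)
        new_dir <- if (i == 2L) rand_dir() else turn(dir, 180 - ang)
        cand <- coords[i - 1L, ] + draw_bond() * new_dir
        prev <- coords[seq_len(i - 2L), , drop = FALSE]
        if (min_dist2(cand, placed) >= exclusion^2 &&
            min_dist2(cand, prev) >= exclusion^2) {
          coords[i, ] <- cand
          dir <- new_dir
          placed_ok <- TRUE
          break
        }
      }
      if (!placed_ok) {
        abort("self-avoiding walk stalled; reduce chain length or exclusion radius.")
      }
      i <- i + 1L
    }
    placed <- rbind(placed, coords)
    rows[[ci]] <- tibble(chain_id = chain_id_pool[ci],
                         resno = seq_len(n),
                         aa = sample(AA_ALPHABET, n, replace = TRUE,
                                     prob = AA_BACKGROUND),
                         x = coords[, 1], y = coords[, 2], z = coords[, 3])
  }
  out <- bind_rows(rows)
  attr(out, "seed") <- seed
  attr(out, "params") <- list(exclusion = exclusion, bond_mean = bond_mean,
                              bond_sd = bond_sd)
  class(out) <- c("synthetic_protein", class(out))
  out
}

#' Chain sequences of a synthetic protein
#'
#' @param protein A [generate_protein()] result.
#' @return A [chain_sequence_set()].
#' @export
protein_sequences <- function(protein) {
  s <- vapply(split(protein$aa, factor(protein$chain_id, unique(protein$chain_id))),
              paste, character(1), collapse = "")
  chain_sequence_set(unique(protein$chain_id), s)
}

#' True structure of a synthetic protein
#'
#' @param protein A [generate_protein()] result.
#' @return A [structure_model()].
#' @export
protein_structure <- function(protein) {
  structure_model(tibble(chain_id = protein$chain_id, resno = protein$resno,
                         x = protein$x, y = protein$y, z = protein$z,
                         aa = protein$aa))
}

#' Rasterize a synthetic protein into a density map with label grids
#'
#' The density is a sum of isotropic Gaussian blobs at the C-alpha positions
#' (plus weaker pseudo C and N blobs placed 1/3 and 2/3 of the way to the
#' next C-alpha, purely cosmetic), min-max normalized to [0, 1]. Label grids
#' mark the voxel nearest each atom with its class; exactly one voxel is
#' labeled C-alpha per residue, and the amino-acid label grid carries the
#' residue type at that voxel (the none/unknown class elsewhere).
#'
#' @param protein A [generate_protein()] result.
#' @param voxel_size Voxel edge in Angstrom (default 1).
#' @param blob_sigma Gaussian blob spread in Angstrom (default 1).
#' @param padding Box padding around the protein in Angstrom (default 10).
#' @param include_cn Add pseudo C/N blobs and labels (default TRUE).
#' @return A `synthetic_map_bundle` list: `grid` ([density_grid()]),
#'   `atom_labels` (1 = CA, 2 = C, 3 = N, 4 = none), `aa_labels` (1..20 =
#'   amino acid, 21 = none), `truth` (the protein).
#' @export
rasterize <- function(protein, voxel_size = 1, blob_sigma = 1,
                      padding = 10, include_cn = TRUE) {
  if (voxel_size <= 0 || blob_sigma <= 0) abort("voxel_size and blob_sigma must be > 0.")
  ca <- as.matrix(protein[, c("x", "y", "z")])
  origin <- unname(floor(apply(ca, 2L, min) - padding))
  dims <- unname(ceiling((apply(ca, 2L, max) + padding - origin) / voxel_size) + 1L)
  dens <- array(0, dims)
  atom_lab <- array(4L, dims)
  aa_lab <- array(21L, dims)
  axes <- lapply(1:3, function(a) origin[a] + (seq_len(dims[a]) - 1L) * voxel_size)
  add_blob <- function(pt, amp) {
    lo <- pmax(floor((pt - 3 * blob_sigma - origin) / voxel_size) + 1L, 1L)
    hi <- pmin(ceiling((pt + 3 * blob_sigma - origin) / voxel_size) + 1L, dims)
    ix <- lo[1]:hi[1]; iy <- lo[2]:hi[2]; iz <- lo[3]:hi[3]
    gx <- exp(-(axes[[1]][ix] - pt[1])^2 / (2 * blob_sigma^2))
    gy <- exp(-(axes[[2]][iy] - pt[2])^2 / (2 * blob_sigma^2))
    gz <- exp(-(axes[[3]][iz] - pt[3])^2 / (2 * blob_sigma^2))
    dens[ix, iy, iz] <<- dens[ix, iy, iz] + amp * (gx %o% gy %o% gz)
  }
  nearest_voxel <- function(pt) pmin(pmax(round((pt - origin) / voxel_size) + 1L, 1L), dims)
  # pseudo C/N first so that C-alpha labels take priority at collisions
  if (include_cn) {
    for (ci in unique(protein$chain_id)) {
      idx <- which(protein$chain_id == ci)
      for (r in head(seq_along(idx), -1L)) {
        p0 <- ca[idx[r], ]; p1 <- ca[idx[r + 1L], ]
        pc <- p0 + (p1 - p0) / 3
        pn <- p0 + 2 * (p1 - p0) / 3
        add_blob(pc, 0.6); add_blob(pn, 0.6)
        vc <- nearest_voxel(pc); vn <- nearest_voxel(pn)
        if (atom_lab[vn[1], vn[2], vn[3]] == 4L) atom_lab[vn[1], vn[2], vn[3]] <- 3L
        if (atom_lab[vc[1], vc[2], vc[3]] == 4L) atom_lab[vc[1], vc[2], vc[3]] <- 2L
      }
    }
  }
  for (r in seq_len(nrow(ca))) {
    add_blob(ca[r, ], 1)
    v <- nearest_voxel(ca[r, ])
    atom_lab[v[1], v[2], v[3]] <- 1L
    aa_lab[v[1], v[2], v[3]] <- aa_index(protein$aa[r])
  }
  grid <- normalize_density(density_grid(dens, voxel_size, origin))
  structure(list(grid = grid, atom_labels = atom_lab, aa_labels = aa_lab,
                 truth = protein),
            class = "synthetic_map_bundle")
}

#' Simulate classifier output for a labeled synthetic map
#'
#' At labeled voxels, probability mass `correct_prob` goes to the true class
#' and the remainder is spread uniformly over the other classes. At
#' unlabeled voxels the mass goes to the none class, except that with
#' probability `fp_rate` a voxel becomes a false positive: the mass lands on
#' a random atom class instead. Reproducible from `seed`.
#'
#' @param bundle A [rasterize()] bundle.
#' @param correct_prob Probability mass on the true class, in (0, 1].
#' @param fp_rate False-positive rate at unlabeled voxels (default 0).
#' @param seed Integer seed.
#' @return A [prediction_grids()].
#' @export
simulate_predictions <- function(bundle, correct_prob, fp_rate = 0, seed = 1) {
  if (correct_prob <= 0 || correct_prob > 1) abort("`correct_prob` must be in (0, 1].")
  set.seed(seed)
  dims <- dim(bundle$atom_labels)
  nvox <- prod(dims)
  lab <- as.integer(bundle$atom_labels)
  if (fp_rate > 0) {
    none_idx <- which(lab == 4L)
    flip <- none_idx[runif(length(none_idx)) < fp_rate]
    lab[flip] <- sample(1:3, length(flip), replace = TRUE)
  }
  spread4 <- (1 - correct_prob) / 3
  atom <- matrix(spread4, nvox, 4L)
  atom[cbind(seq_len(nvox), lab)] <- correct_prob
  aalab <- as.integer(bundle$aa_labels)
  aalab[lab != 1L] <- 21L                  # amino-acid identity only at CA voxels
  spread21 <- (1 - correct_prob) / 20
  aa <- matrix(spread21, nvox, 21L)
  aa[cbind(seq_len(nvox), aalab)] <- correct_prob
  prediction_grids(array(atom, c(dims, 4L)), array(aa, c(dims, 21L)))
}

#' Synthetic training data for the confidence classifiers
#'
#' Features are Uniform(0, 1); labels are Bernoulli with success probability
#' `plogis(beta0 + beta1 * x)`.
#'
#' @param n Number of observations.
#' @param beta0,beta1 Planted logistic coefficients.
#' @param seed Integer seed.
#' @return A tibble with columns `x` and `y`.
#' @export
make_confidence_dataset <- function(n, beta0, beta1, seed) {
  if (n < 1L) abort("`n` must be positive.")
  set.seed(seed)
  x <- runif(n)
  y <- rbinom(n, 1L, plogis(beta0 + beta1 * x))
  tibble(x = x, y = y)
}

#' Build a toy labeled training set of 32^3 sub-grids
#'
#' Tiles a rasterized bundle and pairs each density tile with the matching
#' label tile (atom or amino-acid labels), for [train_toy()].
#'
#' @param bundle A [rasterize()] bundle.
#' @param labels `"atom"` (4 classes) or `"aa"` (21 classes).
#' @return List of `list(x, labels)` training samples.
#' @export
training_samples <- function(bundle, labels = c("atom", "aa")) {
  labels <- match.arg(labels)
  lab_grid <- if (labels == "atom") bundle$atom_labels else bundle$aa_labels
  none <- if (labels == "atom") 4L else 21L
  xt <- tile_into_subgrids(bundle$grid)
  lt <- tile_into_subgrids(lab_grid)
  purrr::map2(xt, lt, function(a, b) {
    lb <- b$values
    lb[lb == 0] <- none                    # zero-padding maps to the none class
    list(x = a$values, labels = array(as.integer(lb), dim(lb)))
  })
}
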