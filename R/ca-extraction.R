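#' Select candidate C-alpha voxels from prediction grids
#'
#' Voxels whose C-alpha class probability is strictly greater than
#' `threshold` are selected. Each candidate carries its world coordinate
#' (via the grid geometry) and its 20-type amino-acid probability vector,
#' renormalized after dropping the none/unknown class (emissions are defined
#' over the 20 standard amino acids only).
#'
#' @param preds A [prediction_grids()] aligned to `grid`.
#' @param grid The source [density_grid()].
#' @param threshold Selection threshold on the C-alpha probability
#'   (default 0.4, strict inequality).
#' @return A tibble with columns `voxel_index` (0-based, n x 3 matrix column),
#'   `x`, `y`, `z` (Angstrom), `ca_prob`, and `aa_probs` (n x 20 matrix
#'   column). May have zero rows.
#' @export
select_ca_voxels <- function(preds, grid, threshold = 0.4) {
  dm <- dim(preds$atom_probs)[1:3]
  if (!identical(dm, dim(grid))) abort("prediction grids do not match the map shape.")
  ca <- preds$atom_probs[, , , 1L]
  sel <- which(ca > threshold)
  if (length(sel) == 0L) {
    return(tibble(voxel_index = matrix(integer(), 0, 3),
                  x = numeric(), y = numeric(), z = numeric(),
                  ca_prob = numeric(), aa_probs = matrix(numeric(), 0, 20)))
  }
  idx1 <- arrayInd(sel, dm)                  # 1-based
  idx0 <- idx1 - 1L
  coords <- voxel_to_angstrom(grid, idx0)
  aam <- matrix(preds$aa_probs, prod(dm), 21L)[sel, , drop = FALSE]
  aam <- aam[, 1:20, drop = FALSE]
  rs <- rowSums(aam)
  zero <- rs <= 0
  if (any(zero)) aam[zero, ] <- 1 / 20       # uninformative fallback
  aam[!zero, ] <- aam[!zero, , drop = FALSE] / rs[!zero]
  tibble(voxel_index = idx0,
         x = coords[, 1], y = coords[, 2], z = coords[, 3],
         ca_prob = ca[sel],
         aa_probs = aam)
}

#' Cluster candidate C-alpha voxels into atoms
#'
#' Candidates are grouped into connected components of the graph linking
#' voxels within `radius` of each other (single linkage). Each cluster is
#' represented by its medoid — the member voxel minimizing the summed
#' distance to the other members, ties broken by higher C-alpha probability,
#' then by lower voxel index — while the cluster's C-alpha and amino-acid
#' probabilities are the member means (amino-acid means renormalized to
#' sum 1).
#'
#' @param candidates Output of [select_ca_voxels()].
#' @param radius Linkage radius in Angstrom (default 2).
#' @return A `ca_atom_set` tibble: `x`, `y`, `z`, `ca_prob`, `aa_probs`
#'   (n x 20 matrix column), `cluster_size`.
#' @export
cluster_ca <- function(candidates, radius = 2) {
  if (radius <= 0) abort("`radius` must be > 0.")
  n <- nrow(candidates)
  if (n == 0L) {
    out <- tibble(x = numeric(), y = numeric(), z = numeric(),
                  ca_prob = numeric(), aa_probs = matrix(numeric(), 0, 20),
                  cluster_size = integer())
    class(out) <- c("ca_atom_set", class(out))
    return(out)
  }
  xyz <- as.matrix(candidates[, c("x", "y", "z")])
  # order-independent: work on a canonical ordering of the candidates
  ord <- order(xyz[, 1], xyz[, 2], xyz[, 3], candidates$ca_prob)
  xyz <- xyz[ord, , drop = FALSE]
  cand <- candidates[ord, ]
  d <- as.matrix(dist(xyz))
  adj <- d <= radius
  gr <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected", diag = FALSE)
  comp <- igraph::components(gr)$membership
  rows <- lapply(seq_len(max(comp)), function(k) {
    mem <- which(comp == k)
    if (length(mem) == 1L) {
      med <- mem
    } else {
      sumd <- rowSums(d[mem, mem, drop = FALSE])
      best <- which(abs(sumd - min(sumd)) < 1e-9)
      if (length(best) > 1L) {
        pr <- cand$ca_prob[mem[best]]
        best <- best[pr == max(pr)]
      }
      med <- mem[min(best)]
    }
    aam <- colMeans(cand$aa_probs[mem, , drop = FALSE])
    aam <- unname(aam / sum(aam))
    tibble(x = unname(xyz[med, 1]), y = unname(xyz[med, 2]), z = unname(xyz[med, 3]),
           ca_prob = mean(cand$ca_prob[mem]),
           aa_probs = matrix(aam, 1),
           cluster_size = length(mem))
  })
  out <- bind_rows(rows)
  out <- out[order(out$x, out$y, out$z), ]
  class(out) <- c("ca_atom_set", class(out))
  out
}

#' @export
print.ca_atom_set <- function(x, ...) {
  cat(sprintf("<ca_atom_set> %d atoms (from %d selected voxels)\n",
              nrow(x), sum(x$cluster_size)))
  NextMethod()
}

#' Extract clustered C-alpha atoms from prediction grids
#'
#' Convenience wrapper: [select_ca_voxels()] then [cluster_ca()].
#'
#' @inheritParams select_ca_voxels
#' @inheritParams cluster_ca
#' @return A `ca_atom_set` tibble.
#' @export
extract_ca_atoms <- function(preds, grid, threshold = 0.4, radius = 2) {
  cluster_ca(select_ca_voxels(preds, grid, threshold), radius)
}

#' Write extracted atoms as TSV
#'
#' Dumps coordinates, C-alpha probability, the top-scoring amino-acid type
#' and cluster size for inspection.
#'
#' @param atoms A `ca_atom_set`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ca_tsv <- function(atoms, path) {
  top <- AA_ALPHABET[max.col(atoms$aa_probs, ties.method = "first")]
  utils::write.table(
    data.frame(x = atoms$x, y = atoms$y, z = atoms$z,
               ca_prob = atoms$ca_prob, top_aa = top,
               cluster_size = atoms$cluster_size),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
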