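#' Pipeline configuration
#'
#' Collects every tunable of the map-to-model workflow with the method's
#' published defaults: C-alpha selection threshold 0.4, clustering radius
#' 2 Angstrom, transition model mu = 3.8047 Angstrom, sigma = 0.036
#' Angstrom, lambda = 10. Unknown keys are rejected.
#'
#' @param ... Overrides for: `ca_threshold`, `cluster_radius`, `mu`, `sigma`,
#'   `lambda`, `background_frequencies` ("default" or a 20-vector),
#'   `normalize` (min-max normalize the map), `tile_size`, `seed`.
#' @return A `pipeline_config` list.
#' @export
#' @examples
#' pipeline_config(ca_threshold = 0.5)$ca_threshold
pipeline_config <- function(...) {
  cfg <- list(ca_threshold = 0.4,
              cluster_radius = 2.0,
              mu = 3.8047,
              sigma = 0.036,
              lambda = 10,
              background_frequencies = "default",
              normalize = TRUE,
              tile_size = 32L,
              seed = 1L)
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown) > 0L) {
    abort(sprintf("unknown config key(s): %s.", paste(unknown, collapse = ", ")))
  }
  cfg[names(over)] <- over
  structure(cfg, class = "pipeline_config")
}

config_background <- function(cfg) {
  b <- cfg$background_frequencies
  if (identical(b, "default")) return(aa_background())
  if (is.character(b)) {
    b <- as.numeric(utils::read.table(b)[[1]])
  }
  as.numeric(b)
}

#' Run the full map-to-model pipeline
#'
#' Executes the workflow end to end: read (or accept) the density map and
#' chain sequences, predict per-voxel class probabilities (networks,
#' surrogate function, or precomputed grids), select and cluster C-alpha
#' voxels, build the HMM, align every chain with the no-repeat Viterbi
#' decoder, assemble the backbone model, optionally score confidences, and
#' optionally write a PDB. Deterministic given inputs, config and seed.
#'
#' @param map A [density_grid()] or path to an MRC/CCP4 file.
#' @param sequences A [chain_sequence_set()] or path to a FASTA file.
#' @param source Prediction source for [predict_grids()]: trained networks,
#'   a surrogate function, or a [prediction_grids()].
#' @param config A [pipeline_config()].
#' @param confidence Optional `list(ca =, aa =)` of [logistic_model()]s.
#' @param pdb_out Optional output PDB path.
#' @return A `voxtrace_run` list: `model` ([structure_model()]), `atoms`,
#'   `hmm`, `alignments`, and `manifest` (config, stage timings in seconds,
#'   stage counts).
#' @export
run_pipeline <- function(map, sequences, source, config = pipeline_config(),
                         confidence = NULL, pdb_out = NULL) {
  if (!inherits(config, "pipeline_config")) abort("`config` must be a pipeline_config().")
  set.seed(config$seed)
  timings <- c()
  tic <- function() Sys.time()
  lap <- function(t0) as.numeric(difftime(Sys.time(), t0, units = "secs"))

  t0 <- tic()
  grid <- if (is.character(map)) read_density_map(map) else map
  chains <- if (is.character(sequences)) read_fasta(sequences) else sequences
  if (!inherits(grid, "density_grid")) abort("stage read: `map` is not a density grid.")
  if (!inherits(chains, "chain_sequence_set")) abort("stage read: `sequences` is not a chain set.")
  timings["read"] <- lap(t0)

  t0 <- tic()
  preds <- predict_grids(source, grid, normalize = config$normalize)
  timings["predict"] <- lap(t0)

  t0 <- tic()
  candidates <- select_ca_voxels(preds, grid, config$ca_threshold)
  atoms <- cluster_ca(candidates, config$cluster_radius)
  timings["cluster"] <- lap(t0)
  if (nrow(atoms) < sum(chains$length)) {
    abort(sprintf(paste0("stage align: infeasible alignment — %d predicted C-alpha states ",
                         "for %d residues; lower `ca_threshold` (currently %g)."),
                  nrow(atoms), sum(chains$length), config$ca_threshold))
  }

  t0 <- tic()
  hmm <- build_hmm(atoms, mu = config$mu, sigma = config$sigma,
                   lambda = config$lambda, background = config_background(config))
  alignments <- align_all_chains(hmm, chains)
  model <- paths_to_structure(alignments, atoms, chains)
  timings["align"] <- lap(t0)

  if (!is.null(confidence)) {
    t0 <- tic()
    model <- apply_confidence(model, confidence$ca, confidence$aa)
    timings["confidence"] <- lap(t0)
  }
  if (!is.null(pdb_out)) {
    write_pdb(model, pdb_out)
  }
  manifest <- list(
    config = unclass(config),
    timings = as.list(timings),
    counts = list(candidate_voxels = nrow(candidates),
                  clustered_atoms = nrow(atoms),
                  hmm_states = nrow(atoms),
                  chains = nrow(chains),
                  residues_aligned = nrow(model)))
  structure(list(model = model, atoms = atoms, hmm = hmm,
                 alignments = alignments, manifest = manifest),
            class = "voxtrace_run")
}

#' @export
print.voxtrace_run <- function(x, ...) {
  cnt <- x$manifest$counts
  cat(sprintf(paste0("<voxtrace_run> %d candidate voxels -> %d atoms -> ",
                     "%d residues aligned over %d chain(s)\n"),
              cnt$candidate_voxels, cnt$clustered_atoms,
              cnt$residues_aligned, cnt$chains))
  invisible(x)
}

#' Write a run manifest as JSON
#'
#' @param run A `voxtrace_run`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(run, path) {
  man <- run$manifest
  man$config$background_frequencies <-
    if (is.character(man$config$background_frequencies)) {
      man$config$background_frequencies
    } else {
      as.numeric(man$config$background_frequencies)
    }
  jsonlite::write_json(man, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Glance at a pipeline run
#'
#' @param x A `voxtrace_run`.
#' @param ... Unused.
#' @return One-row tibble of stage counts and total wall time.
#' @export
glance.voxtrace_run <- function(x, ...) {
  cnt <- x$manifest$counts
  tibble(candidate_voxels = cnt$candidate_voxels,
         clustered_atoms = cnt$clustered_atoms,
         chains = cnt$chains,
         residues_aligned = cnt$residues_aligned,
         seconds = sum(unlist(x$manifest$timings)))
}
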