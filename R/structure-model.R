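#' Construct a backbone structure model
#'
#' A C-alpha-only model: one row per residue, ordered within chains. The
#' confidence columns hold per-residue probabilities in `[0, 1]` (1 when no
#' confidence model has been applied).
#'
#' @param residues A data frame with columns `chain_id`, `resno`, `x`, `y`,
#'   `z`, `aa` (one-letter code) and optionally `ca_conf`, `aa_conf`,
#'   `ca_prob`, `emission_prob`, `atom_index`.
#' @return A tibble of class `structure_model`.
#' @export
structure_model <- function(residues) {
  residues <- as_tibble(residues)
  needed <- c("chain_id", "resno", "x", "y", "z", "aa")
  missing_cols <- setdiff(needed, names(residues))
  if (length(missing_cols) > 0L) {
    abort(sprintf("missing residue columns: %s.", paste(missing_cols, collapse = ", ")))
  }
  if (!"ca_conf" %in% names(residues)) residues$ca_conf <- 1
  if (!"aa_conf" %in% names(residues)) residues$aa_conf <- 1
  class(residues) <- c("structure_model", class(residues))
  residues
}

#' @export
print.structure_model <- function(x, ...) {
  cat(sprintf("<structure_model> %d residues in %d chain(s)\n",
              nrow(x), length(unique(x$chain_id))))
  NextMethod()
}

chain_id_pool <- c(LETTERS, letters, as.character(0:9))

#' Write a C-alpha model as PDB
#'
#' One `ATOM` record per residue (atom name `CA`), serial and residue numbers
#' sequential per chain. The B-factor column carries the amino-acid confidence
#' scaled to `[0, 100]`; occupancy carries the C-alpha confidence.
#'
#' @param model A [structure_model()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_pdb <- function(model, path) {
  chains <- unique(model$chain_id)
  if (length(chains) > length(chain_id_pool)) {
    abort(sprintf("PDB chain ids exhausted: %d chains exceed the %d available ids.",
                  length(chains), length(chain_id_pool)))
  }
  ids <- chain_id_pool[seq_along(chains)]
  aa3 <- bio3d::aa123(model$aa)
  ch <- ids[match(model$chain_id, chains)]
  resno <- stats::ave(seq_len(nrow(model)), model$chain_id, FUN = seq_along)
  bio3d::write.pdb(file = path,
                   xyz = as.numeric(t(as.matrix(model[, c("x", "y", "z")]))),
                   type = rep("ATOM", nrow(model)),
                   resno = resno,
                   resid = aa3,
                   eleno = seq_len(nrow(model)),
                   elety = rep("CA", nrow(model)),
                   chain = ch,
                   o = round(model$ca_conf, 2),
                   b = round(100 * model$aa_conf, 2))
  invisible(path)
}

#' Read a reference structure (PDB), keeping C-alpha atoms only
#'
#' Alternate locations are resolved to the highest-occupancy conformer; chain
#' order is preserved as encountered in the file.
#'
#' @param path Path to a PDB file.
#' @return A [structure_model()].
#' @export
read_reference_pdb <- function(path) {
  pdb <- bio3d::read.pdb(path)
  at <- pdb$atom
  at <- at[at$elety == "CA" & at$type == "ATOM", , drop = FALSE]
  if (nrow(at) == 0L) abort(sprintf("no C-alpha atoms in '%s'.", path))
  at$o[is.na(at$o)] <- 1
  key <- paste(at$chain, at$resno, at$insert)
  keep <- unlist(lapply(split(seq_len(nrow(at)), factor(key, levels = unique(key))),
                        function(i) i[which.max(at$o[i])]),
                 use.names = FALSE)
  at <- at[sort(keep), , drop = FALSE]
  aa1 <- bio3d::aa321(at$resid)
  ok <- aa1 %in% AA_ALPHABET
  at <- at[ok, , drop = FALSE]
  aa1 <- aa1[ok]
  if (nrow(at) == 0L) abort(sprintf("no standard-residue C-alpha atoms in '%s'.", path))
  structure_model(tibble(chain_id = as.character(at$chain),
                         resno = at$resno,
                         x = at$x, y = at$y, z = at$z,
                         aa = aa1,
                         ca_conf = at$o,
                         aa_conf = at$b / 100))
}
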