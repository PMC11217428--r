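#' Align one chain sequence to the HMM with the no-repeat Viterbi decoder
#'
#' A customized Viterbi decoder in which a hidden state (predicted C-alpha
#' atom) may occur at most once in the decoded path. The dynamic program runs
#' in natural-log space. At each observation column `j >= 2`, scores are
#' updated only for states not yet committed:
#' `T1[i, j] = max_k (T1[k, j-1] + log gamma[k, i]) + log delta[i, O_j]`,
#' where committed states are frozen at `-Inf` (so they are unavailable as
#' update targets, and drop out as predecessors one column later, while the
#' most recently committed state remains the natural predecessor of the
#' current column). After each column the column argmax `z_j` is committed;
#' the first path state `x_1 = T2[z_2, 2]` is committed as soon as it is
#' known. The returned path is `x_1, z_2, ..., z_T`, which is repeat-free by
#' construction. Ties are broken toward the lowest state index.
#'
#' @param hmm A [build_hmm()] model.
#' @param sequence Amino-acid string (or integer indices in 1..20).
#' @param available Optional integer vector of usable state indices
#'   (default: all states). Must contain at least as many states as the
#'   sequence has residues.
#' @param chain_id Identifier recorded in the result.
#' @return A `ca_alignment` list: `chain_id`, `path` (state indices into
#'   `hmm$atoms`, one per residue), `log_prob` (joint log-probability of the
#'   decoded path), `emission_prob` (per-position emission probability used),
#'   `T1`, `T2` (dynamic-programming tables over the available-state subset),
#'   and `available` (the subset the tables refer to).
#' @export
modified_viterbi <- function(hmm, sequence, available = NULL, chain_id = "A") {
  obs <- if (is.character(sequence)) seq_to_indices(sequence) else as.integer(sequence)
  Tn <- length(obs)
  K_all <- nrow(hmm$delta)
  avail <- sort(as.integer(available %||% seq_len(K_all)))
  k <- length(avail)
  if (k < Tn) {
    abort(sprintf(paste0("infeasible alignment: %d available states for %d residues; ",
                         "lower the C-alpha probability threshold to admit more states."),
                  k, Tn))
  }
  ldelta <- log(hmm$delta[avail, , drop = FALSE])
  if (k > 1L) {
    lgam <- hmm$log_gamma[avail, avail, drop = FALSE]
    rowls <- apply(lgam, 1L, logsumexp)         # renormalize over survivors
    fin <- is.finite(rowls)
    lgam[fin, ] <- lgam[fin, , drop = FALSE] - rowls[fin]
    lgam[!fin, ] <- -Inf
  } else {
    lgam <- matrix(-Inf, 1L, 1L)
  }
  pi0 <- build_initial(hmm$delta[avail, , drop = FALSE], obs[1])
  T1 <- matrix(-Inf, k, Tn)
  T2 <- matrix(0L, k, Tn)
  T1[, 1] <- log(pi0) + ldelta[, obs[1]]
  visited <- logical(k)
  z <- integer(Tn)
  x1 <- NA_integer_
  if (Tn >= 2L) {
    for (j in 2:Tn) {
      prev <- T1[, j - 1]
      scores <- prev + lgam                     # scores[k', i]
      best <- apply(scores, 2L, max)
      arg <- max.col(t(scores), ties.method = "first")
      # deterministic fallback when a column is all -Inf: smallest usable index
      dead <- !is.finite(best)
      if (any(dead)) {
        for (i in which(dead)) {
          cand <- which(!visited & seq_len(k) != i)
          arg[i] <- if (length(cand) > 0L) cand[1] else i
        }
      }
      col <- best + ldelta[, obs[j]]
      col[visited] <- -Inf
      T1[, j] <- col
      T2[, j] <- arg
      zj <- pick_argmax(col, visited)
      z[j] <- zj
      visited[zj] <- TRUE
      if (j == 2L) {
        x1 <- T2[zj, 2L]
        if (visited[x1]) {                      # only possible via fallback paths
          x1 <- which(!visited)[1]
        }
        visited[x1] <- TRUE
      }
    }
    path_sub <- c(x1, z[2:Tn])
  } else {
    path_sub <- pick_argmax(T1[, 1], visited)
  }
  stopifnot(!anyDuplicated(path_sub))
  lp <- log(pi0[path_sub[1]]) + ldelta[path_sub[1], obs[1]]
  if (Tn >= 2L) {
    for (j in 2:Tn) {
      lp <- lp + lgam[path_sub[j - 1], path_sub[j]] + ldelta[path_sub[j], obs[j]]
    }
  }
  structure(list(chain_id = chain_id,
                 path = avail[path_sub],
                 log_prob = lp,
                 emission_prob = hmm$delta[cbind(avail[path_sub], obs)],
                 observations = obs,
                 T1 = T1, T2 = T2,
                 available = avail,
                 visited_states = avail[sort(path_sub)]),
            class = "ca_alignment")
}

pick_argmax <- function(col, visited) {
  ok <- which(!visited)
  if (length(ok) == 0L) abort("no unvisited states remain.")
  best <- ok[which.max(col[ok])]
  if (!is.finite(col[best])) ok[1] else best
}

#' @export
print.ca_alignment <- function(x, ...) {
  cat(sprintf("<ca_alignment> chain %s: %d residues, log-probability %.2f\n",
              x$chain_id, length(x$path), x$log_prob))
  invisible(x)
}

#' Align all chains of a protein to the HMM
#'
#' Chains are aligned one by one in descending sequence-length order (ties by
#' input order). After each chain is aligned, the states in its path are
#' removed from the HMM (surviving transition rows and the initial
#' distribution are renormalized) before the next chain is aligned, so no
#' state is used twice across chains.
#'
#' @param hmm A [build_hmm()] model.
#' @param chains A [chain_sequence_set()].
#' @return List of `ca_alignment` results, in the input chain order.
#' @export
align_all_chains <- function(hmm, chains) {
  K <- nrow(hmm$delta)
  if (sum(chains$length) > K) {
    abort(sprintf(paste0("infeasible alignment: %d hidden states for %d total residues; ",
                         "lower the C-alpha probability threshold to admit more states."),
                  K, sum(chains$length)))
  }
  ord <- order(-chains$length, seq_len(nrow(chains)))
  avail <- seq_len(K)
  results <- vector("list", nrow(chains))
  for (ci in ord) {
    res <- tryCatch(
      modified_viterbi(hmm, chains$sequence[ci], avail, chains$chain_id[ci]),
      error = function(e) {
        abort(sprintf("alignment failed at chain '%s': %s",
                      chains$chain_id[ci], conditionMessage(e)))
      })
    results[[ci]] <- res
    avail <- setdiff(avail, res$path)
  }
  all_states <- unlist(lapply(results, `[[`, "path"))
  stopifnot(!anyDuplicated(all_states))
  results
}

#' Assemble aligned paths into a backbone structure model
#'
#' Residue j of each chain receives the coordinate of the atom its path
#' visits at position j and the chain's j-th amino acid; the per-position
#' emission probability and the atom's C-alpha probability are retained for
#' confidence scoring.
#'
#' @param results List of `ca_alignment` (from [align_all_chains()]).
#' @param atoms The `ca_atom_set` the HMM was built over.
#' @param chains The [chain_sequence_set()] that was aligned.
#' @return A [structure_model()] with extra columns `ca_prob`,
#'   `emission_prob`, `atom_index`.
#' @export
paths_to_structure <- function(results, atoms, chains) {
  rows <- lapply(seq_len(nrow(chains)), function(ci) {
    res <- results[[ci]]
    letters_i <- strsplit(chains$sequence[ci], "")[[1]]
    if (length(res$path) != length(letters_i)) {
      abort(sprintf("path length %d does not match chain '%s' length %d.",
                    length(res$path), chains$chain_id[ci], length(letters_i)))
    }
    tibble(chain_id = chains$chain_id[ci],
           resno = seq_along(letters_i),
           x = atoms$x[res$path], y = atoms$y[res$path], z = atoms$z[res$path],
           aa = letters_i,
           ca_prob = atoms$ca_prob[res$path],
           emission_prob = res$emission_prob,
           atom_index = res$path)
  })
  structure_model(bind_rows(rows))
}
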