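# Shared fixtures and independent brute-force oracles.

# quiet wrapper: OpenBabel chatters on stderr for some conversions
quietly <- function(expr) suppressWarnings(suppressMessages(expr))

mk_block <- function(smiles, id, aps = 1L) {
  building_block(parse_molecule(smiles, id), aps)
}

# three structurally distinct single-attachment blocks whose pairwise
# products stay below the 0.95 dedupe threshold
distinct_trio <- function() {
  list(mk_block("Cc1ccccc1", "00000001"),
       mk_block("NCCCCO", "00000002"),
       mk_block("Cc1cccs1", "00000003"))
}

# Brute-force enumeration oracle: nested loops over unordered block pairs
# and attachment-point pairs within the heavy-atom budget, assembling via
# couple_blocks, then an exhaustive-pairwise greedy dedupe using the scalar
# tanimoto() on individually computed fingerprints.
oracle_enumerate <- function(scaffold, blocks, budget = 18L, threshold = 0.95) {
  prods <- list()
  nb <- length(blocks)
  for (i in seq_len(nb)) {
    for (j in i:nb) {
      h <- heavy_atom_count(blocks[[i]]$mol) + heavy_atom_count(blocks[[j]]$mol)
      if (h > budget) next
      aps_i <- blocks[[i]]$attachment_atoms
      aps_j <- blocks[[j]]$attachment_atoms
      comb <- 0L
      for (a in seq_along(aps_i)) {
        bstart <- if (i == j) a else 1L
        for (b in bstart:length(aps_j)) {
          prods[[length(prods) + 1L]] <- couple_blocks(
            scaffold, blocks[[i]], aps_i[a], blocks[[j]], aps_j[b],
            combination = comb, budget = budget)
          comb <- comb + 1L
        }
      }
    }
  }
  kept <- list()
  for (p in prods) {
    fp <- fingerprint(p$mol)
    dup <- FALSE
    for (k in kept) {
      if (tanimoto(fp, fingerprint(k$mol)) >= threshold) { dup <- TRUE; break }
    }
    if (!dup) kept[[length(kept) + 1L]] <- p
  }
  kept
}

# Exhaustive greedy-leader dedupe oracle on a list of molecules/blocks.
oracle_dedupe <- function(items, threshold) {
  mols <- lapply(items, function(x) if (inherits(x, "oxa_block")) x$mol else x)
  fps <- lapply(mols, fingerprint)
  keep <- integer()
  for (i in seq_along(items)) {
    dup <- any(vapply(keep, function(k) {
      tanimoto(fps[[i]], fps[[k]]) >= threshold
    }, TRUE))
    if (!dup) keep <- c(keep, i)
  }
  items[keep]
}

# Exhaustive greedy-leader clustering oracle (join first leader at >= t).
oracle_cluster <- function(items, threshold) {
  mols <- lapply(items, function(x) if (inherits(x, "oxa_block")) x$mol else x)
  fps <- lapply(mols, fingerprint)
  leaders <- integer()
  assign <- integer(length(items))
  for (i in seq_along(items)) {
    hit <- 0L
    for (li in seq_along(leaders)) {
      if (tanimoto(fps[[i]], fps[[leaders[li]]]) >= threshold) { hit <- li; break }
    }
    if (hit) assign[i] <- hit else {
      leaders <- c(leaders, i)
      assign[i] <- length(leaders)
    }
  }
  assign
}

# Build a single-isoform docking-record table from a named score vector.
toy_records <- function(scores, isoform = "Ec",
                        score_name = "affinity") {
  n <- length(scores)
  df <- data.frame(compound_id = names(scores), isoform = isoform,
                   anchor_rmsd = 1.0, affinity = 0, fitness = 0.5,
                   binding = 0.5, energy = 0)
  df[[score_name]] <- unname(scores)
  df
}

# SUM-rule fusion oracle: plain sum of per-list average ranks, ordered by
# (sum, id).
oracle_fuse <- function(score_lists, lower_better) {
  ids <- names(score_lists[[1]])
  sums <- setNames(numeric(length(ids)), ids)
  for (k in seq_along(score_lists)) {
    v <- score_lists[[k]][ids]
    r <- rank(if (lower_better[k]) v else -v, ties.method = "average")
    sums <- sums + r
  }
  ids[order(sums, ids)]
}
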