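# Combinatorial assembly of amino-oxazole derivatives from building blocks.
#
# Both R-groups are coupled to the amide nitrogen of the
# 2-amino-oxazole-5-carboxamide scaffold, so a block pair is unordered:
# (b1, b2) and (b2, b1) give the same molecule and canonicalization (plus the
# final similarity dedupe) removes coincident products.

#' The 2-amino-oxazole-5-carboxamide scaffold
#'
#' The fixed core of every library compound. Its amide nitrogen (two
#' hydrogens before substitution) is the single coupling atom at which both
#' substituents R1 and R2 are attached.
#'
#' @return An `oxa_scaffold`: list with `mol` (an `oxa_mol`), `coupling_atom`
#'   (atom index of the amide nitrogen) and `arity` (2).
#' @examples
#' sc <- oxazole_scaffold()
#' heavy_atom_count(sc$mol)  # 9
#' @export
oxazole_scaffold <- function() {
  mol <- parse_molecule("NC(=O)c1cnc(N)o1", "ao")
  at <- mol$atoms; bd <- mol$bonds
  carbonyl_c <- unique(c(
    bd$a1[bd$order == 2 & at$element[bd$a1] == "C" & at$element[bd$a2] == "O"],
    bd$a2[bd$order == 2 & at$element[bd$a2] == "C" & at$element[bd$a1] == "O"]
  ))
  amide_n <- which(vapply(seq_len(nrow(at)), function(i) {
    if (at$element[i] != "N" || at$n_h[i] < 2L) return(FALSE)
    nb <- c(bd$a2[bd$a1 == i], bd$a1[bd$a2 == i])
    any(nb %in% carbonyl_c)
  }, TRUE))
  stopifnot(length(amide_n) == 1L)
  structure(list(mol = mol, coupling_atom = amide_n, arity = 2L),
            class = "oxa_scaffold")
}

#' Declare a molecule as a building block
#'
#' @param mol An `oxa_mol`.
#' @param attachment_atoms Atom indices eligible for coupling; defaults to
#'   every C/N/O/S atom bearing at least one hydrogen ([attachment_points()]).
#' @return An `oxa_block`: list with `id`, `mol`, `attachment_atoms`.
#' @export
building_block <- function(mol, attachment_atoms = NULL) {
  stopifnot(inherits(mol, "oxa_mol"))
  valid <- attachment_points(mol)
  if (is.null(attachment_atoms)) {
    attachment_atoms <- valid
  } else if (!all(attachment_atoms %in% valid)) {
    stop(sprintf("block %s: attachment atom(s) %s are not hydrogenated C/N/O/S",
                 mol$id,
                 paste(setdiff(attachment_atoms, valid), collapse = ", ")))
  }
  structure(list(id = mol$id, mol = mol, attachment_atoms = as.integer(attachment_atoms)),
            class = "oxa_block")
}

#' @export
print.oxa_block <- function(x, ...) {
  cat(sprintf("<oxa_block %s> %s (%d heavy atoms, %d attachment points)\n",
              x$id, x$mol$smiles, heavy_atom_count(x$mol),
              length(x$attachment_atoms)))
  invisible(x)
}

#' Coupling-eligible atoms of a molecule
#'
#' A block can be coupled to the scaffold's amide nitrogen through any
#' hydrogenated carbon, nitrogen, oxygen or sulfur atom.
#'
#' @param mol An `oxa_mol` (or `oxa_block`).
#' @return Integer atom indices in canonical atom order.
#' @export
attachment_points <- function(mol) {
  if (inherits(mol, "oxa_block")) return(mol$attachment_atoms)
  stopifnot(inherits(mol, "oxa_mol"))
  which(mol$atoms$element %in% c("C", "N", "O", "S") & mol$atoms$n_h >= 1L)
}

#' Retain building blocks by heavy-atom count
#'
#' @param blocks List of `oxa_block` objects.
#' @param min_heavy,max_heavy Inclusive bounds (default 6-12).
#' @return The retained blocks, input order preserved.
#' @export
filter_blocks <- function(blocks, min_heavy = 6L, max_heavy = 12L) {
  keep <- vapply(blocks, function(b) {
    h <- heavy_atom_count(b$mol)
    h >= min_heavy && h <= max_heavy
  }, TRUE)
  blocks[keep]
}

#' Remove redundant molecules at a Tanimoto threshold
#'
#' Greedy leader pass in input order: an item is kept iff its Tanimoto
#' similarity to every previously kept item is strictly below `threshold`.
#' The kept set is therefore pairwise sub-threshold and the operation is
#' idempotent.
#'
#' @param items List of `oxa_block` or `oxa_mol` objects.
#' @param threshold Similarity threshold (default 0.95).
#' @return The kept items, input order preserved.
#' @export
dedupe_by_similarity <- function(items, threshold = 0.95) {
  if (!length(items)) return(items)
  mols <- lapply(items, function(x) if (inherits(x, "oxa_block")) x$mol else x)
  fps <- fingerprint_matrix(mols)
  keep <- .leader_keep(fps, threshold)
  items[keep]
}

# Indices kept by a greedy leader pass over fingerprint rows.
.leader_keep <- function(fps, threshold) {
  n <- nrow(fps)
  keep <- logical(n)
  kept_rows <- NULL
  for (i in seq_len(n)) {
    if (is.null(kept_rows)) {
      keep[i] <- TRUE
      kept_rows <- fps[i, , drop = FALSE]
    } else {
      sims <- .tanimoto_rows(fps[i, ], kept_rows)
      if (all(sims < threshold)) {
        keep[i] <- TRUE
        kept_rows <- rbind(kept_rows, fps[i, ])
      }
    }
  }
  which(keep)
}

# Insert a ring-closure label after the k-th atom token of a SMILES string,
# consuming one hydrogen if the token is a bracket atom with explicit H.
.smiles_attach_label <- function(smiles, tokens, atom_idx, label) {
  tok <- tokens[atom_idx, ]
  before <- substring(smiles, 1, tok$end)
  after <- if (tok$end < nchar(smiles)) substring(smiles, tok$end + 1L) else ""
  if (tok$bracket) {
    body <- substring(smiles, tok$start, tok$end)
    newbody <- sub("H3", "H2", body, fixed = TRUE)
    if (identical(newbody, body)) newbody <- sub("H2", "H", body, fixed = TRUE)
    if (identical(newbody, body)) newbody <- sub("H", "", body, fixed = TRUE)
    # a bare neutral atom needs no bracket at all
    if (grepl("^\\[[A-Za-z][a-z]?\\]$", newbody)) {
      newbody <- substring(newbody, 2, nchar(newbody) - 1L)
    }
    before <- paste0(substring(smiles, 1, tok$start - 1L), newbody)
  }
  paste0(before, label, after)
}

# Splice attachment labels into a block's canonical SMILES.
.block_labelled_smiles <- function(block, atom_idx, label) {
  tokens <- .smiles_atom_tokens(block$mol$smiles)
  .smiles_attach_label(block$mol$smiles, tokens, atom_idx, label)
}

#' Couple two building blocks to the scaffold
#'
#' Attaches `b1` (through its atom `ap1`) and `b2` (through `ap2`) to the
#' scaffold's amide nitrogen, forming the tertiary carboxamide. The combined
#' R-group size is limited to `budget` heavy atoms.
#'
#' @param scaffold An `oxa_scaffold`.
#' @param b1,b2 `oxa_block` objects (R1 and R2).
#' @param ap1,ap2 Attachment atom indices within each block.
#' @param combination Zero-based combination number distinguishing
#'   attachment-isomer variants of the same block pair.
#' @param budget Maximum combined heavy atoms of the two blocks (default 18).
#' @return An `oxa_compound`: list with `identifier`, `r1`, `r2`,
#'   `combination`, and the assembled `mol`.
#' @export
couple_blocks <- function(scaffold, b1, ap1, b2, ap2, combination = 0L,
                          budget = 18L) {
  stopifnot(inherits(scaffold, "oxa_scaffold"),
            inherits(b1, "oxa_block"), inherits(b2, "oxa_block"))
  h1 <- heavy_atom_count(b1$mol); h2 <- heavy_atom_count(b2$mol)
  if (h1 + h2 > budget) {
    stop(sprintf("R-group budget exceeded: %d + %d > %d heavy atoms",
                 h1, h2, budget))
  }
  if (!(ap1 %in% b1$attachment_atoms)) {
    stop(sprintf("atom %d is not an attachment point of block %s", ap1, b1$id))
  }
  if (!(ap2 %in% b2$attachment_atoms)) {
    stop(sprintf("atom %d is not an attachment point of block %s", ap2, b2$id))
  }
  smi <- .assembled_smiles(scaffold, b1, ap1, b2, ap2)
  ident <- .format_identifier(b1$id, b2$id, combination)
  mol <- parse_molecule(smi, ident)
  structure(list(identifier = ident,
                 r1 = list(block_id = b1$id, atom = as.integer(ap1)),
                 r2 = list(block_id = b2$id, atom = as.integer(ap2)),
                 combination = as.integer(combination),
                 mol = mol),
            class = "oxa_compound")
}

#' @export
print.oxa_compound <- function(x, ...) {
  cat(sprintf("<oxa_compound %s> %s\n", x$identifier, x$mol$smiles))
  invisible(x)
}

# Raw (un-canonicalized) SMILES of scaffold + two labelled blocks, joined by
# ring-closure bonds %91 and %92 across dot-separated components.
.assembled_smiles <- function(scaffold, b1, ap1, b2, ap2) {
  sc_tokens <- .smiles_atom_tokens(scaffold$mol$smiles)
  sc <- .smiles_attach_label(scaffold$mol$smiles, sc_tokens,
                             scaffold$coupling_atom, "%91")
  sc_tokens2 <- .smiles_atom_tokens(sc)
  sc <- .smiles_attach_label(sc, sc_tokens2, scaffold$coupling_atom, "%92")
  paste(sc,
        .block_labelled_smiles(b1, ap1, "%91"),
        .block_labelled_smiles(b2, ap2, "%92"),
        sep = ".")
}

.format_identifier <- function(id1, id2, combination) {
  sprintf("ao-%s-%s-%04d", .block_code(id1), .block_code(id2),
          as.integer(combination))
}

# Numeric suffix of a block id (ZINC-style), or the id itself if none.
.block_code <- function(id) {
  m <- regmatches(id, regexpr("[0-9]+$", id))
  if (length(m) && nzchar(m)) m else id
}

#' Compound identifier in the `ao-R1-R2-combination` scheme
#'
#' @param compound An `oxa_compound`.
#' @return Text identifier `ao-<R1 id>-<R2 id>-<zero-padded combination>`.
#' @export
compound_identifier <- function(compound) {
  stopifnot(inherits(compound, "oxa_compound"))
  compound$identifier
}

#' Parse a compound identifier back into its components
#'
#' Accepts 3- or 4-digit (or longer) combination fields.
#'
#' @param text Identifier such as `"ao-02168779-40448781-0000"`.
#' @return A list with `r1`, `r2` (block codes) and `combination` (integer).
#' @export
parse_compound_identifier <- function(text) {
  stopifnot(length(text) == 1L)
  p <- strsplit(text, "-", fixed = TRUE)[[1]]
  if (length(p) != 4L || p[1] != "ao" || !grepl("^[0-9]{3,}$", p[4])) {
    stop(sprintf("unparsable compound identifier: %s", text))
  }
  list(r1 = p[2], r2 = p[3], combination = as.integer(p[4]))
}

# Vectorized split of identifiers into r1/r2 codes (used by enrichment).
.split_identifiers <- function(ids) {
  parts <- strsplit(ids, "-", fixed = TRUE)
  bad <- vapply(parts, function(p) length(p) != 4L || p[1] != "ao", TRUE)
  if (any(bad)) {
    stop(sprintf("unparsable compound identifier(s): %s",
                 paste(utils::head(ids[bad], 3), collapse = ", ")))
  }
  data.frame(compound_id = ids,
             r1 = vapply(parts, `[[`, "", 2),
             r2 = vapply(parts, `[[`, "", 3),
             combination = as.integer(vapply(parts, `[[`, "", 4)))
}

# Table of unordered block-pair / attachment-point combinations within the
# heavy-atom budget, in deterministic enumeration order, with zero-based
# combination numbers per block pair.
.combination_table <- function(blocks, budget) {
  heavies <- vapply(blocks, function(b) heavy_atom_count(b$mol), 0L)
  rows <- list()
  nb <- length(blocks)
  for (i in seq_len(nb)) {
    for (j in i:nb) {
      if (heavies[i] + heavies[j] > budget) next
      aps_i <- blocks[[i]]$attachment_atoms
      aps_j <- blocks[[j]]$attachment_atoms
      comb <- 0L
      for (a in seq_along(aps_i)) {
        bstart <- if (i == j) a else 1L
        for (b in bstart:length(aps_j)) {
          rows[[length(rows) + 1L]] <-
            c(i = i, j = j, ap1 = aps_i[a], ap2 = aps_j[b], comb = comb)
          comb <- comb + 1L
        }
      }
    }
  }
  if (!length(rows)) {
    return(data.frame(i = integer(), j = integer(), ap1 = integer(),
                      ap2 = integer(), comb = integer()))
  }
  as.data.frame(do.call(rbind, rows))
}

#' Stream of assembled library compounds
#'
#' Returns an iterator over the deduplicated combinatorial library so that
#' downstream consumers (notably reservoir sampling) never materialize the
#' whole library. Compounds are emitted in deterministic enumeration order:
#' unordered block pairs in input order, attachment-point pairs within each
#' pair, with a greedy leader similarity dedupe applied to assembled products
#' along the stream.
#'
#' @param scaffold An `oxa_scaffold`.
#' @param blocks List of `oxa_block` objects (already deduplicated).
#' @param budget Combined R-group heavy-atom budget (default 18).
#' @param dedupe_threshold Tanimoto threshold for product dedupe (default
#'   0.95).
#' @return A function; each call returns the next `oxa_compound`, or `NULL`
#'   when the stream is exhausted.
#' @export
library_stream <- function(scaffold, blocks, budget = 18L,
                           dedupe_threshold = 0.95) {
  stopifnot(inherits(scaffold, "oxa_scaffold"))
  combos <- .combination_table(blocks, budget)
  pair_key <- if (nrow(combos)) paste(combos$i, combos$j) else character()
  pair_groups <- if (nrow(combos)) split(seq_len(nrow(combos)), factor(pair_key, levels = unique(pair_key))) else list()
  gi <- 0L
  buffer <- list()
  kept_fps <- NULL
  nextone <- function() {
    while (!length(buffer) && gi < length(pair_groups)) {
      gi <<- gi + 1L
      idx <- pair_groups[[gi]]
      chunk <- combos[idx, , drop = FALSE]
      raw <- character(nrow(chunk))
      idents <- character(nrow(chunk))
      for (r in seq_len(nrow(chunk))) {
        b1 <- blocks[[chunk$i[r]]]; b2 <- blocks[[chunk$j[r]]]
        raw[r] <- .assembled_smiles(scaffold, b1, chunk$ap1[r], b2, chunk$ap2[r])
        idents[r] <- .format_identifier(b1$id, b2$id, chunk$comb[r])
      }
      canon <- .ob_canonical(raw, idents)
      mols <- parse_molecules(canon, idents)
      fps <- fingerprint_matrix(mols)
      for (r in seq_len(nrow(chunk))) {
        sims <- if (is.null(kept_fps)) numeric() else .tanimoto_rows(fps[r, ], kept_fps)
        if (all(sims < dedupe_threshold)) {
          kept_fps <<- rbind(kept_fps, fps[r, , drop = FALSE])
          b1 <- blocks[[chunk$i[r]]]; b2 <- blocks[[chunk$j[r]]]
          buffer[[length(buffer) + 1L]] <<- structure(
            list(identifier = idents[r],
                 r1 = list(block_id = b1$id, atom = chunk$ap1[r]),
                 r2 = list(block_id = b2$id, atom = chunk$ap2[r]),
                 combination = chunk$comb[r],
                 mol = mols[[r]]),
            class = "oxa_compound")
        }
      }
    }
    if (!length(buffer)) return(NULL)
    out <- buffer[[1L]]
    buffer[[1L]] <<- NULL
    out
  }
  nextone
}

#' Enumerate the full combinatorial library
#'
#' Materializes [library_stream()]; intended for small block sets (tests,
#' worked examples). The emitted count equals brute-force nested-loop
#' enumeration followed by similarity dedupe.
#'
#' @inheritParams library_stream
#' @return List of `oxa_compound` objects in deterministic order.
#' @export
enumerate_library <- function(scaffold, blocks, budget = 18L,
                              dedupe_threshold = 0.95) {
  it <- library_stream(scaffold, blocks, budget, dedupe_threshold)
  out <- list()
  while (!is.null(cmp <- it())) out[[length(out) + 1L]] <- cmp
  out
}

#' Uniform sample of library compounds without replacement
#'
#' Reservoir sampling (Algorithm R) over a compound stream, so the library
#' need not be materialized. The same seed always yields the same sample.
#' The sample is returned in stream order.
#'
#' @param stream Either an iterator from [library_stream()] or a list of
#'   `oxa_compound` objects.
#' @param n Sample size.
#' @param seed Integer seed.
#' @return List of `n` `oxa_compound` objects.
#' @export
sample_library <- function(stream, n, seed) {
  nextone <- if (is.function(stream)) {
    stream
  } else {
    k <- 0L
    function() {
      if (k >= length(stream)) return(NULL)
      k <<- k + 1L
      stream[[k]]
    }
  }
  .with_seed(seed, {
    reservoir <- vector("list", n)
    order_seen <- integer(n)
    t <- 0L
    while (!is.null(cmp <- nextone())) {
      t <- t + 1L
      if (t <= n) {
        reservoir[[t]] <- cmp
        order_seen[t] <- t
      } else {
        j <- sample.int(t, 1L)
        if (j <= n) {
          reservoir[[j]] <- cmp
          order_seen[j] <- t
        }
      }
    }
    if (t < n) stop(sprintf("requested %d compounds but the stream holds %d", n, t))
    reservoir[order(order_seen)]
  })
}

#' Library manifest table
#'
#' @param compounds List of `oxa_compound` objects.
#' @return Data frame with columns `identifier`, `r1`, `r2`, `combination`,
#'   `heavy_atoms`, `smiles`.
#' @export
library_manifest <- function(compounds) {
  data.frame(
    identifier = vapply(compounds, `[[`, "", "identifier"),
    r1 = vapply(compounds, function(x) x$r1$block_id, ""),
    r2 = vapply(compounds, function(x) x$r2$block_id, ""),
    combination = vapply(compounds, function(x) x$combination, 0L),
    heavy_atoms = vapply(compounds, function(x) heavy_atom_count(x$mol), 0L),
    smiles = vapply(compounds, function(x) x$mol$smiles, "")
  )
}
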