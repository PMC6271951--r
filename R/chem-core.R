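#' @import ChemmineR
#' @importFrom ChemmineOB convertFormat fingerprintOB propOB
NULL

# Organic-subset elements accepted in building blocks and assembled compounds.
.ORGANIC_ELEMENTS <- c("B", "C", "N", "O", "P", "S", "F", "Cl", "Br", "I", "H")

#' Parse a SMILES string into a molecule
#'
#' Molecules are canonicalized on input (OpenBabel canonical SMILES) and carry
#' an explicit atom and bond table so that downstream code can apply simple
#' structural rules (attachment points, donor/acceptor conventions) without
#' re-deriving chemistry. Canonicalization is idempotent: parsing the
#' `smiles` field of a molecule reproduces the same structure.
#'
#' @param text A single SMILES string.
#' @param id A text label used in error messages and output files.
#' @return An object of class `oxa_mol`: a list with elements `id`,
#'   `smiles` (canonical SMILES), `atoms` (data frame with columns `element`,
#'   `aromatic`, `charge`, `n_h` giving the hydrogen count of each heavy
#'   atom), and `bonds` (data frame with columns `a1`, `a2`, `order`; indices
#'   are 1-based into `atoms`).
#' @examples
#' m <- parse_molecule("c1ccccc1", "benzene")
#' heavy_atom_count(m)
#' @export
parse_molecule <- function(text, id = "mol") {
  parse_molecules(text, id)[[1]]
}

#' Parse many SMILES strings at once
#'
#' Vectorized companion of [parse_molecule()]; a single OpenBabel round trip
#' is used for the whole batch.
#'
#' @param texts Character vector of SMILES strings.
#' @param ids Character vector of labels (recycled rules not applied; must
#'   match length of `texts`).
#' @return A list of `oxa_mol` objects, named by `ids`.
#' @export
parse_molecules <- function(texts, ids = paste0("mol", seq_along(texts))) {
  stopifnot(is.character(texts), length(texts) >= 1L, length(ids) == length(texts))
  if (anyDuplicated(ids)) stop("molecule ids must be unique")
  canon <- .ob_canonical(texts, ids)
  sdf <- .ob_sdfset(canon, ids)
  out <- vector("list", length(texts))
  names(out) <- ids
  for (i in seq_along(texts)) {
    tok <- .smiles_atom_tokens(canon[i])
    out[[i]] <- .mol_from_sdf(sdf[[i]], canon[i], ids[i], tok)
  }
  out
}

# Canonicalize a batch of SMILES; errors name the offending id.
.ob_canonical <- function(texts, ids) {
  src <- paste0(paste(texts, ids), "\n", collapse = "")
  res <- suppressWarnings(convertFormat("SMI", "CAN", src))
  lines <- strsplit(res, "\n", fixed = TRUE)[[1]]
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  got <- vapply(parts, function(p) if (length(p) >= 2) p[2] else "", "")
  smi <- vapply(parts, `[[`, "", 1)
  canon <- smi[match(ids, got)]
  bad <- is.na(canon) | !nzchar(canon)
  if (any(bad)) {
    stop(sprintf("malformed SMILES for input id(s): %s",
                 paste(ids[bad], collapse = ", ")), call. = FALSE)
  }
  canon
}

# Convert canonical SMILES to an SDFset with explicit hydrogens. Explicit H
# makes bond-less molecules (single heavy atom) valid V2000 and lets hydrogen
# counts be read off as H neighbours.
.ob_sdfset <- function(canon, ids) {
  src <- paste0(paste(canon, ids), "\n", collapse = "")
  txt <- suppressWarnings(
    convertFormat("SMI", "SDF", src, options = data.frame(names = "h", args = ""))
  )
  sdf <- suppressWarnings(ChemmineR::read.SDFset(strsplit(txt, "\n", fixed = TRUE)[[1]]))
  ok <- ChemmineR::validSDF(sdf)
  if (!all(ok)) {
    stop(sprintf("could not build structures for id(s): %s",
                 paste(ids[!ok], collapse = ", ")), call. = FALSE)
  }
  if (length(sdf) != length(ids)) {
    stop("structure conversion dropped molecules unexpectedly", call. = FALSE)
  }
  sdf
}

# Tokenize the atoms of a SMILES string. Returns a data frame with one row per
# atom in order of appearance: element, aromatic flag, formal charge, and the
# start/end character positions of the atom token (used to splice attachment
# ring-closure labels into the string).
.smiles_atom_tokens <- function(smiles) {
  chars <- strsplit(smiles, "", fixed = TRUE)[[1]]
  n <- length(chars)
  rows <- list()
  i <- 1L
  while (i <= n) {
    ch <- chars[i]
    if (ch == "[") {
      j <- i
      while (j <= n && chars[j] != "]") j <- j + 1L
      body <- paste(chars[(i + 1L):(j - 1L)], collapse = "")
      sym <- regmatches(body, regexpr("^[0-9]*([A-Za-z][a-z]?)", body))
      elem <- sub("^[0-9]*", "", sym)
      aromatic <- elem %in% c("b", "c", "n", "o", "p", "s", "se", "as")
      charge <- 0L
      plus <- regmatches(body, regexpr("\\+[0-9]*", body))
      minus <- regmatches(body, regexpr("-[0-9]*", body))
      if (length(plus)) charge <- if (nchar(plus) > 1) as.integer(substring(plus, 2)) else sum(strsplit(body, "")[[1]] == "+")
      if (length(minus)) charge <- -(if (nchar(minus) > 1) as.integer(substring(minus, 2)) else sum(strsplit(body, "")[[1]] == "-"))
      rows[[length(rows) + 1L]] <- list(
        element = .cap_element(elem), aromatic = aromatic, charge = charge,
        start = i, end = j, bracket = TRUE
      )
      i <- j + 1L
    } else if (ch %in% c("C", "N", "O", "P", "S", "B", "F", "I")) {
      two <- if (i < n) paste0(ch, chars[i + 1L]) else ch
      if (two %in% c("Cl", "Br")) {
        rows[[length(rows) + 1L]] <- list(element = two, aromatic = FALSE, charge = 0L,
                                          start = i, end = i + 1L, bracket = FALSE)
        i <- i + 2L
      } else {
        rows[[length(rows) + 1L]] <- list(element = ch, aromatic = FALSE, charge = 0L,
                                          start = i, end = i, bracket = FALSE)
        i <- i + 1L
      }
    } else if (ch %in% c("b", "c", "n", "o", "p", "s")) {
      rows[[length(rows) + 1L]] <- list(element = toupper(ch), aromatic = TRUE, charge = 0L,
                                        start = i, end = i, bracket = FALSE)
      i <- i + 1L
    } else {
      # bonds, branches, ring closures, dots, stereo marks
      i <- i + 1L
    }
  }
  do.call(rbind.data.frame, c(rows, list(stringsAsFactors = FALSE)))
}

.cap_element <- function(elem) {
  paste0(toupper(substring(elem, 1, 1)), substring(elem, 2))
}

# Assemble an oxa_mol from an explicit-H SDF and the SMILES token table.
.mol_from_sdf <- function(sdf, smiles, id, tokens) {
  ab <- ChemmineR::atomblock(sdf)
  elems <- gsub("_.*$", "", rownames(ab))
  heavy <- which(elems != "H")
  if (nrow(tokens) != length(heavy)) {
    stop(sprintf("atom bookkeeping mismatch for id %s", id), call. = FALSE)
  }
  bad <- !(elems %in% .ORGANIC_ELEMENTS)
  if (any(bad)) {
    stop(sprintf("id %s: element(s) outside the organic subset: %s",
                 id, paste(unique(elems[bad]), collapse = ", ")), call. = FALSE)
  }
  bb <- ChemmineR::bondblock(sdf)
  a1 <- as.integer(bb[, 1]); a2 <- as.integer(bb[, 2]); ord <- as.integer(bb[, 3])
  n_h <- integer(length(heavy))
  hidx <- which(elems == "H")
  for (k in seq_along(heavy)) {
    h <- heavy[k]
    n_h[k] <- sum((a1 == h & a2 %in% hidx) | (a2 == h & a1 %in% hidx))
  }
  keep <- (a1 %in% heavy) & (a2 %in% heavy)
  remap <- match(seq_along(elems), heavy)
  bonds <- data.frame(a1 = remap[a1[keep]], a2 = remap[a2[keep]], order = ord[keep])
  atoms <- data.frame(element = tokens$element, aromatic = tokens$aromatic,
                      charge = tokens$charge, n_h = n_h)
  structure(list(id = id, smiles = smiles, atoms = atoms, bonds = bonds),
            class = "oxa_mol")
}

#' @export
print.oxa_mol <- function(x, ...) {
  cat(sprintf("<oxa_mol %s> %s (%d heavy atoms)\n",
              x$id, x$smiles, nrow(x$atoms)))
  invisible(x)
}

#' Count non-hydrogen atoms
#'
#' Heavy-atom counts drive the building-block size filter (6-12 heavy atoms)
#' and the 18-heavy-atom budget for an R1/R2 substituent pair.
#'
#' @param mol An `oxa_mol`.
#' @return Integer count of non-hydrogen atoms.
#' @export
heavy_atom_count <- function(mol) {
  stopifnot(inherits(mol, "oxa_mol"))
  nrow(mol$atoms)
}

#' Topological path fingerprint of a molecule
#'
#' Uses the OpenBabel FP2 fingerprint: hashed linear fragments of length 1-7
#' folded to 1024 bits. A path-type fingerprint makes the Tanimoto thresholds
#' used throughout the pipeline (0.95 for redundancy removal, 0.7 for
#' building-block clustering) behave conventionally.
#'
#' @param mol An `oxa_mol`.
#' @return An `oxa_fp` object: logical bit vector of length 1024 with
#'   attribute `popcount`.
#' @export
fingerprint <- function(mol) {
  stopifnot(inherits(mol, "oxa_mol"))
  as_fingerprint(fingerprint_matrix(list(mol))[1, ])
}

#' Fingerprint a list of molecules as a bit matrix
#'
#' @param mols List of `oxa_mol` objects.
#' @return Logical matrix, one row per molecule (row names = molecule ids).
#' @export
fingerprint_matrix <- function(mols) {
  stopifnot(length(mols) >= 1L)
  ids <- vapply(mols, function(m) m$id, "")
  canon <- vapply(mols, function(m) m$smiles, "")
  sdf <- .ob_sdfset(canon, make.unique(ids))
  m <- as.matrix(fingerprintOB(sdf, "FP2")) > 0
  rownames(m) <- ids
  m
}

#' Construct a fingerprint from a logical bit vector
#'
#' @param bits Logical (or 0/1) vector.
#' @return An `oxa_fp` object.
#' @export
as_fingerprint <- function(bits) {
  bits <- as.logical(bits)
  structure(bits, popcount = sum(bits), class = "oxa_fp")
}

#' @export
print.oxa_fp <- function(x, ...) {
  cat(sprintf("<oxa_fp> %d bits, popcount %d\n", length(x), attr(x, "popcount")))
  invisible(x)
}

#' Tanimoto similarity of two bit fingerprints
#'
#' `|A intersect B| / |A union B|` over the set bits. By convention two
#' all-zero fingerprints compare as identical (1.0) while a zero fingerprint
#' against a non-zero one scores 0.0; this keeps redundancy removal stable for
#' featureless single-atom fragments.
#'
#' @param a,b Fingerprints (`oxa_fp` or logical vectors of equal length).
#' @return Similarity in \[0, 1\].
#' @export
tanimoto <- function(a, b) {
  a <- as.logical(a); b <- as.logical(b)
  if (length(a) != length(b)) stop("fingerprint lengths differ")
  u <- sum(a | b)
  if (u == 0) return(1.0)
  sum(a & b) / u
}

# Row-vs-rows Tanimoto against a logical matrix; same zero-bit conventions.
.tanimoto_rows <- function(bits, mat) {
  if (is.null(dim(mat))) mat <- matrix(mat, nrow = 1)
  inter <- as.vector(mat %*% bits)
  uni <- attr_popcounts(mat) + sum(bits) - inter
  out <- ifelse(uni == 0, 1.0, inter / uni)
  as.numeric(out)
}

attr_popcounts <- function(mat) rowSums(mat)

#' Physicochemical descriptor profile
#'
#' Molecular weight, logP and topological polar surface area come from
#' OpenBabel's additive models; hydrogen-bond donor and acceptor counts are
#' computed from the molecule's own atom table using documented conventions:
#' a donor is an N or O bearing at least one hydrogen; an acceptor is an N or
#' O excluding pyrrole-type aromatic NH nitrogens and amide nitrogens
#' (N single-bonded to a carbonyl carbon).
#'
#' @param mol An `oxa_mol`.
#' @return A data frame with one row: `molecular_weight` (Da), `logp`, `tpsa`
#'   (A^2), `hbd`, `hba`, `heavy_atoms`.
#' @export
descriptor_profile <- function(mol) {
  stopifnot(inherits(mol, "oxa_mol"))
  sdf <- .ob_sdfset(mol$smiles, mol$id)
  p <- propOB(sdf)
  data.frame(
    id = mol$id,
    molecular_weight = p$MW,
    logp = p$logP,
    tpsa = p$TPSA,
    hbd = .count_hbd(mol),
    hba = .count_hba(mol),
    heavy_atoms = heavy_atom_count(mol)
  )
}

.count_hbd <- function(mol) {
  with(mol$atoms, sum(element %in% c("N", "O") & n_h >= 1L))
}

.count_hba <- function(mol) {
  at <- mol$atoms
  bd <- mol$bonds
  cand <- which(at$element %in% c("N", "O"))
  # carbonyl carbons: C double-bonded to O
  carbonyl_c <- unique(c(
    bd$a1[bd$order == 2 & at$element[bd$a1] == "C" & at$element[bd$a2] == "O"],
    bd$a2[bd$order == 2 & at$element[bd$a2] == "C" & at$element[bd$a1] == "O"]
  ))
  is_amide_n <- function(i) {
    if (at$element[i] != "N") return(FALSE)
    nb <- c(bd$a2[bd$a1 == i & bd$order == 1], bd$a1[bd$a2 == i & bd$order == 1])
    any(nb %in% carbonyl_c)
  }
  keep <- vapply(cand, function(i) {
    if (at$element[i] == "N" && at$aromatic[i] && at$n_h[i] >= 1L) return(FALSE)
    if (is_amide_n(i)) return(FALSE)
    TRUE
  }, TRUE)
  sum(keep)
}

#' Rule-of-five compliance
#'
#' Inclusive Lipinski bounds: molecular weight <= 500 Da, logP <= 5,
#' donors <= 5, acceptors <= 10.
#'
#' @param profile One-row data frame from [descriptor_profile()] (or any list
#'   with `molecular_weight`, `logp`, `hbd`, `hba`).
#' @return Logical.
#' @export
rule_of_five_pass <- function(profile) {
  profile$molecular_weight <= 500 && profile$logp <= 5 &&
    profile$hbd <= 5 && profile$hba <= 10
}

#' Read a SMILES file
#'
#' One record per line, `SMILES<whitespace>ID`; lines starting with `#` are
#' ignored. Records missing an id get `mol<line>` labels.
#'
#' @param path File path.
#' @return List of `oxa_mol` objects.
#' @export
read_smiles_file <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (!length(lines)) return(list())
  parts <- strsplit(lines, "[ \t]+")
  smi <- vapply(parts, `[[`, "", 1)
  ids <- vapply(seq_along(parts), function(i) {
    if (length(parts[[i]]) >= 2) parts[[i]][2] else paste0("mol", i)
  }, "")
  parse_molecules(smi, ids)
}

#' Write molecules to a SMILES file
#'
#' @param mols List of `oxa_mol` objects.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_smiles_file <- function(mols, path) {
  writeLines(vapply(mols, function(m) paste(m$smiles, m$id, sep = "\t"), ""), path)
  invisible(path)
}

#' Write molecules to an SDF file (V2000)
#'
#' @param mols List of `oxa_mol` objects.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_sdf_file <- function(mols, path) {
  canon <- vapply(mols, function(m) m$smiles, "")
  ids <- vapply(mols, function(m) m$id, "")
  sdf <- .ob_sdfset(canon, ids)
  ChemmineR::write.SDF(sdf, file = path)
  invisible(path)
}
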