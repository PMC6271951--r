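# Shannon-entropy conservation profiling of the BC ATP binding site.

#' Standard amino-acid alphabet used by sequence profiles
#'
#' @return Character vector of the 20 one-letter codes, alphabetical.
#' @export
amino_acids <- function() {
  c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
    "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
}

#' The seven biotin carboxylase isoforms
#'
#' Four Gram-negative and three Gram-positive species whose BC binding sites
#' are modeled on the E. coli reference structure.
#'
#' @return Data frame with columns `code`, `organism`, `gram`.
#' @export
bc_isoforms <- function() {
  data.frame(
    code = c("Ec", "Hi", "Pa", "Mc", "Ef", "Sp", "Sa"),
    organism = c("Escherichia coli", "Haemophilus influenzae",
                 "Pseudomonas aeruginosa", "Moraxella catarrhalis",
                 "Enterococcus faecalis", "Streptococcus pneumoniae",
                 "Staphylococcus aureus"),
    gram = c("negative", "negative", "negative", "negative",
             "positive", "positive", "positive")
  )
}

#' Shannon entropy of an amino-acid frequency vector
#'
#' `H = -sum(p * log2(p))` with the convention `0 * log2(0) = 0`. Log base 2
#' throughout, so entropies are in bits; the maximum for 20 symbols is
#' `log2(20) ~ 4.32` bits.
#'
#' @param freq Numeric 20-vector of probabilities (non-negative, summing to 1
#'   within `tol`).
#' @param tol Tolerance on the sum-to-one check.
#' @return Entropy in bits.
#' @examples
#' shannon_entropy(rep(1 / 20, 20))  # log2(20)
#' @export
shannon_entropy <- function(freq, tol = 1e-6) {
  if (any(freq < 0)) stop("frequencies must be non-negative")
  if (abs(sum(freq) - 1) > tol) {
    stop(sprintf("frequencies must sum to 1 (got %.6f)", sum(freq)))
  }
  p <- freq[freq > 0]
  -sum(p * log2(p))
}

#' Load the bundled background amino-acid composition
#'
#' A generic protein-like composition (UniProtKB/Swiss-Prot-era residue
#' frequencies) used as the reference for the maximum attainable profile
#' entropy.
#'
#' @param path Optional path to a two-column TSV (`aa`, `frequency`);
#'   defaults to the bundled table.
#' @return Named numeric 20-vector of frequencies summing to 1.
#' @export
background_composition <- function(path = NULL) {
  if (is.null(path)) path <- .extdata("aa_background_composition.tsv")
  df <- .read_tsv(path)
  v <- stats::setNames(df$frequency, df$aa)
  v <- v[amino_acids()]
  if (anyNA(v)) stop("background composition must cover all 20 amino acids")
  v / sum(v)
}

#' Maximum entropy of a background composition
#'
#' The Shannon entropy of a generic protein-like amino-acid composition; a
#' profile position cannot be less conserved than this reference.
#'
#' @param background Named 20-vector of frequencies (default: bundled
#'   composition).
#' @return Entropy in bits.
#' @export
background_max_entropy <- function(background = background_composition()) {
  shannon_entropy(background / sum(background))
}

#' Mean and standard deviation of entropy values
#'
#' The standard deviation uses the sample (n-1) convention; for summaries of
#' small position sets the mean is the robust quantity.
#'
#' @param values Numeric vector of entropies (bits); must be non-empty.
#' @return List with `mean` and `sd` (bits; `sd` is `NA` for a single value).
#' @export
entropy_summary <- function(values) {
  if (!length(values)) stop("empty entropy list")
  list(mean = mean(values), sd = stats::sd(values))
}

#' Load the BC binding-site residue table
#'
#' 21 ATP-binding-site positions (E. coli residue numbering 116-438) with
#' per-position sequence entropy, ligand-binding probability and confidence,
#' and the residue identity in each of the seven isoforms.
#'
#' @param path Optional TSV path; defaults to the bundled table.
#' @return Data frame with columns `residue_number`, `entropy`,
#'   `probability`, `confidence`, and one column per isoform code.
#' @export
load_binding_site_table <- function(path = NULL) {
  if (is.null(path)) path <- .extdata("binding_site_residues.tsv")
  df <- .read_tsv(path, colClasses = c(
    residue_number = "integer", entropy = "numeric",
    probability = "numeric", confidence = "numeric"
  ))
  need <- c("residue_number", "entropy", "probability", "confidence",
            bc_isoforms()$code)
  missing <- setdiff(need, names(df))
  if (length(missing)) {
    stop(sprintf("binding-site table lacks column(s): %s",
                 paste(missing, collapse = ", ")))
  }
  aa_ok <- vapply(bc_isoforms()$code, function(cc) {
    all(df[[cc]] %in% amino_acids())
  }, TRUE)
  if (!all(aa_ok)) stop("binding-site table contains invalid residue letters")
  df
}

#' Classify the cross-isoform conservation of a binding-site position
#'
#' A position is `conserved_all` when one residue occurs in every isoform,
#' `gram_specific` when it is uniform within each Gram group but differs
#' between the groups, and `variable` otherwise.
#'
#' @param position One row of [load_binding_site_table()] (or any list with
#'   the isoform columns).
#' @param isoforms Isoform table (default [bc_isoforms()]).
#' @return One of `"conserved_all"`, `"gram_specific"`, `"variable"`.
#' @export
classify_position_conservation <- function(position, isoforms = bc_isoforms()) {
  res <- vapply(isoforms$code, function(cc) as.character(position[[cc]]), "")
  if (anyNA(res) || any(!nzchar(res))) stop("residues missing for some isoforms")
  neg <- res[isoforms$gram == "negative"]
  pos <- res[isoforms$gram == "positive"]
  if (length(unique(res)) == 1L) return("conserved_all")
  if (length(unique(neg)) == 1L && length(unique(pos)) == 1L) return("gram_specific")
  "variable"
}

#' Residue substitutions needed to model one isoform's binding site
#'
#' Lists the binding-site positions at which the target isoform differs from
#' the reference, i.e. the side-chain mutations applied when building the
#' target's structural model from the reference crystal structure.
#'
#' @param target Isoform code (e.g. `"Sp"`).
#' @param reference Reference isoform code (default `"Ec"`).
#' @param table Binding-site table (default: bundled).
#' @return Data frame with columns `residue_number`, `from_aa`, `to_aa`;
#'   zero rows when target equals reference.
#' @export
mutated_binding_site <- function(target, reference = "Ec",
                                 table = load_binding_site_table()) {
  codes <- bc_isoforms()$code
  if (!(target %in% codes)) stop(sprintf("unknown isoform: %s", target))
  if (!(reference %in% codes)) stop(sprintf("unknown isoform: %s", reference))
  differ <- table[[target]] != table[[reference]]
  data.frame(residue_number = table$residue_number[differ],
             from_aa = table[[reference]][differ],
             to_aa = table[[target]][differ])
}

#' Read a sequence profile from a TSV file
#'
#' Expected columns: `position` plus the 20 amino-acid frequency columns.
#'
#' @param path File path.
#' @return An `oxa_profile`: list with `positions` (integer vector) and
#'   `frequencies` (matrix, rows = positions, columns = [amino_acids()]).
#' @export
read_profile_tsv <- function(path) {
  df <- .read_tsv(path)
  aas <- amino_acids()
  if (!all(c("position", aas) %in% names(df))) {
    stop("profile TSV needs a 'position' column and all 20 amino-acid columns")
  }
  freq <- as.matrix(df[, aas])
  freq <- freq / rowSums(freq)
  .new_profile(as.integer(df$position), freq)
}

.new_profile <- function(positions, freq) {
  rownames(freq) <- positions
  colnames(freq) <- amino_acids()
  bad <- abs(rowSums(freq) - 1) > 1e-9 | apply(freq < 0, 1, any)
  if (any(bad)) stop("profile rows must be probability vectors")
  structure(list(positions = positions, frequencies = freq),
            class = "oxa_profile")
}

#' @export
print.oxa_profile <- function(x, ...) {
  cat(sprintf("<oxa_profile> %d positions, mean entropy %.3f bits\n",
              length(x$positions), mean(profile_entropies(x))))
  invisible(x)
}

#' Per-position entropies of a profile
#'
#' @param profile An `oxa_profile`.
#' @return Numeric vector of entropies (bits), named by position.
#' @export
profile_entropies <- function(profile) {
  stopifnot(inherits(profile, "oxa_profile"))
  apply(profile$frequencies, 1, shannon_entropy)
}

#' Build a sequence profile from a FASTA alignment
#'
#' Simple per-column residue frequencies (pseudocount 0); gaps and
#' non-standard letters are ignored within each column.
#'
#' @param path Path to an aligned FASTA file of protein sequences.
#' @return An `oxa_profile` with one position per alignment column.
#' @export
profile_from_alignment <- function(path) {
  aln <- Biostrings::readAAStringSet(path)
  if (!length(aln)) stop("empty alignment")
  if (length(unique(Biostrings::width(aln))) != 1L) {
    stop("sequences are not aligned (unequal lengths)")
  }
  cons <- Biostrings::consensusMatrix(aln)
  aas <- amino_acids()
  counts <- matrix(0, nrow = ncol(cons), ncol = length(aas),
                   dimnames = list(NULL, aas))
  present <- intersect(rownames(cons), aas)
  counts[, present] <- t(cons[present, , drop = FALSE])
  tot <- rowSums(counts)
  if (any(tot == 0)) stop("alignment column with no standard residues")
  .new_profile(seq_len(nrow(counts)), counts / tot)
}
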