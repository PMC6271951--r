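# Post-docking computation: anchor-consistency filtering, joint-probability
# docking accuracy, per-isoform SUM-rule score fusion, cross-isoform group
# consensus, rank correlation, and pose-benchmark threshold counting.

#' Default ranking direction of each docking score
#'
#' Affinity is a predicted ln Ki, so lower is better; the fitness and binding
#' probabilities and the reported interaction energy are better when larger
#' (top-ranked compounds in the study carry large positive energies).
#'
#' @return Named character vector, values `"lower"` or `"higher"`.
#' @export
score_directions <- function() {
  c(affinity = "lower", fitness = "higher", binding = "higher",
    energy = "higher")
}

.RECORD_COLS <- c("compound_id", "isoform", "anchor_rmsd", "affinity",
                  "fitness", "binding", "energy")

#' Read a docking-record table
#'
#' Tab-separated, one row per compound x isoform, with columns
#' `compound_id`, `isoform`, `anchor_rmsd`, `affinity`, `fitness`,
#' `binding`, `energy`. Ranges are validated (`anchor_rmsd >= 0`, `fitness`
#' and `binding` in \[0, 1\]).
#'
#' @param path File path.
#' @return Data frame of docking records.
#' @export
read_docking_records <- function(path) {
  df <- .read_tsv(path)
  validate_docking_records(df)
}

#' Validate a docking-record data frame
#'
#' @param records Data frame with the docking-record columns.
#' @return The validated data frame (invisibly unchanged).
#' @export
validate_docking_records <- function(records) {
  missing <- setdiff(.RECORD_COLS, names(records))
  if (length(missing)) {
    stop(sprintf("docking records lack column(s): %s",
                 paste(missing, collapse = ", ")))
  }
  if (any(records$anchor_rmsd < 0)) stop("anchor_rmsd must be >= 0")
  if (any(records$fitness < 0 | records$fitness > 1)) {
    stop("fitness must lie in [0, 1]")
  }
  if (any(records$binding < 0 | records$binding > 1)) {
    stop("binding must lie in [0, 1]")
  }
  if (anyDuplicated(paste(records$compound_id, records$isoform))) {
    stop("duplicate compound x isoform rows")
  }
  records
}

#' Write docking records to TSV
#'
#' @param records Docking-record data frame.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_docking_records <- function(records, path) {
  .write_tsv(validate_docking_records(records)[, .RECORD_COLS], path)
}

#' Anchor-consistency filter
#'
#' A compound passes when its amino-oxazole anchor was docked within
#' `cutoff` (inclusive) of the reference anchor conformation in every
#' isoform of the set; compounds lacking a record for any isoform fail.
#'
#' @param records Docking-record data frame.
#' @param isoforms Character vector of isoform codes that must all pass
#'   (default: all seven).
#' @param cutoff Anchor RMSD cutoff in Angstrom (default 2.0).
#' @return Character vector of passing compound ids (in first-appearance
#'   order).
#' @export
anchor_consistency_filter <- function(records, isoforms = bc_isoforms()$code,
                                      cutoff = 2.0) {
  if (!length(isoforms)) stop("empty isoform set")
  sub <- records[records$isoform %in% isoforms, , drop = FALSE]
  ids <- unique(records$compound_id)
  ok_counts <- table(factor(sub$compound_id[sub$anchor_rmsd <= cutoff],
                            levels = ids))
  n_counts <- table(factor(sub$compound_id, levels = ids))
  pass <- ids[n_counts == length(isoforms) & ok_counts == length(isoforms)]
  pass
}

#' Per-docking accuracy from a joint pass fraction
#'
#' Treating the anchor-consistency events in the `k` isoforms as independent,
#' a joint pass fraction `f` implies a per-docking success probability
#' `p = f^(1/k)`.
#'
#' @param pass_fraction Fraction of compounds passing the filter jointly,
#'   in (0, 1\].
#' @param k Number of isoforms.
#' @return Estimated per-docking accuracy `p`.
#' @examples
#' docking_accuracy(1246716 / 8898942, 7)  # ~0.755
#' @export
docking_accuracy <- function(pass_fraction, k) {
  if (pass_fraction <= 0) stop("pass fraction must be positive")
  if (pass_fraction > 1) stop("pass fraction cannot exceed 1")
  if (k < 1) stop("k must be >= 1")
  pass_fraction^(1 / k)
}

#' Compound counts of the published screening campaign
#'
#' The screening stage docked 8,898,942 amino-oxazole derivatives against
#' seven BC isoforms; 1,246,716 of them kept the anchor within 2 Angstrom of
#' the reference conformation in every isoform. These counts are the inputs
#' to the joint-probability accuracy estimate.
#'
#' @return Named list: `screened`, `passed`, `isoforms`.
#' @export
screening_counts <- function() {
  list(screened = 8898942L, passed = 1246716L, isoforms = 7L)
}

#' Rank compounds of one isoform by a single docking score
#'
#' Ties receive average ranks; the final row order is by rank with a
#' deterministic compound-id tie-break. Rank 1 is the best compound in the
#' configured direction.
#'
#' @param records Docking records of a single isoform (one row per compound).
#' @param score Score column name (one of `affinity`, `fitness`, `binding`,
#'   `energy`).
#' @param direction `"lower"` or `"higher"` = which end is better
#'   (default: [score_directions()]).
#' @return An `oxa_ranking` data frame with columns `compound_id`, `rank`,
#'   `relative_rank`.
#' @export
rank_by_score <- function(records, score, direction = NULL) {
  if (!(score %in% names(score_directions()))) {
    stop(sprintf("unknown score: %s", score))
  }
  if (anyDuplicated(records$compound_id)) {
    stop("one record per compound required (single isoform)")
  }
  if (is.null(direction)) direction <- score_directions()[[score]]
  v <- records[[score]]
  key <- if (direction == "lower") v else -v
  .make_ranking(records$compound_id, key)
}

# Build an oxa_ranking from ids and a "smaller is better" key.
.make_ranking <- function(ids, key) {
  r <- rank(key, ties.method = "average")
  ord <- order(key, ids)
  out <- data.frame(compound_id = ids[ord], rank = r[ord],
                    relative_rank = r[ord] / length(ids))
  class(out) <- c("oxa_ranking", "data.frame")
  out
}

#' Fuse rankings with the SUM rule
#'
#' Consensus ranking in which each compound's fused score is the sum of its
#' ranks across the input lists; lower sums rank first. Being rank-based,
#' the fusion is invariant under any strictly monotone transformation of the
#' underlying scores.
#'
#' @param rankings List of `oxa_ranking` objects over identical compound
#'   sets.
#' @return An `oxa_ranking` with an additional `fused_sum` column.
#' @export
fuse_scores_sum <- function(rankings) {
  if (!length(rankings)) stop("no rankings to fuse")
  ids <- sort(rankings[[1]]$compound_id)
  sums <- numeric(length(ids))
  for (rk in rankings) {
    if (!identical(sort(rk$compound_id), ids)) {
      stop("rankings cover different compound sets")
    }
    sums <- sums + rk$rank[match(ids, rk$compound_id)]
  }
  out <- .make_ranking(ids, sums)
  out$fused_sum <- sums[match(out$compound_id, ids)]
  out
}

#' Per-isoform consensus over the four docking scores
#'
#' Convenience wrapper: ranks one isoform's records by each docking score in
#' its configured direction and fuses the four rankings with the SUM rule.
#'
#' @param records Docking records of a single isoform.
#' @param directions Named direction overrides (default
#'   [score_directions()]).
#' @return An `oxa_ranking` with `fused_sum`.
#' @export
isoform_consensus <- function(records, directions = score_directions()) {
  rks <- lapply(names(directions), function(s) {
    rank_by_score(records, s, directions[[s]])
  })
  fuse_scores_sum(rks)
}

#' Cross-isoform group consensus ranking
#'
#' SUM-rule fusion of per-isoform fused rankings, restricted to the
#' isoforms of a group. The fusion nesting follows the screening protocol:
#' scores are fused within each isoform first, then isoforms within the
#' group.
#'
#' @param records Docking records covering the group's isoforms.
#' @param group `"gram_negative"`, `"gram_positive"`, or `"all"`; or a
#'   character vector of isoform codes.
#' @param directions Named score directions.
#' @return An `oxa_ranking` with `fused_sum`.
#' @export
group_consensus <- function(records, group = "all",
                            directions = score_directions()) {
  codes <- .group_codes(group)
  codes <- codes[codes %in% unique(records$isoform)]
  if (!length(codes)) stop("empty isoform group")
  per_iso <- lapply(codes, function(cc) {
    isoform_consensus(records[records$isoform == cc, , drop = FALSE],
                      directions)
  })
  fuse_scores_sum(per_iso)
}

.group_codes <- function(group) {
  iso <- bc_isoforms()
  if (length(group) == 1L && group %in% c("gram_negative", "gram_positive", "all")) {
    switch(group,
           gram_negative = iso$code[iso$gram == "negative"],
           gram_positive = iso$code[iso$gram == "positive"],
           all = iso$code)
  } else {
    unknown <- setdiff(group, iso$code)
    if (length(unknown)) {
      stop(sprintf("unknown isoform code(s): %s", paste(unknown, collapse = ", ")))
    }
    group
  }
}

#' Consensus rankings for the three standard groups
#'
#' @param records Docking records (typically restricted to compounds passing
#'   [anchor_consistency_filter()]).
#' @param directions Named score directions.
#' @return Named list of `oxa_ranking` objects: `gram_negative`,
#'   `gram_positive`, `all`.
#' @export
consensus_rankings <- function(records, directions = score_directions()) {
  list(gram_negative = group_consensus(records, "gram_negative", directions),
       gram_positive = group_consensus(records, "gram_positive", directions),
       all = group_consensus(records, "all", directions))
}

#' Pearson correlation of two rankings on the relative-rank scale
#'
#' Matches compounds by id and correlates their relative ranks; symmetric
#' and bounded in \[-1, 1\].
#'
#' @param list_a,list_b `oxa_ranking` objects over the same compounds.
#' @return Pearson correlation coefficient.
#' @export
rank_correlation <- function(list_a, list_b) {
  if (nrow(list_a) < 2L) stop("need at least two compounds")
  m <- match(list_a$compound_id, list_b$compound_id)
  if (anyNA(m) || nrow(list_a) != nrow(list_b)) {
    stop("rankings cover different compound sets")
  }
  stats::cor(list_a$relative_rank, list_b$relative_rank[m])
}

#' Count poses docked within an RMSD threshold
#'
#' Strict comparison (`< cutoff`); on the bundled benchmark no value lies in
#' \[2.0, 2.208\) so strict vs inclusive is observationally equivalent there.
#'
#' @param rmsds Numeric vector of non-negative RMSD values (Angstrom).
#' @param cutoff Threshold (default 2.0).
#' @return Integer count.
#' @export
count_poses_within <- function(rmsds, cutoff = 2.0) {
  if (any(rmsds < 0)) stop("RMSD values must be non-negative")
  sum(rmsds < cutoff)
}

#' Load the bundled cross-docking pose benchmark
#'
#' @return Data frame with columns `pdb_id`, `scaffold`, `vina`, `esimdock`
#'   (ligand heavy-atom RMSD in Angstrom, 14 complexes).
#' @export
load_pose_benchmark <- function() {
  .read_tsv(.extdata("pose_rmsd_benchmark.tsv"))
}

#' Load the bundled top-compound docking score table
#'
#' Scores of five top-ranked amino-oxazole derivatives against the Ec and Sp
#' isoforms, in the docking-record schema.
#'
#' @return Docking-record data frame (10 rows).
#' @export
load_top_compound_scores <- function() {
  read_docking_records(.extdata("top_compound_scores.tsv"))
}

#' Write a ranking to TSV
#'
#' @param ranking An `oxa_ranking`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_ranking <- function(ranking, path) {
  .write_tsv(as.data.frame(ranking), path)
}
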