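# Anchor filtering, accuracy estimation, SUM-rule fusion, rank correlation.

test_that("anchor-consistency filter requires all isoforms within the inclusive cutoff", {
  iso <- bc_isoforms()$code
  mk <- function(id, rmsds) {
    data.frame(compound_id = id, isoform = iso, anchor_rmsd = rmsds,
               affinity = 0, fitness = 0.5, binding = 0.5, energy = 0)
  }
  rec <- rbind(mk("good", rep(1.4, 7)),
               mk("edge", rep(2.0, 7)),          # exactly at the cutoff
               mk("bad", c(rep(1.0, 6), 2.5)),
               mk("partial", rep(0.5, 7))[1:6, ]) # missing one isoform
  pass <- anchor_consistency_filter(rec)
  expect_setequal(pass, c("good", "edge"))
  expect_error(anchor_consistency_filter(rec, isoforms = character()), "empty")
  # the bundled top-compound scores all pass against Ec/Sp
  top <- load_top_compound_scores()
  expect_length(anchor_consistency_filter(top, isoforms = c("Ec", "Sp")), 5L)
})

test_that("joint-probability accuracy is the k-th root of the pass fraction", {
  expect_equal(docking_accuracy(1, 7), 1)
  expect_equal(docking_accuracy(0.5^7, 7), 0.5)
  expect_error(docking_accuracy(0, 7), "positive")
  expect_error(docking_accuracy(1.2, 7), "exceed")
})

test_that("single-score ranking uses direction, average ties and id tie-breaks", {
  rec <- toy_records(c(a = 3, b = 1, c = 2), score_name = "affinity")
  rk <- rank_by_score(rec, "affinity")  # lower is better
  expect_identical(rk$compound_id, c("b", "c", "a"))
  expect_equal(rk$rank[match(c("a", "b", "c"), rk$compound_id)], c(3, 1, 2))
  tie <- rank_by_score(toy_records(c(a = 1, b = 1, c = 1)), "affinity")
  expect_equal(tie$rank, rep(2, 3))  # (N+1)/2 everywhere
  expect_identical(tie$compound_id, c("a", "b", "c"))
  hi <- rank_by_score(toy_records(c(a = 0.9, b = 0.1), score_name = "fitness"),
                      "fitness")
  expect_identical(hi$compound_id[1], "a")
  expect_error(rank_by_score(rec, "glory"), "unknown score")
  # double ranking (ranking the ranks) is idempotent
  set.seed(7)
  sc <- setNames(rnorm(50), sprintf("c%02d", 1:50))
  r1 <- rank_by_score(toy_records(sc), "affinity")
  r2 <- rank_by_score(
    toy_records(setNames(r1$rank[match(names(sc), r1$compound_id)], names(sc))),
    "affinity")
  expect_identical(r1$compound_id, r2$compound_id)
})

test_that("SUM-rule fusion matches brute force, breaks ties by id, and is monotone-invariant", {
  asc <- rank_by_score(toy_records(c(A = 1, B = 2, C = 3)), "affinity")
  expect_identical(fuse_scores_sum(list(asc))$compound_id, asc$compound_id)
  expect_identical(fuse_scores_sum(list(asc, asc))$compound_id, asc$compound_id)
  desc <- rank_by_score(toy_records(c(A = 3, B = 2, C = 1)), "affinity")
  both <- fuse_scores_sum(list(asc, desc))
  expect_identical(both$compound_id, c("A", "B", "C"))  # equal sums, id order
  expect_equal(both$fused_sum, rep(4, 3))
  # random multi-score fusion against the oracle
  set.seed(13)
  ids <- sprintf("m%03d", 1:100)
  scores <- list(setNames(rnorm(100), ids), setNames(rnorm(100), ids),
                 setNames(round(rnorm(100), 1), ids))  # ties included
  rks <- lapply(scores, function(s) rank_by_score(toy_records(s), "affinity"))
  fused <- fuse_scores_sum(rks)
  expect_identical(fused$compound_id,
                   oracle_fuse(scores, lower_better = c(TRUE, TRUE, TRUE)))
  # invariance under strictly monotone score transforms
  rks_exp <- lapply(scores, function(s) {
    rank_by_score(toy_records(setNames(exp(s[ids]), ids)), "affinity")
  })
  expect_identical(fuse_scores_sum(rks_exp)$compound_id, fused$compound_id)
  expect_error(fuse_scores_sum(list(asc, rks[[1]])), "different compound sets")
})

test_that("group consensus fuses per-isoform lists and satisfies the rank-sum identity", {
  blocks <- sprintf("%08d", 1:12)
  ids <- generate_compound_ids(blocks, 100, seed = 3)
  rec <- generate_docking_records(ids, simulation_params(
    seed = 4, anchor_pass_prob = 1, group_correlation = 0.5))
  cons <- consensus_rankings(rec)
  # single-isoform group equals that isoform's fused list
  ec <- group_consensus(rec, "Ec")
  ec_direct <- isoform_consensus(rec[rec$isoform == "Ec", ])
  expect_identical(ec$compound_id, ec_direct$compound_id)
  # brute-force oracle: sum the per-isoform fused ranks
  per_iso <- lapply(bc_isoforms()$code, function(cc) {
    isoform_consensus(rec[rec$isoform == cc, ])
  })
  sums <- rowSums(vapply(per_iso, function(rk) {
    rk$rank[match(ids, rk$compound_id)]
  }, numeric(length(ids))))
  expect_identical(cons$all$compound_id, ids[order(sums, ids)])
  # rank-sum identity: all = gram_negative + gram_positive on every compound
  key <- function(rk) rk$fused_sum[match(ids, rk$compound_id)]
  expect_equal(key(cons$all), key(cons$gram_negative) + key(cons$gram_positive))
  expect_error(group_consensus(rec, "Zz"), "unknown isoform")
})

test_that("unanimous best compound tops the consensus", {
  iso <- bc_isoforms()$code
  rec <- do.call(rbind, lapply(iso, function(cc) {
    data.frame(compound_id = c("star", "meh1", "meh2"), isoform = cc,
               anchor_rmsd = 1, affinity = c(-5, 1, 2),
               fitness = c(0.99, 0.5, 0.4), binding = c(0.99, 0.5, 0.4),
               energy = c(80, 10, 5))
  }))
  for (grp in c("gram_negative", "gram_positive", "all")) {
    expect_identical(group_consensus(rec, grp)$compound_id[1], "star")
  }
})

test_that("rank correlation is symmetric with the expected extremes", {
  asc <- rank_by_score(toy_records(setNames(1:10, letters[1:10])), "affinity")
  rev <- rank_by_score(toy_records(setNames(10:1, letters[1:10])), "affinity")
  expect_equal(rank_correlation(asc, asc), 1)
  expect_equal(rank_correlation(asc, rev), -1)
  set.seed(2)
  r1 <- rank_by_score(toy_records(setNames(rnorm(30), sprintf("x%02d", 1:30))), "affinity")
  r2 <- rank_by_score(toy_records(setNames(rnorm(30), sprintf("x%02d", 1:30))), "affinity")
  expect_equal(rank_correlation(r1, r2), rank_correlation(r2, r1))
  expect_error(rank_correlation(asc[1, ], asc[1, ]), "two compounds")
})

test_that("pose-success counting reproduces the benchmark totals", {
  bench <- load_pose_benchmark()
  expect_identical(nrow(bench), 14L)
  expect_identical(count_poses_within(bench$esimdock), 8L)
  expect_identical(count_poses_within(bench$vina), 4L)
  expect_identical(count_poses_within(numeric()), 0L)
  expect_error(count_poses_within(c(1, -0.2)), "non-negative")
})

test_that("docking-record IO validates schema and ranges", {
  top <- load_top_compound_scores()
  tmp <- tempfile(fileext = ".tsv")
  write_docking_records(top, tmp)
  again <- read_docking_records(tmp)
  expect_equal(again$affinity, top$affinity)
  bad <- top; bad$fitness[1] <- 1.7
  expect_error(validate_docking_records(bad), "fitness")
  expect_error(validate_docking_records(top[, -3]), "lack column")
})
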