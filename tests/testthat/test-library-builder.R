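# Combinatorial library construction.

test_that("heavy-atom filter keeps the inclusive 6-12 window in order", {
  blocks <- quietly(list(
    mk_block("CCCC", "b04"), mk_block("CCCCCC", "b06"),
    mk_block("CCCCCCCCCCCC", "b12"), mk_block("CCCCCCCCCCCCC", "b13")))
  kept <- filter_blocks(blocks)
  expect_identical(vapply(kept, `[[`, "", "id"), c("b06", "b12"))
  expect_identical(filter_blocks(list()), list())
})

test_that("similarity dedupe keeps one of identical molecules and all dissimilar ones", {
  five_same <- quietly(lapply(1:5, function(i) {
    mk_block("Clc1ccc(C)cc1", sprintf("dup%d", i))
  }))
  expect_length(quietly(dedupe_by_similarity(five_same)), 1L)
  distinct <- quietly(list(mk_block("CCCCCC", "a1"),
                           mk_block("c1ccncc1C", "a2"),
                           mk_block("OCC1CCCO1", "a3")))
  expect_length(quietly(dedupe_by_similarity(distinct)), 3L)
})

test_that("dedupe matches the exhaustive pairwise oracle on planted families and is idempotent", {
  blocks <- quietly(generate_building_blocks(n_families = 8, seed = 21,
                                             variants_per_family = 5))
  got <- quietly(dedupe_by_similarity(blocks, 0.95))
  want <- quietly(oracle_dedupe(blocks, 0.95))
  expect_identical(vapply(got, `[[`, "", "id"), vapply(want, `[[`, "", "id"))
  # idempotent and pairwise sub-threshold
  again <- quietly(dedupe_by_similarity(got, 0.95))
  expect_identical(vapply(again, `[[`, "", "id"), vapply(got, `[[`, "", "id"))
  fps <- quietly(lapply(got, function(b) fingerprint(b$mol)))
  for (i in seq_along(fps)) {
    for (j in seq_len(i - 1L)) {
      expect_lt(tanimoto(fps[[i]], fps[[j]]), 0.95)
    }
  }
})

test_that("attachment points are hydrogenated C/N/O/S atoms in canonical order", {
  expect_identical(attachment_points(quietly(parse_molecule("C", "methane"))), 1L)
  expect_length(attachment_points(quietly(parse_molecule("c1ccccc1", "benzene"))), 6L)
  acl <- quietly(parse_molecule("CC(=O)Cl", "acetyl_chloride"))
  ap <- attachment_points(acl)
  expect_length(ap, 1L)
  expect_identical(acl$atoms$element[ap], "C")
  expect_gte(acl$atoms$n_h[ap], 1L)  # the methyl carbon only
})

test_that("coupling conserves atoms, builds the dibenzylamide topology, and enforces the budget", {
  sc <- quietly(oxazole_scaffold())
  expect_identical(heavy_atom_count(sc$mol), 9L)
  b1 <- quietly(mk_block("CN", "00000011"))     # methylamine fragment
  b2 <- quietly(mk_block("CO", "00000012"))     # methanol fragment
  cmp <- quietly(couple_blocks(sc, b1, 1L, b2, 1L))
  expect_identical(heavy_atom_count(cmp$mol), 9L + 2L + 2L)
  # two benzyl-type groups reproduce the dibenzylamide analog topology
  bz <- quietly(mk_block("Cc1ccccc1", "00000001"))
  diben <- quietly(couple_blocks(sc, bz, 1L, bz, 1L))
  ref <- quietly(parse_molecule("O=C(N(Cc1ccccc1)Cc1ccccc1)c1cnc(N)o1", "ref"))
  expect_identical(diben$mol$smiles, ref$smiles)
  big1 <- quietly(mk_block("CCCCCCCCC", "00000021"))   # 9 heavy
  big2 <- quietly(mk_block("CCCCCCCCCC", "00000022"))  # 10 heavy
  expect_error(couple_blocks(sc, big1, 1L, big2, 1L), "budget")
  expect_error(quietly(couple_blocks(sc, b1, 2L, b2, 1L)), "attachment")
})

test_that("enumeration equals the brute-force oracle on small block sets", {
  sc <- quietly(oxazole_scaffold())
  one <- quietly(list(mk_block("Cc1ccccc1", "00000001")))
  expect_length(quietly(enumerate_library(sc, one)), 1L)  # self-pair
  trio <- quietly(distinct_trio())
  lib <- quietly(enumerate_library(sc, trio))
  expect_length(lib, 6L)  # 3 self-pairs + 3 cross-pairs, no duplicates
  oracle <- quietly(oracle_enumerate(sc, trio))
  expect_identical(vapply(lib, `[[`, "", "identifier"),
                   vapply(oracle, `[[`, "", "identifier"))
  # multi-attachment-point set against the oracle, including the budget
  blocks <- quietly(list(
    mk_block("Cc1ccccc1", "00000031", c(1L, 3L)),
    mk_block("NCCCCO", "00000032", 1L),
    mk_block("CCCCCCCCCC", "00000033", 2L)))  # 10 heavy: pairs limited
  lib2 <- quietly(enumerate_library(sc, blocks))
  oracle2 <- quietly(oracle_enumerate(sc, blocks))
  expect_identical(vapply(lib2, `[[`, "", "identifier"),
                   vapply(oracle2, `[[`, "", "identifier"))
  # every emitted compound satisfies the R-group budget
  for (cmp in lib2) {
    expect_lte(heavy_atom_count(cmp$mol), 18L + 9L)
  }
})

test_that("coincident assemblies from symmetric attachment points are removed", {
  sc <- quietly(oxazole_scaffold())
  # para-substituted symmetric block: both CH3 attachment points give the
  # same product molecule
  xyl <- quietly(parse_molecule("Cc1ccc(C)cc1", "00000041"))
  methyls <- which(xyl$atoms$element == "C" & xyl$atoms$n_h == 3L)
  sym <- building_block(xyl, methyls)
  lib <- quietly(enumerate_library(sc, list(sym)))
  smis <- vapply(lib, function(x) x$mol$smiles, "")
  expect_identical(anyDuplicated(smis), 0L)
  expect_lt(length(lib), 3L)  # naive ap-pair count would be 3
})

test_that("reservoir sampling is seed-reproducible and near-uniform", {
  sc <- quietly(oxazole_scaffold())
  trio <- quietly(distinct_trio())
  lib <- quietly(enumerate_library(sc, trio))
  all6 <- sample_library(lib, length(lib), seed = 1)
  expect_setequal(vapply(all6, `[[`, "", "identifier"),
                  vapply(lib, `[[`, "", "identifier"))
  s1 <- sample_library(lib, 3, seed = 99)
  s2 <- sample_library(lib, 3, seed = 99)
  expect_identical(vapply(s1, `[[`, "", "identifier"),
                   vapply(s2, `[[`, "", "identifier"))
  expect_error(sample_library(lib, 10, seed = 1), "stream holds")
  # uniformity: each of 6 compounds appears in a 3-of-6 sample with
  # frequency 1/2 across seeds
  counts <- setNames(numeric(length(lib)), vapply(lib, `[[`, "", "identifier"))
  reps <- 2000L
  for (s in seq_len(reps)) {
    picked <- vapply(sample_library(lib, 3, seed = s), `[[`, "", "identifier")
    counts[picked] <- counts[picked] + 1
  }
  expect_true(all(abs(counts / reps - 0.5) < 0.05))
})

test_that("identifiers follow the ao-R1-R2-combination scheme and round-trip", {
  sc <- quietly(oxazole_scaffold())
  b1 <- quietly(mk_block("Cc1ccccc1", "ZINC02168779"))
  b2 <- quietly(mk_block("NCCCCO", "ZINC40448781"))
  cmp <- quietly(couple_blocks(sc, b1, 1L, b2, 1L, combination = 0L))
  expect_identical(compound_identifier(cmp), "ao-02168779-40448781-0000")
  parsed <- parse_compound_identifier("ao-00403318-01672846-0002")
  expect_identical(parsed, list(r1 = "00403318", r2 = "01672846",
                                combination = 2L))
  # 3-digit combination fields (as printed in older tables) also parse
  expect_identical(parse_compound_identifier("ao-02168779-40448781-000")$combination, 0L)
  expect_error(parse_compound_identifier("zn-1-2-000"), "unparsable")
})
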