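# Seeded generators for every input the pipeline consumes: building blocks
# with plantable similarity families, multi-isoform docking records with a
# latent-quality model, sequence profiles, and toy 3D complexes with
# prescribed contact geometries. All generators are bit-reproducible under a
# fixed seed and thread seeds explicitly (no global RNG state is disturbed).

#' Simulation parameters for synthetic docking records
#'
#' The generator emulates the data-generating situation of the screening
#' stage: per-compound latent quality shared across isoforms within a Gram
#' group, a tunable correlation between the Gram-negative and Gram-positive
#' latent components, independent per-isoform anchor-pass events, and
#' optional planted building-block clusters whose compounds get a quality
#' boost in one group.
#'
#' @param seed Integer seed.
#' @param isoforms Isoform table (default [bc_isoforms()]).
#' @param anchor_pass_prob Per-isoform probability that the anchor docks
#'   within 2 Angstrom (default 0.755, the per-docking accuracy estimated
#'   from the screening counts).
#' @param group_correlation Correlation `rho` between the Gram-negative and
#'   Gram-positive latent quality components (default 0.8), induced through
#'   a shared factor: `q_group = sqrt(rho) * common + sqrt(1 - rho) *
#'   specific`.
#' @param planted_clusters List of planted effects; each element is a list
#'   with `blocks` (block ids), `position` (`"R1"`/`"R2"`), `group`
#'   (`"gram_negative"`/`"gram_positive"`) and `effect` (latent-quality
#'   units).
#' @param score_noise_sd Standard deviation of per-isoform, per-score noise
#'   (default 0.1).
#' @return A `simulation_params` list.
#' @export
simulation_params <- function(seed = 1L, isoforms = bc_isoforms(),
                              anchor_pass_prob = 0.755,
                              group_correlation = 0.8,
                              planted_clusters = list(),
                              score_noise_sd = 0.1) {
  if (anchor_pass_prob <= 0 || anchor_pass_prob > 1) {
    stop("anchor_pass_prob must lie in (0, 1]")
  }
  if (group_correlation < -1 || group_correlation > 1) {
    stop("group_correlation must lie in [-1, 1]")
  }
  if (score_noise_sd < 0) stop("score_noise_sd must be non-negative")
  for (pc in planted_clusters) {
    if (!all(c("blocks", "position", "group", "effect") %in% names(pc))) {
      stop("each planted cluster needs blocks, position, group, effect")
    }
    if (!is.finite(pc$effect)) stop("planted effect sizes must be finite")
  }
  structure(list(seed = as.integer(seed), isoforms = isoforms,
                 anchor_pass_prob = anchor_pass_prob,
                 group_correlation = group_correlation,
                 planted_clusters = planted_clusters,
                 score_noise_sd = score_noise_sd),
            class = "simulation_params")
}

#' Generate building blocks from the bundled fragment pool
#'
#' Deterministically samples curated organic fragments (6-12 heavy atoms,
#' grouped into structural families) and optionally inflates each family
#' with near-duplicate variants, which makes similarity structure available
#' for dedupe and clustering tests. Variants are created by coupling a small
#' decoration (methyl or fluorine) at varying attachment points of the
#' family's base fragment.
#'
#' @param n Number of blocks to return (ignored when `n_families` is given).
#' @param seed Integer seed.
#' @param heavy_range Inclusive heavy-atom bounds applied to the output
#'   (default `c(6, 12)`).
#' @param n_families If set, sample this many families instead and emit
#'   `variants_per_family` blocks from each.
#' @param variants_per_family Variants per family (default 5).
#' @param max_attachment_points Cap on attachment points per block (keeps
#'   combinatorial enumeration tractable; default 2).
#' @return List of `oxa_block` objects.
#' @export
generate_building_blocks <- function(n = 50L, seed = 1L,
                                     heavy_range = c(6L, 12L),
                                     n_families = NULL,
                                     variants_per_family = 5L,
                                     max_attachment_points = 2L) {
  pool <- read_smiles_file(.extdata("fragment_pool.smi"))
  fam <- as.integer(vapply(pool, function(m) m$id, "")) %/% 1000L
  pool <- lapply(pool, identity)
  keep <- vapply(pool, function(m) {
    h <- heavy_atom_count(m)
    h >= heavy_range[1] && h <= heavy_range[2]
  }, TRUE)
  pool <- pool[keep]; fam <- fam[keep]
  .with_seed(seed, {
    if (!is.null(n_families)) {
      fams <- sample(unique(fam), n_families)
      mols <- list()
      for (f in fams) {
        base <- pool[fam == f]
        base_mol <- base[[sample.int(length(base), 1L)]]
        mols <- c(mols, .family_variants(base_mol, variants_per_family,
                                         heavy_range))
      }
    } else {
      if (n > length(pool)) {
        stop(sprintf("requested %d blocks but the pool holds %d after the size filter",
                     n, length(pool)))
      }
      mols <- pool[sort(sample.int(length(pool), n))]
    }
    lapply(mols, function(m) {
      aps <- attachment_points(m)
      building_block(m, utils::head(aps, max_attachment_points))
    })
  })
}

# Near-duplicate variants of a base fragment: the base itself plus copies
# decorated with a methyl or fluorine at successive attachment points.
.family_variants <- function(base_mol, k, heavy_range) {
  out <- list(base_mol)
  aps <- attachment_points(base_mol)
  decos <- c("C", "F")
  tokens <- .smiles_atom_tokens(base_mol$smiles)
  v <- 1L
  for (deco in decos) {
    for (ap in aps) {
      if (length(out) >= k) break
      lab <- .smiles_attach_label(base_mol$smiles, tokens, ap, "%93")
      smi <- paste0(lab, ".", deco, "%93")
      id <- sprintf("%s%02d", base_mol$id, v)  # numeric suffix kept parseable
      m <- tryCatch(parse_molecule(smi, id), error = function(e) NULL)
      v <- v + 1L
      if (is.null(m)) next
      h <- heavy_atom_count(m)
      if (h < heavy_range[1] || h > heavy_range[2]) next
      if (m$smiles %in% vapply(out, function(x) x$smiles, "")) next
      out[[length(out) + 1L]] <- m
    }
    if (length(out) >= k) break
  }
  out[seq_len(min(k, length(out)))]
}

#' Generate synthetic multi-isoform docking records
#'
#' Latent-quality model: each compound draws a shared standard-normal factor
#' and group-specific factors combined as `q_group = sqrt(rho) * common +
#' sqrt(1 - rho) * specific`, so the two Gram groups' qualities correlate at
#' `rho`. Planted clusters add their effect size to the stated group's
#' quality for compounds carrying a member block at the stated position.
#' Within a group, each isoform's four scores are monotone maps of the group
#' quality plus independent Gaussian noise, oriented to honour
#' [score_directions()]: affinity decreases with quality (lower is better),
#' fitness and binding are logistic in quality, energy increases with
#' quality. Anchor RMSDs are drawn so that `P(anchor_rmsd <= 2) =
#' anchor_pass_prob` independently per isoform.
#'
#' @param compound_ids Character vector of compound identifiers in the
#'   `ao-<R1>-<R2>-<combination>` scheme (block membership for planting is
#'   parsed from them).
#' @param params A [simulation_params()] object.
#' @return Docking-record data frame (`length(compound_ids)` x isoforms
#'   rows).
#' @export
generate_docking_records <- function(compound_ids, params) {
  stopifnot(inherits(params, "simulation_params"))
  n <- length(compound_ids)
  iso <- params$isoforms
  rho <- params$group_correlation
  parts <- .split_identifiers(compound_ids)
  .with_seed(params$seed, {
    common <- stats::rnorm(n)
    q <- list(
      negative = sqrt(rho) * common + sqrt(1 - rho) * stats::rnorm(n),
      positive = sqrt(rho) * common + sqrt(1 - rho) * stats::rnorm(n))
    for (pc in params$planted_clusters) {
      codes <- vapply(pc$blocks, .block_code, "")
      carried <- if (pc$position == "R1") parts$r1 %in% codes else
        parts$r2 %in% codes
      grp <- if (pc$group == "gram_negative") "negative" else "positive"
      q[[grp]][carried] <- q[[grp]][carried] + pc$effect
    }
    rows <- vector("list", nrow(iso))
    for (k in seq_len(nrow(iso))) {
      qg <- q[[iso$gram[k]]]
      noise <- function() stats::rnorm(n, sd = params$score_noise_sd)
      pass <- stats::runif(n) <= params$anchor_pass_prob
      rmsd <- ifelse(pass, stats::runif(n, 0, 2), stats::runif(n, 2.0001, 8))
      rows[[k]] <- data.frame(
        compound_id = compound_ids,
        isoform = iso$code[k],
        anchor_rmsd = rmsd,
        affinity = -(qg + noise()),
        fitness = stats::plogis(qg + noise()),
        binding = stats::plogis(qg + noise()),
        energy = 40 + 15 * (qg + noise()))
    }
    validate_docking_records(do.call(rbind, rows))
  })
}

#' Synthetic compound identifiers from block pairs
#'
#' Uniformly pairs blocks at R1 and R2 (with replacement across compounds)
#' and formats identifiers in the `ao-<R1>-<R2>-<combination>` scheme;
#' duplicated pairs get increasing combination numbers.
#'
#' @param blocks List of `oxa_block` objects (or character block ids).
#' @param n Number of compounds.
#' @param seed Integer seed.
#' @return Character vector of `n` unique identifiers.
#' @export
generate_compound_ids <- function(blocks, n, seed = 1L) {
  ids <- if (is.character(blocks)) blocks else
    vapply(blocks, function(b) b$id, "")
  .with_seed(seed, {
    r1 <- sample(ids, n, replace = TRUE)
    r2 <- sample(ids, n, replace = TRUE)
    key <- paste(r1, r2)
    comb <- stats::ave(seq_len(n), key, FUN = seq_along) - 1L
    vapply(seq_len(n), function(i) .format_identifier(r1[i], r2[i], comb[i]), "")
  })
}

#' Generate a synthetic sequence profile
#'
#' Conserved positions get a near-point-mass on one residue; all other
#' positions draw Dirichlet(concentration x background) frequencies, so the
#' profile interpolates between strong conservation (small concentration
#' with a point mass) and the background composition (large concentration).
#'
#' @param n_positions Number of positions.
#' @param conserved_positions Integer positions made near-invariant.
#' @param concentration Dirichlet concentration multiplier (> 0).
#' @param seed Integer seed.
#' @param background Background composition (default: bundled).
#' @return An `oxa_profile`.
#' @export
generate_profile <- function(n_positions, conserved_positions = integer(),
                             concentration = 5, seed = 1L,
                             background = background_composition()) {
  if (concentration <= 0) stop("concentration must be positive")
  bg <- background / sum(background)
  .with_seed(seed, {
    freq <- t(vapply(seq_len(n_positions), function(i) {
      g <- stats::rgamma(20, shape = concentration * 20 * bg)
      g / sum(g)
    }, numeric(20)))
    for (p in conserved_positions) {
      v <- rep(1e-4 / 19, 20)
      v[sample.int(20, 1L)] <- 1 - 1e-4
      freq[p, ] <- v
    }
    .new_profile(seq_len(n_positions), freq)
  })
}

.COMPLEX_CLASSES <- c("hbond", "halogen_bond", "aromatic", "hydrophobic",
                      "destabilizing")

#' Generate a toy complex realizing prescribed contacts
#'
#' Places one protein probe site per prescribed residue along the x axis
#' (15 Angstrom apart, far beyond every cutoff) and a ligand atom or ring
#' at the geometry that realizes exactly the prescribed contact class under
#' the default cutoffs and no others. Aromatic prescriptions place full
#' six-membered rings (a stacked pair), so they yield one or more contacts,
#' all aromatic; every other class yields exactly one contact.
#'
#' @param prescription Data frame (or list of pairs) with columns
#'   `residue_number` and `contact_class`.
#' @param seed Integer seed (reserved for future jitter; geometry is
#'   deterministic).
#' @return An `oxa_complex` (writable with [write_complex_pdb()]).
#' @export
generate_complex <- function(prescription, seed = 1L) {
  if (is.list(prescription) && !is.data.frame(prescription)) {
    prescription <- do.call(rbind, lapply(prescription, function(p) {
      data.frame(residue_number = p[[1]], contact_class = p[[2]])
    }))
  }
  if (is.null(prescription) || !nrow(prescription)) {
    prescription <- data.frame(residue_number = integer(),
                               contact_class = character())
  }
  bad <- setdiff(prescription$contact_class, .COMPLEX_CLASSES)
  if (length(bad)) {
    stop(sprintf("unsupported contact class(es): %s",
                 paste(unique(bad), collapse = ", ")))
  }
  if (anyDuplicated(prescription$residue_number)) {
    stop("unsatisfiable prescription: one contact class per residue probe")
  }
  prot <- list(); lig <- list()
  hexagon <- function(cx, cy, cz, r = 1.39) {
    th <- seq(0, by = pi / 3, length.out = 6)
    cbind(cx + r * cos(th), cy + r * sin(th), cz)
  }
  lig_serial <- 0L
  for (k in seq_len(nrow(prescription))) {
    rn <- as.integer(prescription$residue_number[k])
    cls <- prescription$contact_class[k]
    x <- 15 * k
    if (cls == "hbond") {
      prot[[k]] <- data.frame(residue_name = "SER", atom_name = "OG",
                              element = "O", x = x, y = 0, z = 0,
                              residue_number = rn)
      lig[[k]] <- data.frame(element = "O", x = x, y = 2.9, z = 0)
    } else if (cls == "halogen_bond") {
      prot[[k]] <- data.frame(residue_name = "GLY", atom_name = "N",
                              element = "N", x = x, y = 0, z = 0,
                              residue_number = rn)
      lig[[k]] <- data.frame(element = "Cl", x = x, y = 3.2, z = 0)
    } else if (cls == "aromatic") {
      ph <- hexagon(x, 0, 0)
      prot[[k]] <- data.frame(
        residue_name = "PHE",
        atom_name = c("CG", "CD1", "CE1", "CZ", "CE2", "CD2"),
        element = "C", x = ph[, 1], y = ph[, 2], z = ph[, 3],
        residue_number = rn)
      lr <- hexagon(x, 0, 3.6)
      lig[[k]] <- data.frame(element = "C", x = lr[, 1], y = lr[, 2],
                             z = lr[, 3])
    } else if (cls == "hydrophobic") {
      prot[[k]] <- data.frame(residue_name = "LEU", atom_name = "CD1",
                              element = "C", x = x, y = 0, z = 0,
                              residue_number = rn)
      lig[[k]] <- data.frame(element = "C", x = x, y = 4.0, z = 0)
    } else { # destabilizing
      prot[[k]] <- data.frame(residue_name = "LEU", atom_name = "CD1",
                              element = "C", x = x, y = 0, z = 0,
                              residue_number = rn)
      lig[[k]] <- data.frame(element = "O", x = x, y = 3.5, z = 0)
    }
  }
  pdf <- if (length(prot)) do.call(rbind, prot) else
    data.frame(residue_name = character(), atom_name = character(),
               element = character(), x = numeric(), y = numeric(),
               z = numeric(), residue_number = integer())
  # an anchor protein atom far from everything keeps empty prescriptions valid
  pdf <- rbind(pdf, data.frame(residue_name = "GLY", atom_name = "CA",
                               element = "C", x = -100, y = 0, z = 0,
                               residue_number = 1L))
  ldf <- if (length(lig)) do.call(rbind, lig) else
    data.frame(element = character(), x = numeric(), y = numeric(),
               z = numeric())
  ldf <- rbind(ldf, data.frame(element = "C", x = -100, y = 50, z = 0))
  ldf$residue_number <- 9001L
  ldf$residue_name <- "LIG"
  ldf$atom_name <- paste0(ldf$element, seq_len(nrow(ldf)))
  psites <- pdf[, c("element", "x", "y", "z", "residue_number",
                    "residue_name", "atom_name")]
  psites <- cbind(psites, .protein_roles(psites$residue_name,
                                         psites$atom_name, psites$element))
  lsites <- ldf[, c("element", "x", "y", "z", "residue_number",
                    "residue_name", "atom_name")]
  lsites <- cbind(lsites,
                  .ligand_roles(lsites$element,
                                as.matrix(lsites[, c("x", "y", "z")])))
  structure(list(protein = psites, ligand = lsites), class = "oxa_complex")
}
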