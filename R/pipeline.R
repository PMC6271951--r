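# Orchestration: configuration, stage execution in dependency order, and
# report generation.

.CONFIG_DEFAULTS <- list(
  seed = 1L,
  stages = c("library", "postprocess", "enrichment", "interactions",
             "conservation"),
  blocks_file = NULL,       # SMILES file of building blocks; NULL = synthetic
  records_file = NULL,      # docking-record TSV; NULL = synthetic
  n_blocks = 40L,           # synthetic blocks drawn from the bundled pool
  n_compounds = 2000L,      # compounds carried into the screening stage
  assemble = FALSE,         # TRUE: reservoir-sample assembled molecules
  min_heavy = 6L,
  max_heavy = 12L,
  dedupe_threshold = 0.95,
  budget = 18L,
  anchor_cutoff = 2.0,
  cluster_threshold = 0.7,
  alpha = 20,
  delta_flag = 0.05,
  anchor_pass_prob = 0.755,
  group_correlation = 0.8,
  score_noise_sd = 0.1,
  n_complexes = 5L
)

#' Load a pipeline configuration file
#'
#' Plain-text `key: value` (YAML) configuration; missing keys take
#' documented defaults, unknown keys are rejected, and values are validated
#' against their constraints. An empty file yields the full default
#' configuration.
#'
#' @param path Configuration file path, or `NULL` for pure defaults.
#' @return A validated `oxa_config` list.
#' @export
load_config <- function(path = NULL) {
  user <- list()
  if (!is.null(path)) {
    if (!file.exists(path)) stop(sprintf("config file not found: %s", path))
    user <- yaml::read_yaml(path)
    if (is.null(user)) user <- list()
  }
  unknown <- setdiff(names(user), names(.CONFIG_DEFAULTS))
  if (length(unknown)) {
    stop(sprintf("unknown config key(s): %s", paste(unknown, collapse = ", ")))
  }
  cfg <- .CONFIG_DEFAULTS
  cfg[names(user)] <- user
  validate_config(cfg)
}

#' Validate a pipeline configuration
#'
#' @param cfg Named list of configuration values.
#' @return The configuration with class `oxa_config`.
#' @export
validate_config <- function(cfg) {
  chk <- function(ok, key, constraint) {
    if (!ok) stop(sprintf("config key '%s' violates constraint: %s",
                          key, constraint))
  }
  chk(all(cfg$stages %in% .CONFIG_DEFAULTS$stages), "stages",
      "subset of library, postprocess, enrichment, interactions, conservation")
  chk(is.numeric(cfg$seed) && cfg$seed == as.integer(cfg$seed), "seed",
      "integer")
  chk(cfg$min_heavy >= 1 && cfg$max_heavy >= cfg$min_heavy, "min_heavy/max_heavy",
      "1 <= min_heavy <= max_heavy")
  chk(cfg$dedupe_threshold > 0 && cfg$dedupe_threshold <= 1, "dedupe_threshold",
      "in (0, 1]")
  chk(cfg$cluster_threshold > 0 && cfg$cluster_threshold <= 1,
      "cluster_threshold", "in (0, 1]")
  chk(cfg$budget >= 2, "budget", ">= 2 heavy atoms")
  chk(cfg$anchor_cutoff > 0, "anchor_cutoff", "> 0 Angstrom")
  chk(cfg$alpha > 0, "alpha", "> 0")
  chk(cfg$delta_flag >= 0, "delta_flag", ">= 0")
  chk(cfg$anchor_pass_prob > 0 && cfg$anchor_pass_prob <= 1,
      "anchor_pass_prob", "in (0, 1]")
  chk(cfg$group_correlation >= -1 && cfg$group_correlation <= 1,
      "group_correlation", "in [-1, 1]")
  chk(cfg$score_noise_sd >= 0, "score_noise_sd", ">= 0")
  chk(cfg$n_blocks >= 2, "n_blocks", ">= 2")
  chk(cfg$n_compounds >= 10, "n_compounds", ">= 10")
  chk(cfg$n_complexes >= 0, "n_complexes", ">= 0")
  structure(cfg, class = "oxa_config")
}

#' Write a configuration to a YAML file
#'
#' @param cfg An `oxa_config` (or plain list).
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' Run the redesign pipeline
#'
#' Executes the enabled stages in dependency order -- library construction,
#' docking post-processing, R-group enrichment, interaction profiling --
#' plus the independent conservation stage, exchanging data between stages
#' through files in `out_dir`. Every source of randomness derives from
#' `cfg$seed`, so re-running with an identical configuration reproduces
#' identical outputs.
#'
#' @param cfg An `oxa_config` from [load_config()].
#' @param out_dir Output directory (created if needed).
#' @return The run report (also written to `report.json`): per-stage record
#'   counts, the anchor pass fraction and implied docking accuracy, the
#'   Gram-negative vs Gram-positive consensus rank correlation, enrichment
#'   summaries, and stage timings.
#' @export
run_pipeline <- function(cfg, out_dir) {
  stopifnot(inherits(cfg, "oxa_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seeds <- .child_seeds(cfg$seed, 6L)
  report <- list(seed = cfg$seed, stages = list())
  t_stage <- function(expr) {
    t0 <- proc.time()[["elapsed"]]
    v <- force(expr)
    list(value = v, seconds = round(proc.time()[["elapsed"]] - t0, 2))
  }
  blocks <- NULL
  compound_ids <- NULL

  if ("library" %in% cfg$stages) {
    st <- t_stage({
      raw <- if (!is.null(cfg$blocks_file)) {
        lapply(read_smiles_file(cfg$blocks_file), building_block)
      } else {
        generate_building_blocks(cfg$n_blocks, seed = seeds[1],
                                 heavy_range = c(cfg$min_heavy, cfg$max_heavy))
      }
      filt <- filter_blocks(raw, cfg$min_heavy, cfg$max_heavy)
      dd <- dedupe_by_similarity(filt, cfg$dedupe_threshold)
      write_smiles_file(lapply(dd, `[[`, "mol"), file.path(out_dir, "blocks.smi"))
      list(raw = raw, deduped = dd)
    })
    blocks <- st$value$deduped
    if (cfg$assemble) {
      stream <- library_stream(oxazole_scaffold(), blocks, cfg$budget,
                               cfg$dedupe_threshold)
      compounds <- sample_library(stream, cfg$n_compounds, seeds[2])
      manifest <- library_manifest(compounds)
      compound_ids <- manifest$identifier
    } else {
      compound_ids <- generate_compound_ids(blocks, cfg$n_compounds, seeds[2])
      manifest <- .split_identifiers(compound_ids)
    }
    .write_tsv(manifest, file.path(out_dir, "library_manifest.tsv"))
    report$stages$library <- list(
      seconds = st$seconds, blocks_in = length(st$value$raw),
      blocks_deduped = length(blocks), compounds = length(compound_ids))
  }

  records <- NULL
  rankings <- NULL
  if ("postprocess" %in% cfg$stages) {
    if (is.null(cfg$records_file) && is.null(compound_ids)) {
      stop("stage 'postprocess' is missing upstream output of stage 'library'")
    }
    st <- t_stage({
      recs <- if (!is.null(cfg$records_file)) {
        read_docking_records(cfg$records_file)
      } else {
        generate_docking_records(compound_ids, simulation_params(
          seed = seeds[3], anchor_pass_prob = cfg$anchor_pass_prob,
          group_correlation = cfg$group_correlation,
          score_noise_sd = cfg$score_noise_sd))
      }
      write_docking_records(recs, file.path(out_dir, "docking_records.tsv"))
      isoset <- intersect(bc_isoforms()$code, unique(recs$isoform))
      pass <- anchor_consistency_filter(recs, isoset, cfg$anchor_cutoff)
      writeLines(pass, file.path(out_dir, "anchor_pass_ids.txt"))
      passed <- recs[recs$compound_id %in% pass, , drop = FALSE]
      rks <- consensus_rankings(passed)
      for (g in names(rks)) {
        write_ranking(rks[[g]], file.path(out_dir, sprintf("ranking_%s.tsv", g)))
      }
      n_scr <- length(unique(recs$compound_id))
      f <- length(pass) / n_scr
      list(records = recs, pass = pass, rankings = rks,
           screened = n_scr, f = f,
           accuracy = if (f > 0) docking_accuracy(f, length(isoset)) else NA,
           corr = if (length(pass) >= 2)
             rank_correlation(rks$gram_negative, rks$gram_positive) else NA)
    })
    records <- st$value$records
    rankings <- st$value$rankings
    report$stages$postprocess <- list(
      seconds = st$seconds, records = nrow(records),
      screened = st$value$screened, passed = length(st$value$pass),
      pass_fraction = st$value$f,
      accuracy_estimate = st$value$accuracy,
      rank_correlation_neg_pos = st$value$corr)
  }

  if ("enrichment" %in% cfg$stages) {
    if (is.null(rankings)) {
      stop("stage 'enrichment' is missing upstream output of stage 'postprocess'")
    }
    if (is.null(blocks)) {
      stop("stage 'enrichment' is missing upstream output of stage 'library'")
    }
    st <- t_stage({
      cl <- cluster_blocks(blocks, cfg$cluster_threshold)
      .write_tsv(cl, file.path(out_dir, "block_clusters.tsv"))
      cells <- enrichment_cells(rankings[c("gram_negative", "gram_positive")],
                                cl, alpha = cfg$alpha)
      .write_tsv(cells, file.path(out_dir, "enrichment_cells.tsv"))
      dB <- delta_bedroc(cells, cfg$delta_flag)
      .write_tsv(dB, file.path(out_dir, "delta_bedroc.tsv"))
      list(clusters = max(cl$cluster_id), cells = nrow(cells),
           flagged = sum(dB$flagged, na.rm = TRUE))
    })
    report$stages$enrichment <- c(list(seconds = st$seconds), st$value)
  }

  if ("interactions" %in% cfg$stages && cfg$n_complexes > 0) {
    st <- t_stage({
      site <- load_binding_site_table()
      res_pool <- site$residue_number
      classes <- .COMPLEX_CLASSES
      cseeds <- .child_seeds(seeds[4], cfg$n_complexes)
      contact_sets <- lapply(seq_len(cfg$n_complexes), function(i) {
        pres <- .with_seed(cseeds[i], {
          k <- sample(2:4, 1)
          data.frame(residue_number = sample(res_pool, k),
                     contact_class = sample(classes, k, replace = TRUE))
        })
        detect_contacts(generate_complex(pres, seed = cseeds[i]))
      })
      prof <- residue_profiles(contact_sets, res_pool)
      .write_tsv(prof, file.path(out_dir, "residue_profiles.tsv"))
      hal <- halogen_contributions(contact_sets)
      .write_tsv(hal, file.path(out_dir, "halogen_shares.tsv"))
      list(complexes = cfg$n_complexes,
           contacts = sum(vapply(contact_sets, nrow, 0L)),
           halogen_bonds = sum(hal$n_halogen_bonds))
    })
    report$stages$interactions <- c(list(seconds = st$seconds), st$value)
  }

  if ("conservation" %in% cfg$stages) {
    st <- t_stage({
      site <- load_binding_site_table()
      summ <- entropy_summary(site$entropy)
      site$conservation <- vapply(seq_len(nrow(site)), function(i) {
        classify_position_conservation(site[i, ])
      }, "")
      .write_tsv(site, file.path(out_dir, "binding_site_conservation.tsv"))
      list(positions = nrow(site), mean_entropy = summ$mean,
           sd_entropy = summ$sd,
           background_entropy = background_max_entropy(),
           gram_specific = site$residue_number[site$conservation == "gram_specific"])
    })
    report$stages$conservation <- c(list(seconds = st$seconds), st$value)
  }

  skipped <- setdiff(.CONFIG_DEFAULTS$stages, cfg$stages)
  if (length(skipped)) report$skipped_stages <- skipped
  jsonlite::write_json(report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(report)
}
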