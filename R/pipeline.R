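# End-to-end orchestration: simulate -> screen -> splice -> rnamap ->
# tissue -> gsea, with a shared validated configuration and a run
# manifest recording seeds, parameters and per-stage status.

#' Default pipeline configuration
#'
#' Nested list of every tunable parameter of every stage, with the
#' published values as defaults where the study states them (cutoffs
#' +/- 2 SD; NPI < 0.8 with p <= 0.05 and >= 2 siRNAs; k = 4 clusters;
#' 20% splice change with FDR < 0.05; 31-nt windows; CPM sum > 10).
#' Problem sizes default to desk-scale values.
#'
#' @return Named nested list.
#' @export
defaultConfig <- function() {
  list(
    seed = 1L,
    screen = list(n_genes = 352L, planted_down = 10L, effect = -4,
                  noise_sd = 1, row_sd = 0.5, col_sd = 0.5,
                  down_cutoff = -2, up_cutoff = 2, min_replicates = 2L,
                  as_printed = FALSE, npi_cutoff = 0.8, alpha = 0.05,
                  k = 4L, n_init = 10L),
    splicing = list(n_events = 400L, coverage = 100L, delta_psi = 0.3,
                    prop_repressed = 0.15, prop_enhanced = 0.1,
                    delta_cutoff = 0.2, strict_cutoff = 0.3,
                    fdr_cutoff = 0.05),
    rnamap = list(flank = 300L, exon_into = 50L, window = 31L,
                  step = 1L, p_threshold = 1e-3),
    tissue = list(n_genes = 1000L, n_samples = 200L,
                  enriched_set_size = 50L, n_decoy_sets = 20L,
                  cpm_threshold = 10, n_perm = 200L)
  )
}

.checkConfig <- function(config, template, path = "") {
  unknown <- setdiff(names(config), names(template))
  if (length(unknown) > 0)
    stop(sprintf("config error: unknown key(s) %s",
                 paste0(path, unknown, collapse = ", ")))
  for (nm in names(config))
    if (is.list(template[[nm]]))
      .checkConfig(config[[nm]], template[[nm]], paste0(path, nm, "."))
  invisible(TRUE)
}

#' Read and validate a run configuration
#'
#' Reads a YAML configuration and merges it over [defaultConfig()];
#' unknown keys are rejected before any stage runs.
#'
#' @param path YAML file path, or `NULL` for the defaults.
#' @param overrides named list merged last (e.g. parsed flags).
#' @return Validated configuration list.
#' @export
readRunConfig <- function(path = NULL, overrides = NULL) {
  config <- defaultConfig()
  merge_in <- function(base, extra, tpl) {
    .checkConfig(extra, tpl)
    for (nm in names(extra)) {
      base[[nm]] <- if (is.list(tpl[[nm]]))
        merge_in(base[[nm]], extra[[nm]], tpl[[nm]]) else extra[[nm]]
    }
    base
  }
  if (!is.null(path)) {
    user <- yaml::read_yaml(path)
    config <- merge_in(config, user, defaultConfig())
  }
  if (!is.null(overrides))
    config <- merge_in(config, overrides, defaultConfig())
  config
}

.stage <- function(manifest, name, fun) {
  t0 <- proc.time()[["elapsed"]]
  res <- tryCatch(list(value = fun(), status = "ok", error = NA_character_),
                  error = function(e)
                    list(value = NULL, status = "failed",
                         error = conditionMessage(e)))
  manifest$stages[[name]] <- list(
    status = res$status, error = res$error,
    elapsed_s = round(proc.time()[["elapsed"]] - t0, 3))
  manifest$value[[name]] <- res$value
  manifest
}

#' Run the full pipeline on simulated data
#'
#' Executes the stages in dependency order (screen simulation and
#' normalization -> hit calling and clustering -> splicing simulation,
#' delta-PSI testing and shortlisting -> motif scan and RNA map ->
#' tissue simulation, filtering, normalization, dichotomization,
#' ranking -> GSEA), writes TSV outputs and a JSON run manifest, and
#' stops downstream stages on a failure (recorded in the manifest).
#'
#' @param config configuration from [readRunConfig()] /
#'   [defaultConfig()].
#' @param out_dir output directory (default: a temporary directory).
#' @param quiet suppress progress messages.
#' @return list: `manifest` (config snapshot, seeds, per-stage status
#'   and wall-clock), `results` (in-memory stage results), `out_dir`.
#' @export
runPipeline <- function(config = defaultConfig(), out_dir = tempfile("run"),
                        quiet = TRUE) {
  .checkConfig(config, defaultConfig())
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  note <- function(...) if (!quiet) message(sprintf(...))
  manifest <- list(config = config, seed = config$seed,
                   started = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
                   out_dir = out_dir, stages = list(), value = list())
  sc <- config$screen; sp <- config$splicing; rm_ <- config$rnamap
  ti <- config$tissue

  note("stage: screen")
  manifest <- .stage(manifest, "screen", function() {
    eff <- if (sc$planted_down > 0)
      data.frame(gene_id = sprintf("gene%05d", seq_len(sc$planted_down)),
                 IL8 = sc$effect, IL6 = sc$effect)
    else NULL
    sim <- simulateScreen(sc$n_genes, effect_table = eff,
                          artifact_spec = list(row_sd = sc$row_sd,
                                               col_sd = sc$col_sd),
                          noise_sd = sc$noise_sd, seed = config$seed)
    b <- do.call(rbind, lapply(c("IL8", "IL6", "p16", "p21", "BrdU"),
                               function(r) bScore(sim$plates, r)))
    hits <- callPrimaryHits(b, down_cutoff = sc$down_cutoff,
                            up_cutoff = sc$up_cutoff,
                            min_replicates = sc$min_replicates,
                            as_printed = sc$as_printed)
    writeResultsTsv(hits, file.path(out_dir, "primary_hits.tsv"))
    down <- hits$sirna_id[hits$direction == "down"]
    clusters <- NULL
    if (length(down) >= sc$k) {
      bd <- b[b$sirna_id %in% down & b$readout %in% c("p16", "p21",
                                                      "BrdU"), ]
      prof <- reshapeProfiles(bd)
      clusters <- kmeansCluster(prof, k = min(sc$k, nrow(prof)),
                                n_init = sc$n_init, seed = config$seed)
      roles <- labelClusters(clusters$centers)
      writeResultsTsv(roles, file.path(out_dir, "cluster_roles.tsv"))
    }
    list(sim = sim, bscores = b, hits = hits, clusters = clusters)
  })

  note("stage: splice")
  manifest <- .stage(manifest, "splice", function() {
    if (manifest$stages$screen$status != "ok")
      stop("upstream stage failed")
    sim <- simulateSplicing(
      sp$n_events,
      class_proportions = c(repressed = sp$prop_repressed,
                            enhanced = sp$prop_enhanced,
                            unchanged = 1 - sp$prop_repressed -
                              sp$prop_enhanced),
      coverage = sp$coverage, delta_psi = sp$delta_psi,
      flank_len = rm_$flank, seed = config$seed)
    jc <- sim$junction_counts
    rec <- deltaPsiTest(jc[jc$condition == "control", ],
                        jc[jc$condition == "knockdown", ],
                        "control", "knockdown")
    rec$fdr <- bhFdr(rec$p)
    rec <- classifyRegulation(rec, sp$delta_cutoff, sp$fdr_cutoff)
    writeResultsTsv(rec, file.path(out_dir, "delta_psi.tsv"))
    list(sim = sim, records = rec)
  })

  note("stage: rnamap")
  manifest <- .stage(manifest, "rnamap", function() {
    spl <- manifest$value$splice
    if (is.null(spl)) stop("upstream stage failed")
    up <- spl$sim$sequences[grepl("upstream_intron",
                                  names(spl$sim$sequences))]
    occ <- pwmScan(up, .defaultCuRichMotif(),
                   p_threshold = rm_$p_threshold)
    g_occ <- occurrencesToGenomic(occ, spl$sim$regions)
    anch <- anchorOccurrences(spl$sim$events, g_occ,
                              region_spec = list(
                                upstream = rm_$flank,
                                exon_into = rm_$exon_into,
                                downstream = rm_$flank))
    groups <- setNames(spl$records$regulation_class,
                       spl$records$event_id)
    map <- buildRnaMap(groups, anch,
                       axis_range = c(-rm_$flank, rm_$exon_into),
                       window = rm_$window, step = rm_$step)
    writeResultsTsv(windowSignificance(map),
                    file.path(out_dir, "rna_map_windows.tsv"))
    map
  })

  note("stage: tissue")
  manifest <- .stage(manifest, "tissue", function() {
    sim <- simulateTissueMatrix(
      n_genes = ti$n_genes, n_samples = ti$n_samples,
      enriched_set_size = ti$enriched_set_size, seed = config$seed)
    filt <- cpmFilter(sim$counts, threshold = ti$cpm_threshold)
    norm <- quantileNormalize(log2(filt + 1))
    dich <- dichotomizeByDensityMinimum(sim$psi)
    # high PSI = included; rank by skipping-high (= PSI-low) vs rest
    flip <- ifelse(dich$labels == "high", "low", "high")
    ranked <- rankGenesByT(norm, flip)
    writeResultsTsv(ranked, file.path(out_dir, "tissue_rank.tsv"))
    list(sim = sim, ranked = ranked, dichotomy = dich)
  })

  note("stage: gsea")
  manifest <- .stage(manifest, "gsea", function() {
    tis <- manifest$value$tissue
    if (is.null(tis)) stop("upstream stage failed")
    sets <- c(list(planted = tis$sim$truth$enriched_set),
              decoyGeneSets(tis$ranked$gene, ti$n_decoy_sets,
                            ti$enriched_set_size,
                            seed = config$seed))
    res <- gseaPreranked(tis$ranked, sets, n_perm = ti$n_perm,
                         seed = config$seed)
    writeResultsTsv(res, file.path(out_dir, "gsea.tsv"))
    res
  })

  manifest$finished <- format(Sys.time(), "%Y-%m-%dT%H:%M:%S")
  results <- manifest$value
  manifest$value <- NULL
  jsonlite::write_json(
    manifest[c("config", "seed", "started", "finished", "out_dir",
               "stages")],
    file.path(out_dir, "manifest.json"), auto_unbox = TRUE, digits = NA)
  list(manifest = manifest, results = results, out_dir = out_dir)
}

#' Reshape long B-scores to per-siRNA phenotype profiles
#'
#' Builds the feature matrix fed to [kmeansCluster()]: one row per
#' siRNA, one column per readout x replicate B-score.
#'
#' @param bscores long B-score data.frame ([bScore()] output, possibly
#'   stacked over readouts).
#' @return data.frame with `sirna_id` and `<readout>_r<replicate>`
#'   feature columns (fixed, recorded order).
#' @export
reshapeProfiles <- function(bscores) {
  b <- bscores[bscores$well_role == "sample", ]
  b$feature <- paste0(b$readout, "_r", b$replicate)
  wide <- reshape(b[, c("sirna_id", "feature", "b")],
                  idvar = "sirna_id", timevar = "feature",
                  direction = "wide")
  names(wide) <- sub("^b\\.", "", names(wide))
  feat <- sort(setdiff(names(wide), "sirna_id"))
  wide <- wide[, c("sirna_id", feat)]
  wide[complete.cases(wide), ]
}

#' Random decoy gene sets
#'
#' @param universe gene ids to draw from.
#' @param n_sets number of decoy sets.
#' @param set_size members per set.
#' @param seed integer seed.
#' @return Named list of character vectors.
#' @export
decoyGeneSets <- function(universe, n_sets, set_size, seed = 1L) {
  set.seed(.substream(seed, 5000L))
  sets <- lapply(seq_len(n_sets), function(i)
    sample(universe, set_size))
  names(sets) <- sprintf("decoy%02d", seq_len(n_sets))
  sets
}
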