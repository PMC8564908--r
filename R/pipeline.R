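#' Default pipeline configuration
#'
#' Builds the nested configuration list consumed by [runPipeline()]. In
#' `"simulate"` mode all inputs are generated by the synthetic-cohort
#' module under the configured specs; in `"run"` mode the `paths` entries
#' must point at existing TSV/CSV inputs and `cluster$sensitivity_features`
#' must name the features used to orient the cluster phenotype.
#'
#' @param mode `"simulate"` or `"run"`.
#' @param seed master seed; stage seeds are derived from it.
#' @param outDir run directory for all stage outputs.
#' @param ... named overrides merged over the defaults (nested lists are
#'   merged recursively).
#' @return a `PipelineConfig` list.
#' @export
pipelineConfig <- function(mode = c("simulate", "run"), seed = 1L,
                           outDir = tempfile("rppasig_run_"), ...) {
  mode <- match.arg(mode)
  base <- list(
    mode = mode, seed = as.integer(seed), out_dir = outDir,
    paths = list(protein = NULL, mrna = NULL, metadata = NULL,
                 growth = NULL, gene_map = NULL),
    cohort = list(), growth = list(),
    cluster = list(sensitivity_features = NULL),
    sweep = list(thresholds = seq(0.1, 1.5, by = 0.1), p_cut = 0.01,
                 svm_cost = 1),
    concord = list(n_resistant = 4, n_sensitive = 7, concordance = 0.7,
                   noise_sd = 0.3, n_permutations = 1000),
    ihc = list(n_sections_cr = 8, n_sections_pd = 8, n_cells = 2000,
               cav1_cr = 0.6, cav1_pd = 0.15, sox2_cr = 0.08,
               sox2_pd = 0.45, control_quantile = 0.99))
  mergeConfig(base, list(...))
}

mergeConfig <- function(base, override) {
  for (nm in names(override)) {
    if (is.list(base[[nm]]) && is.list(override[[nm]]))
      base[[nm]] <- mergeConfig(base[[nm]], override[[nm]])
    else base[[nm]] <- override[[nm]]
  }
  base
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file; keys override [pipelineConfig()] defaults.
#' @return a `PipelineConfig` list.
#' @export
readPipelineConfig <- function(path) {
  if (!file.exists(path))
    inputError(sprintf("config file '%s' does not exist", path))
  y <- yaml::read_yaml(path)
  mode <- y$mode %||% "simulate"
  seed <- y$seed %||% 1L
  out <- y$out_dir %||% tempfile("rppasig_run_")
  y$mode <- NULL; y$seed <- NULL; y$out_dir <- NULL
  do.call(pipelineConfig, c(list(mode = mode, seed = seed, outDir = out), y))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the full signature-discovery pipeline
#'
#' Executes, in order: input simulation or loading, Ward bi-clustering with
#' phenotype labeling, in-vivo response calling and prediction scoring with
#' covariate association, the fold-change threshold sweep with SVM
#' evaluation and signature selection/finalization, external-cohort
#' fold-change concordance with a permutation control, and IHC section
#' scoring with the two-marker difference metric. Every stage writes its
#' tables under `out_dir`, and a `manifest.json` records the config hash,
#' master seed and per-stage outputs so a run is exactly reproducible from
#' its manifest. If no mRNA matrix is available the cross-modality and
#' concordance stages are skipped with a logged reason.
#'
#' @param config a `PipelineConfig` list from [pipelineConfig()] or
#'   [readPipelineConfig()].
#' @param quiet suppress progress messages.
#' @return (invisibly) a list with each stage's in-memory results plus the
#'   manifest.
#' @export
runPipeline <- function(config = pipelineConfig(), quiet = FALSE) {
  t0 <- Sys.time()
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  say <- function(...) if (!quiet) message(sprintf(...))
  outputs <- list()
  timings <- list()
  out_file <- function(name) file.path(config$out_dir, name)
  stage <- function(name, code) {
    st <- Sys.time()
    say("[%s] starting", name)
    res <- withCallingHandlers(code, error = function(e) {
      stop(errorCondition(
        sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
        class = c(class(e)[1], "rppasig_stage_error", "error")))
    })
    timings[[name]] <<- as.numeric(difftime(Sys.time(), st, units = "secs"))
    res
  }

  ## config hash from the serialized YAML, for the manifest
  cfg_path <- out_file("config.yaml")
  cfg_writable <- config
  cfg_writable$sweep$thresholds <- as.numeric(config$sweep$thresholds)
  yaml::write_yaml(cfg_writable, cfg_path)
  cfg_hash <- unname(tools::md5sum(cfg_path))

  ## ---- inputs -----------------------------------------------------------
  sim <- identical(config$mode, "simulate")
  inputs <- stage("inputs", {
    if (sim) {
      spec <- do.call(cohortSpec, c(config$cohort,
                                    list(seed = config$seed)))
      cohort <- generateCohort(spec)
      truth <- with(cohort$metadata, setNames(true_cluster, sample_id))
      val_ids <- cohort$metadata$sample_id[cohort$metadata$validated]
      gspec <- do.call(growthSpec, c(config$growth,
                                     list(seed = config$seed + 1L)))
      growth <- generateGrowth(gspec, truth[val_ids])
      writeProfile(cohort$protein, out_file("protein.tsv"))
      writeProfile(cohort$mrna, out_file("mrna.tsv"))
      writeMetadata(cohort$metadata, out_file("metadata.csv"))
      writeGrowth(growth, out_file("growth.csv"))
      outputs$inputs <- c("protein.tsv", "mrna.tsv", "metadata.csv",
                           "growth.csv")
      list(protein = cohort$protein, mrna = cohort$mrna,
           metadata = cohort$metadata, growth = growth)
    } else {
      p <- config$paths
      if (is.null(p$protein) || is.null(p$metadata))
        inputError("run mode requires at least 'protein' and 'metadata' paths")
      gm <- if (!is.null(p$gene_map)) readGeneMap(p$gene_map) else NULL
      list(protein = readProfile(p$protein, "protein", geneMap = gm),
           mrna = if (!is.null(p$mrna)) readProfile(p$mrna, "mrna"),
           metadata = readMetadata(p$metadata),
           growth = if (!is.null(p$growth)) readGrowth(p$growth))
    }
  })
  if (is.null(inputs$mrna))
    say("no mRNA matrix available: cross-modality stages will be skipped")

  ## ---- clustering -------------------------------------------------------
  cluster <- stage("cluster", {
    assignment <- wardBicluster(inputs$protein)
    sens_feats <- config$cluster$sensitivity_features
    if (is.null(sens_feats)) {
      if (!sim)
        inputError("run mode requires cluster$sensitivity_features")
      sens_feats <- metadata(inputs$protein)$signature$group1
    }
    assignment <- labelClusters(assignment, inputs$protein, sens_feats)
    pheno <- predictedPhenotype(assignment)
    write.csv(data.frame(sample_id = names(pheno),
                         cluster = as.character(sampleClusters(assignment)[names(pheno)]),
                         phenotype = unname(pheno)),
              out_file("clusters.csv"), row.names = FALSE)
    write.csv(assignment@sampleLinkage, out_file("sample_linkage.csv"),
              row.names = FALSE)
    outputs$cluster <- c("clusters.csv", "sample_linkage.csv")
    assignment
  })
  phenotype <- predictedPhenotype(cluster)

  ## ---- response evaluation ---------------------------------------------
  respond <- stage("respond", {
    md <- inputs$metadata
    if (!is.null(inputs$growth)) {
      calls <- callResponse(inputs$growth)
      observed <- setNames(calls$call, calls$pdx_id)
      write.csv(calls, out_file("response_calls.csv"), row.names = FALSE)
    } else {
      val <- md[md$validated, ]
      observed <- setNames(val$observed_response, val$sample_id)
      calls <- NULL
    }
    contingency <- evaluatePredictions(phenotype[names(observed)], observed)
    rr <- reportRates(contingency)
    write.csv(data.frame(metric = names(rr), percent = unname(rr)),
              out_file("contingency_rates.csv"), row.names = FALSE)
    assoc <- associationTable(md, predicted = phenotype)
    write.csv(assoc, out_file("covariate_association.csv"),
              row.names = FALSE)
    outputs$respond <- c("response_calls.csv", "contingency_rates.csv",
                          "covariate_association.csv")
    list(calls = calls, observed = observed, contingency = contingency,
         association = assoc)
  })

  ## ---- sweep + selection ------------------------------------------------
  sweep_res <- stage("sweep", {
    diffs <- differentialStats(inputs$protein, phenotype)
    sets <- sweepBiomarkerSets(diffs, thresholds = config$sweep$thresholds,
                               pCut = config$sweep$p_cut)
    sw <- evaluateSweep(inputs$protein, inputs$mrna, sets, phenotype,
                        respond$observed, cost = config$sweep$svm_cost)
    sel <- selectSignature(sw, sets)
    final <- finalizeSignature(sel$set, geneMap(inputs$protein))
    write.csv(diffs, out_file("differential_stats.csv"), row.names = FALSE)
    write.csv(sw$summary, out_file("sweep_evaluation.csv"),
              row.names = FALSE)
    write.csv(data.frame(feature_id = setFeatures(final),
                         direction = unname(featureDirection(final)),
                         threshold = setThreshold(final)),
              out_file("signature.csv"), row.names = FALSE)
    outputs$sweep <- c("differential_stats.csv", "sweep_evaluation.csv",
                        "signature.csv")
    list(diffs = diffs, sets = sets, sweep = sw, selection = sel,
         signature = final)
  })

  ## ---- external concordance --------------------------------------------
  concord <- stage("concord", {
    if (is.null(inputs$mrna)) {
      say("concordance skipped: no mRNA matrix")
      NULL
    } else {
      cc <- config$concord
      int_fc <- groupFoldChange(inputs$mrna, phenotype)
      ext <- generateExternalCohort(int_fc, nResistant = cc$n_resistant,
                                    nSensitive = cc$n_sensitive,
                                    concordance = cc$concordance,
                                    noiseSd = cc$noise_sd,
                                    seed = config$seed + 2L)
      conc <- foldChangeConcordance(inputs$mrna, phenotype, ext$mrna,
                                    ext$labels)
      conc <- randomizationControl(conc, ext$mrna, ext$labels,
                                   nPermutations = cc$n_permutations,
                                   seed = config$seed + 3L)
      write.csv(data.frame(gene = names(conc@internalFC),
                           internal_fc = unname(conc@internalFC),
                           external_fc = unname(conc@externalFC)),
                out_file("concordance_fc.csv"), row.names = FALSE)
      write.csv(data.frame(permutation_r = nullR(conc)),
                out_file("concordance_null.csv"), row.names = FALSE)
      outputs$concord <- c("concordance_fc.csv", "concordance_null.csv")
      conc
    }
  })

  ## ---- IHC scoring ------------------------------------------------------
  ihc <- stage("ihc", {
    cc <- config$ihc
    base_thr <- 1
    control <- generateIHCCells(cc$n_cells, 0.01, base_thr,
                                seed = config$seed + 4L,
                                sectionId = "CTRL", marker = "CAV1")
    thr <- calibrateThreshold(control$mean_intensity,
                              probs = cc$control_quantile)
    mk_sections <- function(group, n, frac_cav1, frac_sox2, offset) {
      do.call(rbind, lapply(seq_len(n), function(i) {
        sid <- sprintf("%s_%02d", group, i)
        rbind(generateIHCCells(cc$n_cells, frac_cav1, base_thr,
                               seed = config$seed + offset + i,
                               sectionId = sid, marker = "CAV1"),
              generateIHCCells(cc$n_cells, frac_sox2, base_thr,
                               seed = config$seed + offset + 1000L + i,
                               sectionId = sid, marker = "SOX2"))
      }))
    }
    cells <- rbind(mk_sections("CR", cc$n_sections_cr, cc$cav1_cr,
                               cc$sox2_cr, 10L),
                   mk_sections("PD", cc$n_sections_pd, cc$cav1_pd,
                               cc$sox2_pd, 5000L))
    per <- split(cells, list(cells$section_id, cells$marker), drop = TRUE)
    scores <- do.call(rbind, lapply(per, scoreSection,
                                    intensityThreshold = thr))
    scores$response_group <- sub("_.*", "", scores$section_id)
    rownames(scores) <- NULL
    comp <- compareGroups(scores)
    write.csv(scores, out_file("ihc_scores.csv"), row.names = FALSE)
    if (!is.null(comp$difference))
      write.csv(comp$difference, out_file("ihc_difference.csv"),
                row.names = FALSE)
    outputs$ihc <- c("ihc_scores.csv", "ihc_difference.csv")
    list(threshold = thr, scores = scores, comparison = comp)
  })

  manifest <- list(config_hash = cfg_hash, seed = config$seed,
                   mode = config$mode,
                   created = format(t0, "%Y-%m-%dT%H:%M:%S%z"),
                   stage_outputs = outputs,
                   stage_seconds = timings)
  jsonlite::write_json(manifest, out_file("manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  say("pipeline complete: %s", config$out_dir)
  invisible(list(inputs = inputs, cluster = cluster, respond = respond,
                 sweep = sweep_res, concord = concord, ihc = ihc,
                 manifest = manifest, out_dir = config$out_dir))
}
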