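## End-to-end orchestration: simulate -> preprocess -> diversity -> screen
## -> bvs -> report, with a JSON run manifest and digest-based stage
## skipping. Tissue-stratified execution (separate tumor and healthy fits)
## is the default.

.pipeline_stages <- c("simulate", "preprocess", "diversity", "screen",
                      "bvs", "report")

#' Default pipeline configuration
#'
#' @param out_dir Artifact directory.
#' @param seed Master seed; stage seeds derive from it.
#' @param stages Which stages to run, in dependency order.
#' @param counts,taxonomy,cytokines,pairing Input paths (filled in
#'   automatically when the simulate stage runs).
#' @param simulate Named list of [study_config()] overrides.
#' @param tissues Tissues to analyze separately (default both).
#' @param top_k Named genera in the composition response.
#' @param transform Covariate transform.
#' @param top_m Cytokines selected by the screen.
#' @param bvs_cytokines Optional explicit cytokine list for the
#'   variable-selection stage (bypasses the screen's selection).
#' @param bvs Named list of [bvs_config()] overrides.
#' @param rarefaction_step,slope_threshold Rarefaction grid controls.
#' @param write_chains Write retained MCMC draws as TSV.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(out_dir, seed = 1, stages = .pipeline_stages,
                            counts = NULL, taxonomy = NULL, cytokines = NULL,
                            pairing = NULL, simulate = list(),
                            tissues = c("tumor", "healthy"), top_k = 3,
                            transform = "log1p_zscore", top_m = 3,
                            bvs_cytokines = NULL, bvs = list(),
                            rarefaction_step = 50, slope_threshold = 1e-5,
                            write_chains = FALSE) {
  if (missing(out_dir) || is.null(out_dir)) {
    stop("pipeline config: `out_dir` is required")
  }
  bad <- setdiff(stages, .pipeline_stages)
  if (length(bad) > 0) stop("unknown stage(s): ", paste(bad, collapse = ", "))
  structure(list(out_dir = out_dir, seed = seed,
                 stages = .pipeline_stages[.pipeline_stages %in% stages],
                 counts = counts, taxonomy = taxonomy, cytokines = cytokines,
                 pairing = pairing, simulate = simulate, tissues = tissues,
                 top_k = top_k, transform = transform, top_m = top_m,
                 bvs_cytokines = bvs_cytokines, bvs = bvs,
                 rarefaction_step = rarefaction_step,
                 slope_threshold = slope_threshold,
                 write_chains = write_chains),
            class = "pipeline_config")
}

#' Read a pipeline configuration from a YAML file
#' @param path YAML file whose keys mirror [pipeline_config()] arguments.
#' @return A [pipeline_config()].
#' @export
read_pipeline_config <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE)) {
    stop("the 'yaml' package is needed to read YAML configs")
  }
  do.call(pipeline_config, yaml::read_yaml(path))
}

.file_digest <- function(paths) {
  paths <- paths[!vapply(paths, is.null, logical(1))]
  unlist(lapply(paths, function(p) unname(tools::md5sum(p))))
}

#' Run the full association pipeline
#'
#' Executes the requested stages in dependency order, writing every output
#' table plus a JSON run manifest (config snapshot, seeds, input digests,
#' package version, per-stage timings, warnings) under `config$out_dir`.
#' A stage whose inputs' digests match the previous manifest and whose
#' outputs already exist is skipped. Identical config and seed give
#' byte-identical numeric outputs.
#'
#' @param config A [pipeline_config()], or the path of a YAML file.
#' @return Invisibly, the manifest list. Errors propagate with the failing
#'   stage named.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "pipeline_config"))
  out <- config$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  prev_manifest <- NULL
  manifest_path <- file.path(out, "manifest.json")
  if (file.exists(manifest_path)) {
    prev_manifest <- tryCatch(jsonlite::read_json(manifest_path),
                              error = function(e) NULL)
  }
  manifest <- list(
    manifest_id = sprintf("run-seed%d-%s", config$seed,
                          format(Sys.time(), "%Y%m%d%H%M%S")),
    package_version = as.character(utils::packageVersion("cytotaxa")),
    seed = config$seed,
    config = config[setdiff(names(config), "out_dir")],
    stages = list(), input_digests = list(), timings = list(),
    warnings = character(0)
  )
  log_msg <- function(stage, ...) {
    message("[", stage, "] ", ...)
  }
  run_stage <- function(stage, inputs, outputs, fun) {
    digest <- .file_digest(inputs)
    prev <- prev_manifest$input_digests[[stage]]
    unchanged <- !is.null(prev) &&
      identical(unname(unlist(prev)), unname(digest)) &&
      all(file.exists(as.character(unlist(outputs))))
    manifest$input_digests[[stage]] <<- as.list(digest)
    if (unchanged) {
      log_msg(stage, "inputs unchanged, outputs present: skipped")
      manifest$stages[[stage]] <<- "skipped"
      return(invisible(NULL))
    }
    t0 <- proc.time()[["elapsed"]]
    withCallingHandlers(
      tryCatch(fun(), error = function(e) {
        stop("stage '", stage, "' failed: ", conditionMessage(e),
             call. = FALSE)
      }),
      warning = function(w) {
        manifest$warnings <<- c(manifest$warnings,
                                paste0(stage, ": ", conditionMessage(w)))
        invokeRestart("muffleWarning")
      }
    )
    manifest$timings[[stage]] <<- proc.time()[["elapsed"]] - t0
    manifest$stages[[stage]] <<- "run"
    invisible(NULL)
  }

  data_dir <- file.path(out, "data")
  if ("simulate" %in% config$stages) {
    run_stage("simulate", inputs = list(), outputs = list(),
              fun = function() {
      sim_args <- config$simulate
      sim_args$seed <- config$seed
      study <- generate_paired_study(do.call(study_config, sim_args))
      write_synthetic_study(study, data_dir)
      log_msg("simulate", "wrote synthetic study (",
              study$config$n_patients, " patients) to ", data_dir)
    })
    config$counts <- file.path(data_dir, "counts.tsv")
    config$taxonomy <- file.path(data_dir, "taxonomy.tsv")
    config$cytokines <- file.path(data_dir, "cytokines.csv")
    config$pairing <- file.path(data_dir, "pairing.tsv")
  }

  for (f in c("counts", "cytokines", "pairing")) {
    if (is.null(config[[f]])) {
      stop("pipeline config: field '", f, "' is required (no path given ",
           "and the simulate stage was not requested)")
    }
    if (!file.exists(config[[f]])) {
      stop("pipeline config: ", f, " file not found: ", config[[f]])
    }
  }

  inputs <- list(config$counts, config$taxonomy, config$cytokines,
                 config$pairing)
  otu <- read_otu_table(config$counts, config$taxonomy)
  panel <- read_cytokine_panel(config$cytokines)
  pairing <- read_sample_pairing(config$pairing)
  loq <- read_loq_table()
  tissue_ids <- list(tumor = pairing$tumor_sample_id,
                     healthy = pairing$healthy_sample_id)

  genus_tab <- NULL
  responses <- list()
  panel_cens <- NULL
  if (any(c("preprocess", "screen", "bvs") %in% config$stages)) {
    comp_paths <- file.path(out, paste0("composition_", config$tissues,
                                        ".csv"))
    run_stage("preprocess", inputs,
              outputs = as.list(comp_paths), fun = function() {
      panel_cens <<- apply_loq(panel, loq, uloq_policy = "clip")
      genus_tab <<- aggregate_to_rank(otu, "genus")
      for (ti in config$tissues) {
        ids <- tissue_ids[[ti]]
        sub <- otu_table(genus_tab$counts[ids, , drop = FALSE],
                         genus_tab$taxonomy)
        responses[[ti]] <<- build_composition_response(sub, config$top_k)
        utils::write.csv(
          data.frame(sample_id = ids, responses[[ti]]$counts,
                     check.names = FALSE),
          file.path(out, paste0("composition_", ti, ".csv")),
          row.names = FALSE, quote = FALSE, fileEncoding = "UTF-8")
      }
      log_msg("preprocess", "built ", config$top_k + 1,
              "-category responses for: ",
              paste(config$tissues, collapse = ", "))
    })
    if (is.null(panel_cens)) {  # stage skipped: rebuild in memory
      panel_cens <- apply_loq(panel, loq, uloq_policy = "clip")
      genus_tab <- aggregate_to_rank(otu, "genus")
      for (ti in config$tissues) {
        ids <- tissue_ids[[ti]]
        sub <- otu_table(genus_tab$counts[ids, , drop = FALSE],
                         genus_tab$taxonomy)
        responses[[ti]] <- build_composition_response(sub, config$top_k)
      }
    }
  }

  if ("diversity" %in% config$stages) {
    run_stage("diversity", inputs,
              outputs = list(file.path(out, "diversity_profile.csv")),
              fun = function() {
      prof <- diversity_profile(otu)
      utils::write.csv(prof, file.path(out, "diversity_profile.csv"),
                       row.names = FALSE, fileEncoding = "UTF-8")
      grids <- lapply(rownames(otu$counts), function(s) {
        rc <- rarefaction_curve(otu$counts[s, ], step = config$rarefaction_step,
                                slope_threshold = config$slope_threshold)
        data.frame(sample_id = s, depth = rc$depths,
                   expected_taxa = rc$expected_taxa,
                   final_slope = rc$final_slope, saturated = rc$saturated)
      })
      utils::write.csv(do.call(rbind, grids),
                       file.path(out, "rarefaction.csv"),
                       row.names = FALSE, fileEncoding = "UTF-8")
      idx_t <- match(pairing$tumor_sample_id, prof$sample_id)
      idx_h <- match(pairing$healthy_sample_id, prof$sample_id)
      tests <- lapply(c("richness", "shannon", "evenness", "chao1"),
                      function(ix) {
        res <- tryCatch(
          paired_signed_rank(prof[[ix]][idx_t], prof[[ix]][idx_h]),
          error = function(e) list(statistic = NA_real_, p_value = NA_real_,
                                   n = NA_integer_))
        data.frame(index = ix, statistic = res$statistic,
                   p_value = res$p_value, n = res$n)
      })
      pc <- tryCatch(pairing_cluster_check(otu, pairing),
                     error = function(e) NA_real_)
      tests <- rbind(do.call(rbind, tests),
                     data.frame(index = "pairing_fraction",
                                statistic = as.numeric(pc),
                                p_value = NA_real_, n = nrow(pairing)))
      utils::write.csv(tests, file.path(out, "diversity_tests.csv"),
                       row.names = FALSE, fileEncoding = "UTF-8")
      log_msg("diversity", "profiles, rarefaction and paired tests written; ",
              "dendrogram pairing fraction ", round(as.numeric(pc), 3))
    })
  }

  screen_results <- list()
  if ("screen" %in% config$stages) {
    screen_paths <- file.path(out, paste0("screening_", config$tissues,
                                          ".csv"))
    run_stage("screen", inputs, outputs = as.list(screen_paths),
              fun = function() {
      for (ti in config$tissues) {
        ids <- tissue_ids[[ti]]
        sub_panel <- cytokine_panel(
          panel_cens$values[ids, , drop = FALSE],
          panel_cens$censored_mask[ids, , drop = FALSE],
          panel_cens$uloq_flagged[ids, , drop = FALSE])
        scr <- screen_cytokines(sub_panel, responses[[ti]],
                                transform = config$transform,
                                top_m = config$top_m)
        screen_results[[ti]] <<- scr
        utils::write.csv(scr$table,
                         file.path(out, paste0("screening_", ti, ".csv")),
                         row.names = FALSE, quote = FALSE,
                         fileEncoding = "UTF-8")
        log_msg("screen", ti, ": top-", scr$m, " = ",
                paste(scr$selection, collapse = ", "))
      }
    })
    if (length(screen_results) == 0) {  # skipped: reload selections
      for (ti in config$tissues) {
        tab <- utils::read.csv(file.path(out, paste0("screening_", ti,
                                                     ".csv")),
                               fileEncoding = "UTF-8")
        screen_results[[ti]] <- list(
          table = tab,
          selection = tab$cytokine[order(tab$rank)][seq_len(config$top_m)])
      }
    }
  }

  if ("bvs" %in% config$stages) {
    ppi_paths <- file.path(out, paste0("ppi_", config$tissues, ".csv"))
    run_stage("bvs", inputs, outputs = as.list(ppi_paths), fun = function() {
      for (ti in config$tissues) {
        ids <- tissue_ids[[ti]]
        chosen <- config$bvs_cytokines
        if (is.null(chosen)) {
          if (is.null(screen_results[[ti]])) {
            stop("no screening result for tissue '", ti, "' and no ",
                 "explicit bvs_cytokines given")
          }
          chosen <- screen_results[[ti]]$selection
        }
        sub <- panel_cens$values[ids, chosen, drop = FALSE]
        dm <- standardize_covariates(sub, transform = config$transform)
        bvs_args <- config$bvs
        bvs_args$seed <- .derive_seed(config$seed,
                                      5 + match(ti, config$tissues))
        res <- run_bvs(dm, responses[[ti]], do.call(bvs_config, bvs_args))
        tabs <- render_association_tables(res)
        utils::write.csv(cbind(term = rownames(res$ppi), tabs$ppi),
                         file.path(out, paste0("ppi_", ti, ".csv")),
                         row.names = FALSE, quote = FALSE,
                         fileEncoding = "UTF-8")
        utils::write.csv(cbind(term = rownames(res$ppi),
                               tabs$posterior_mean),
                         file.path(out, paste0("coefficients_", ti, ".csv")),
                         row.names = FALSE, quote = FALSE,
                         fileEncoding = "UTF-8")
        if (isTRUE(config$write_chains)) {
          chain <- cbind(res$chains$theta, threshold = res$chains$threshold)
          utils::write.table(chain,
                             file.path(out, paste0("chains_", ti, ".tsv")),
                             sep = "\t", row.names = FALSE, quote = FALSE)
        }
        log_msg("bvs", ti, ": ", length(chosen), " cytokines, ",
                "acceptance(covariate) = ",
                round(res$acceptance_rates[["covariate"]], 3))
      }
    })
  }

  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       digits = NA, force = TRUE, null = "null")

  if ("report" %in% config$stages) {
    run_stage("report", inputs,
              outputs = list(file.path(out, "report.txt")),
              fun = function() {
      make_report(out)
    })
    ## re-write manifest with the report timing included
    jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                         digits = NA, force = TRUE, null = "null")
  }
  invisible(manifest)
}

#' Render a plain-text summary report from pipeline artifacts
#'
#' Collates whatever stage outputs are present — screening tables, PPI and
#' coefficient tables, the diversity summary with paired-test p-values —
#' and omits missing sections without error. Regeneration is idempotent.
#'
#' @param artifact_dir Directory written by [run_pipeline()].
#' @return Invisibly, the report path.
#' @export
make_report <- function(artifact_dir) {
  if (!dir.exists(artifact_dir)) stop("no such directory: ", artifact_dir)
  files <- list.files(artifact_dir)
  if (!any(grepl("^(diversity|screening|ppi)", files))) {
    stop("no stage outputs found in ", artifact_dir)
  }
  lines <- c("cytokine-microbiota association pipeline report", "")
  fmt_table <- function(df) {
    c(utils::capture.output(print(df, row.names = FALSE)), "")
  }
  dt <- file.path(artifact_dir, "diversity_tests.csv")
  if (file.exists(dt)) {
    lines <- c(lines, "## Alpha diversity, paired tumor-vs-healthy tests",
               fmt_table(utils::read.csv(dt, fileEncoding = "UTF-8")))
  }
  for (f in sort(files[grepl("^screening_.*\\.csv$", files)])) {
    tab <- utils::read.csv(file.path(artifact_dir, f),
                           fileEncoding = "UTF-8")
    lines <- c(lines, paste0("## Marginal screening (", f, ")"),
               fmt_table(tab[order(tab$rank), ]))
  }
  for (f in sort(files[grepl("^ppi_.*\\.csv$", files)])) {
    lines <- c(lines, paste0("## Posterior probabilities of inclusion (",
                             f, ")"),
               fmt_table(utils::read.csv(file.path(artifact_dir, f),
                                         check.names = FALSE,
                                         fileEncoding = "UTF-8")))
  }
  for (f in sort(files[grepl("^coefficients_.*\\.csv$", files)])) {
    lines <- c(lines, paste0("## Posterior means (conditional on inclusion; ",
                             f, ")"),
               fmt_table(utils::read.csv(file.path(artifact_dir, f),
                                         check.names = FALSE,
                                         fileEncoding = "UTF-8")))
  }
  path <- file.path(artifact_dir, "report.txt")
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}
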