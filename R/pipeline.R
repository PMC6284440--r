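# One reproducible run: simulate (or load) -> quantify -> score -> classify
# response -> discrimination statistics, with every intermediate table, a
# manifest, and a rendered Markdown report.

#' Default pipeline configuration
#'
#' Every assay threshold is a named key defaulting to its protocol value:
#' the 0.42-1.15 um focus band, the 5-foci positivity rule, the 40-cell /
#' 25-percent gamma-H2AX / 3-area QC gates, the 100-cell scoring target, the
#' 10 percent HRR cutoff, the mRECIST bounds (-95, -30, +20) and the 10-day
#' sustained-response window.
#'
#' @param seed integer master seed.
#' @param simulate `NULL`, or a list describing a synthetic study:
#'   `n_models`, `deficient_fraction`, `n_fields`, `n_nuclei` (per field),
#'   `field_shape`, `noise_sd`, `focus_peak_snr`, `n_animals`,
#'   `deficient_forming`, `proficient_forming`.
#' @param inputs `NULL`, or list of paths: `cells_csv`, `volumes_csv`.
#' @param foci,seg,qc parameter objects (see [foci_params()],
#'   [segment_params()], [qc_policy()]).
#' @param cutoff HRR-deficiency cutoff in percent.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(seed = 1L,
                            simulate = list(n_models = 18,
                                            deficient_fraction = 0.25),
                            inputs = NULL,
                            foci = foci_params(), seg = segment_params(),
                            qc = qc_policy(), cutoff = 10) {
  sim_defaults <- list(n_models = 18, deficient_fraction = 0.25,
                       n_fields = 4, n_nuclei = 30,
                       field_shape = c(512L, 512L), noise_sd = 0.02,
                       focus_peak_snr = 8, n_animals = 3,
                       deficient_forming = 0.01, proficient_forming = 0.6)
  if (!is.null(simulate))
    simulate <- utils::modifyList(sim_defaults, simulate)
  structure(list(seed = as.integer(seed), simulate = simulate,
                 inputs = inputs, foci = foci, seg = seg, qc = qc,
                 cutoff = cutoff),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' Recognized top-level keys: `seed`, `cutoff`, `simulate` (sub-keys as in
#' [pipeline_config()]), `inputs`, `foci`, `seg`, `qc` (sub-keys override
#' the corresponding parameter-object defaults).
#'
#' @param path YAML file.
#' @return a `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  cfg <- pipeline_config(
    seed = y$seed %||% 1L,
    simulate = if (is.null(y$inputs)) y$simulate %||% list() else y$simulate,
    inputs = y$inputs,
    foci = do.call(foci_params, y$foci %||% list()),
    seg = do.call(segment_params, y$seg %||% list()),
    qc = do.call(qc_policy, y$qc %||% list()),
    cutoff = y$cutoff %||% 10)
  cfg
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Simulate one model's fields and return its nucleus records.
simulate_model_records <- function(model_id, deficient, sim, cfg, seed) {
  forming <- if (deficient) sim$deficient_forming else sim$proficient_forming
  recs <- lapply(seq_len(sim$n_fields), function(i) {
    fs <- field_spec(
      field_shape = sim$field_shape, n_nuclei = sim$n_nuclei,
      markers = list(RAD51 = marker_model(forming_fraction = forming),
                     gH2AX = marker_model(forming_fraction = 1,
                                          lambda_forming = 15)),
      focus_peak_snr = sim$focus_peak_snr, noise_sd = sim$noise_sd,
      seed = seed + i)
    fld <- synthesize_field(fs, field_id = sprintf("F%d", i),
                            sample_id = model_id,
                            area_id = sprintf("A%d", (i - 1) %% 3 + 1))$field
    quantify_field(fld, foci = cfg$foci, seg = cfg$seg)
  })
  do.call(rbind, recs)
}

run_stage <- function(name, code) {
  tryCatch(code, error = function(e) {
    abort(sprintf("pipeline stage '%s' failed: %s", name,
                  conditionMessage(e)),
          class = "rad51score_stage_error")
  })
}

#' Run the full pipeline
#'
#' Stages: (1) images — simulate fields per model, or load a nucleus-level
#' cell table (the image stage is skipped when only tables are supplied);
#' (2) scoring — per-sample marker scores, QC and HRR calls; (3) response —
#' simulate or load tumor-volume series and classify mRECIST; (4) stats —
#' join into a cohort table and compute the discrimination report;
#' (5) report. Every intermediate is written as CSV; `manifest.json`
#' records the seed, all parameters and a parameter hash, so rerunning the
#' same config and seed reproduces all numeric outputs.
#'
#' @param config a [pipeline_config()] (or a YAML path).
#' @param out_dir run directory (created if needed).
#' @return the run directory, invisibly; the discrimination report and the
#'   cohort table are also returned as attributes `"report"` and `"cohort"`.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  sim <- config$simulate
  truth <- NULL
  skipped <- character()

  cells <- run_stage("images", {
    if (!is.null(config$inputs$cells_csv)) {
      skipped <- c(skipped, "images (cell table supplied)")
      read_cells_csv(config$inputs$cells_csv)
    } else if (!is.null(sim)) {
      truth <- with_seed(config$seed, {
        n <- sim$n_models
        n_def <- round(sim$deficient_fraction * n)
        data.frame(model_id = sprintf("M%02d", seq_len(n)),
                   true_class = sample(rep(c("deficient", "proficient"),
                                           c(n_def, n - n_def))),
                   stringsAsFactors = FALSE)
      })
      do.call(rbind, lapply(seq_len(nrow(truth)), function(i)
        simulate_model_records(truth$model_id[i],
                               truth$true_class[i] == "deficient", sim,
                               config, seed = config$seed + 1000L * i)))
    } else abort("no image source: provide inputs$cells_csv or simulate")
  })
  write.csv(cells, file.path(out_dir, "cells.csv"), row.names = FALSE)
  if (!is.null(truth))
    write.csv(truth, file.path(out_dir, "truth.csv"), row.names = FALSE)

  scores <- run_stage("scoring",
    score_samples(cells, policy = config$qc, cutoff = config$cutoff))
  write.csv(scores, file.path(out_dir, "scores.csv"), row.names = FALSE)

  response <- run_stage("response", {
    if (!is.null(config$inputs$volumes_csv)) {
      vols <- read_volumes_csv(config$inputs$volumes_csv)
      classify_models(vols)
    } else if (!is.null(sim)) {
      vols <- do.call(rbind, lapply(seq_len(nrow(truth)), function(i) {
        k <- if (truth$true_class[i] == "deficient") log(0.04) / 20
             else log(1.3) / 20
        do.call(rbind, lapply(seq_len(sim$n_animals), function(a)
          simulate_volume_series(k, model_id = truth$model_id[i],
                                 animal_id = sprintf("a%d", a),
                                 seed = config$seed + 7000L * i + a)))
      }))
      write.csv(vols, file.path(out_dir, "volumes.csv"), row.names = FALSE)
      classify_models(vols)
    } else NULL
  })
  if (!is.null(response))
    write.csv(response, file.path(out_dir, "response.csv"),
              row.names = FALSE)

  report <- run_stage("stats", {
    if (is.null(response)) NULL else {
      cohort <- merge(scores, response, by.x = "sample_id",
                      by.y = "model_id")
      cohort$responder <- cohort$mrecist %in% c("CR", "PR")
      names(cohort)[names(cohort) == "RAD51_score"] <- "rad51_score"
      write.csv(cohort, file.path(out_dir, "cohort.csv"),
                row.names = FALSE)
      ev <- cohort[cohort$qc_status == "evaluable", , drop = FALSE]
      rep <- discriminate_report(ev, cutoff = config$cutoff)
      jsonlite::write_json(unclass(rep), file.path(out_dir, "stats.json"),
                           auto_unbox = TRUE, digits = NA)
      rep
    }
  })

  params <- list(seed = config$seed, cutoff = config$cutoff,
                 foci = unclass(config$foci), seg = unclass(config$seg),
                 qc = unclass(config$qc), simulate = sim,
                 skipped_stages = skipped)
  pfile <- file.path(out_dir, "params.json")
  jsonlite::write_json(params, pfile, auto_unbox = TRUE, digits = NA)
  manifest <- list(package = "rad51score",
                   version = as.character(packageVersion("rad51score")),
                   r_version = R.version.string,
                   seed = config$seed,
                   parameter_hash = unname(tools::md5sum(pfile)),
                   params = params)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  render_report(out_dir)
  out <- structure(out_dir, report = report,
                   cohort = if (file.exists(file.path(out_dir, "cohort.csv")))
                     read.csv(file.path(out_dir, "cohort.csv")) else NULL)
  invisible(out)
}

fmt_table <- function(df) {
  df[] <- lapply(df, function(x) if (is.numeric(x)) signif(x, 4) else x)
  paste(c(paste(names(df), collapse = " | "),
          paste(rep("---", ncol(df)), collapse = " | "),
          apply(df, 1, paste, collapse = " | ")),
        collapse = "\n")
}

#' Render the run report
#'
#' Writes `report.md` in the run directory: per-sample scores and HRR
#' calls, a waterfall-style response table, and the ROC / sensitivity /
#' specificity / contingency summary. Regeneration is idempotent.
#'
#' @param run_dir a directory produced by [run_pipeline()].
#' @return the report path, invisibly.
#' @export
render_report <- function(run_dir) {
  need <- file.path(run_dir, "scores.csv")
  if (!file.exists(need))
    abort(paste("missing tables:", need), class = "rad51score_data_error")
  scores <- read.csv(need)
  lines <- c("# RAD51 HRR-functionality run report", "",
             "## Sample scores and HRR calls", "", fmt_table(scores), "")
  resp_path <- file.path(run_dir, "response.csv")
  if (file.exists(resp_path)) {
    resp <- read.csv(resp_path)
    resp <- resp[order(resp$best_response, decreasing = TRUE), ]
    lines <- c(lines, "## mRECIST response (waterfall order)", "",
               fmt_table(resp), "")
  } else {
    lines <- c(lines,
               "## mRECIST response", "",
               "_No tumor-volume table in this run; section omitted._", "")
  }
  stats_path <- file.path(run_dir, "stats.json")
  if (file.exists(stats_path)) {
    s <- jsonlite::read_json(stats_path, simplifyVector = TRUE)
    lines <- c(lines, "## Biomarker discrimination", "",
               sprintf("- ROC AUC (%s, low = responder): **%.3f**",
                       s$score, s$auc),
               sprintf("- Sensitivity / specificity at %g%%: %.1f%% / %.1f%%",
                       s$cutoff, s$sensitivity, s$specificity),
               sprintf("- 2x2 (responder x test-positive): a=%d b=%d c=%d d=%d",
                       s$table[1], s$table[2], s$table[3], s$table[4]),
               sprintf("- Odds ratio (Haldane) = %.3g (95%% CI %.3g-%.3g); Fisher p = %.3g",
                       s$odds_ratio, s$or_ci_low, s$or_ci_high, s$fisher_p),
               "")
  }
  path <- file.path(run_dir, "report.md")
  writeLines(lines, path)
  invisible(path)
}
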