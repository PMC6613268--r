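# End-to-end pipeline: simulate -> qc -> variance components -> replicated
# scenario runs -> summary. All randomness flows from `base_seed`:
# simulation uses base_seed, replicate r uses base_seed + r.

#' Pipeline configuration
#'
#' Validates and completes a configuration list (or YAML file, if the yaml
#' package is available). Unknown keys are rejected. Defaults: the study
#' conditions of [sim_config()], the standard QC thresholds (3.5 sd
#' outliers, 0.90 call rate, 0.01 Mendelian inconsistency, 0.005 minor
#' allele frequency), all six scenarios, 100 replicates, and REML variance
#' components.
#'
#' @param config Named list or path to a YAML file; missing entries take
#'   defaults.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(config = list()) {
  if (is.character(config) && length(config) == 1) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("reading YAML configs requires the yaml package", call. = FALSE)
    config <- yaml::read_yaml(config)
  }
  defaults <- list(
    out_dir = "results",
    sim = list(),                # overrides for sim_config()
    qc = list(k_outlier = 3.5, callrate = 0.90, mendelian = 0.01,
              maf = 0.005),
    scenarios = c("PB-A", "CB-A", "CB-A-BOA", "PB-I", "CB-I", "CB-I-BOA"),
    traits = NULL,
    n_replicates = 100L,
    base_seed = 1L,
    components = "reml",         # "reml" or a named list per trait
    epsilon = 1e-6)
  unknown <- setdiff(names(config), names(defaults))
  if (length(unknown))
    stop("unknown config keys: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  cfg <- utils::modifyList(defaults, config)
  bad_sim <- setdiff(names(cfg$sim), names(formals(sim_config)))
  if (length(bad_sim))
    stop("unknown sim config keys: ", paste(bad_sim, collapse = ", "),
         call. = FALSE)
  cfg$sim_config <- do.call(sim_config, cfg$sim)
  scenario_specs(cfg$scenarios)  # validates names
  structure(cfg, class = "pipeline_config")
}

.write_resolved_config <- function(cfg, dir) {
  path <- file.path(dir, "config_resolved.txt")
  keep <- cfg[setdiff(names(cfg), "sim_config")]
  txt <- utils::capture.output(utils::str(keep, give.attr = FALSE))
  writeLines(txt, path)
  invisible(path)
}

#' Simulate a dataset per the pipeline configuration
#'
#' @param cfg A [pipeline_config()].
#' @return The dataset directory path, invisibly; files are written under
#'   `out_dir/dataset`.
#' @export
pipeline_simulate <- function(cfg) {
  cfg <- if (inherits(cfg, "pipeline_config")) cfg else pipeline_config(cfg)
  pop <- simulate_population(cfg$sim_config, seed = cfg$base_seed)
  dir <- file.path(cfg$out_dir, "dataset")
  write_dataset(pop, dir)
  .write_resolved_config(cfg, cfg$out_dir)
  message("dataset written to ", dir)
  invisible(dir)
}

#' Run QC on the pipeline's dataset
#'
#' @param cfg A [pipeline_config()].
#' @return The filtered `cbp_dataset`, invisibly; the QC report is written
#'   to `out_dir/qc_report.csv`.
#' @export
pipeline_qc <- function(cfg) {
  cfg <- if (inherits(cfg, "pipeline_config")) cfg else pipeline_config(cfg)
  ds <- read_dataset(file.path(cfg$out_dir, "dataset"))
  res <- run_qc(ds, cfg$qc$k_outlier, cfg$qc$callrate, cfg$qc$mendelian,
                cfg$qc$maf)
  write_qc_report(res$report, file.path(cfg$out_dir, "qc_report.csv"))
  message(nrow(res$report), " QC removals/masks recorded")
  invisible(res$dataset)
}

# variance components per trait: animal model on the full reference data
# (estimated once and reused across replicates), sire model on all CB data
.pipeline_components <- function(cfg, data) {
  ped <- data$pedigree
  ph <- data$phenotypes
  traits <- cfg$traits %||% unique(ph$trait)
  if (!is.list(cfg$components)) {
    comp <- list(); sire_comp <- list()
    for (tr in traits) {
      cb <- ph[ph$trait == tr & ph$genetic_group == "CB", ]
      cb$sire_id <- ped$sire[match(cb$animal_id, ped$id)]
      ids <- cb$animal_id
      p <- colMeans(data$geno[ids, , drop = FALSE]) / 2
      g <- regularize(single_breed_grm(data$geno[ids, , drop = FALSE], p),
                      cfg$epsilon)
      d <- build_design(cb, grm_ids = g$ids, model = "animal")
      comp[[tr]] <- reml_estimate(d, g, tol = 1e-6, max_iter = 200L)
      ds <- build_design(cb, model = "sire")
      sire_comp[[tr]] <- reml_estimate(ds, tol = 1e-6, max_iter = 200L)
    }
    list(animal = comp, sire = sire_comp)
  } else {
    list(animal = cfg$components$animal, sire = cfg$components$sire)
  }
}

#' Run the replicated scenario comparison
#'
#' @param cfg A [pipeline_config()].
#' @return The `replicate_results` data frame, invisibly; written to
#'   `out_dir/results.csv`.
#' @export
pipeline_run <- function(cfg) {
  cfg <- if (inherits(cfg, "pipeline_config")) cfg else pipeline_config(cfg)
  data <- pipeline_qc(cfg)
  comp <- .pipeline_components(cfg, data)
  res <- run_replicates(data, cfg$scenarios, cfg$traits,
                        n_replicates = cfg$n_replicates,
                        components = comp$animal,
                        sire_components = comp$sire,
                        base_seed = cfg$base_seed)
  data.table::fwrite(res, file.path(cfg$out_dir, "results.csv"))
  invisible(res)
}

#' Summarize pipeline results
#'
#' @param cfg A [pipeline_config()].
#' @return Summary data frame, invisibly; written to
#'   `out_dir/summary.csv`.
#' @export
pipeline_summarize <- function(cfg) {
  cfg <- if (inherits(cfg, "pipeline_config")) cfg else pipeline_config(cfg)
  res <- as.data.frame(data.table::fread(file.path(cfg$out_dir,
                                                   "results.csv")))
  s <- summarize_replicates(res)
  data.table::fwrite(s, file.path(cfg$out_dir, "summary.csv"))
  invisible(s)
}
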