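WORKFLOW_STAGES <- c("design", "simulate", "synth", "preprocess",
                     "epistasis", "classify", "cluster", "report")

STAGE_DEPS <- list(design = character(0), simulate = "design",
                   synth = c("design", "simulate"),
                   preprocess = "synth",
                   epistasis = c("design", "preprocess"),
                   classify = c("design", "preprocess"),
                   cluster = "preprocess",
                   report = "epistasis")

CONFIG_KEYS <- c("resources", "scheme", "crm", "ensemble", "synth",
                 "preprocess", "out_dir", "seed", "log_level")

default_run_config <- function() {
  list(
    resources = list(names = sprintf("cs%02d", 1:8), rank_scores = 1:8),
    scheme = list(type = "hierarchical", total_carbon = 1.5),
    crm = list(),
    ensemble = list(S = 13, theta = 0.5, theta_mode = "uniform",
                    n_replicates = 2, byproduct_counts = c(1, 5)),
    synth = list(replicate_noise_sd = 0.01, read_depth = 10000,
                 n_replicates = 3, blank_od = 0.04),
    preprocess = list(growth_threshold = 0.05, alpha = 0.05,
                      mad_cutoff = 3.5, presence_threshold = 1e-3),
    out_dir = "envc_run", seed = 1, log_level = "info")
}

#' Validate (and complete) a workflow configuration
#'
#' Unknown top-level keys are rejected; missing keys are filled with
#' defaults. Configurations may be read from a YAML file.
#'
#' @param config A named list, or path to a YAML file.
#' @return The completed configuration list.
#' @export
validate_run_config <- function(config = list()) {
  if (is.character(config) && length(config) == 1)
    config <- yaml::read_yaml(config)
  if (!is.list(config)) stop("config must be a list or YAML path")
  unknown <- setdiff(names(config), CONFIG_KEYS)
  if (length(unknown) > 0)
    stop("unknown config keys: ", paste(unknown, collapse = ", "))
  def <- default_run_config()
  for (k in names(def)) {
    if (is.null(config[[k]])) {
      config[[k]] <- def[[k]]
    } else if (is.list(def[[k]])) {
      sub_unknown <- setdiff(names(config[[k]]), names(def[[k]]))
      extra_ok <- k %in% c("crm", "ensemble", "synth")  # pass-through args
      if (length(sub_unknown) > 0 && !extra_ok)
        stop("unknown config keys under '", k, "': ",
             paste(sub_unknown, collapse = ", "))
      for (kk in names(def[[k]]))
        if (is.null(config[[k]][[kk]])) config[[k]][[kk]] <- def[[k]][[kk]]
    }
  }
  if (!is.numeric(config$seed)) stop("seed must be numeric")
  config
}

#' Deterministic per-stage seed fan-out
#'
#' Derives one RNG seed per label from a root seed, reproducibly.
#'
#' @param root_seed Integer root seed.
#' @param labels Character vector of stage labels.
#' @return Named integer vector of seeds, all below 2^31.
#' @export
derive_seeds <- function(root_seed, labels = WORKFLOW_STAGES) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(as.integer(root_seed))
  stats::setNames(sample.int(.Machine$integer.max - 1L, length(labels)),
                  labels)
}

wf_log <- function(level, cfg, ...) {
  if (identical(cfg$log_level, "quiet")) return(invisible())
  message(sprintf("[%s] %s", level, paste0(...)))
}

#' Run the end-to-end synthetic analysis workflow
#'
#' Executes an ordered subset of stages — design, simulate, synth,
#' preprocess, epistasis, classify, cluster, report — writing every output
#' as delimited text or JSON under `config$out_dir` and recording each file
#' with its md5 hash in a manifest. Stage dependencies are enforced: a stage
#' whose inputs were produced neither in this call nor by a previous run in
#' the same directory raises an error. All randomness derives from
#' `config$seed` through a fixed per-stage fan-out, so a rerun with the same
#' configuration reproduces every file hash.
#'
#' @param config A configuration list or YAML path (see
#'   [validate_run_config()]).
#' @param stages Ordered subset of stages to execute.
#' @return The manifest (list with `files`, `config`, `seeds`), invisibly
#'   written to `manifest.json`.
#' @export
run_workflow <- function(config = list(), stages = WORKFLOW_STAGES) {
  cfg <- validate_run_config(config)
  stages <- match.arg(stages, WORKFLOW_STAGES, several.ok = TRUE)
  out <- cfg$out_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  seeds <- derive_seeds(cfg$seed)
  files <- character(0)
  done <- function(stage) file.exists(file.path(out, paste0(".done_", stage)))
  mark <- function(stage) file.create(file.path(out, paste0(".done_", stage)))
  add <- function(...) files <<- c(files, file.path(out, c(...)))

  for (stage in stages) {
    missing_dep <- setdiff(STAGE_DEPS[[stage]], stages[seq_len(match(stage, stages))])
    missing_dep <- missing_dep[!vapply(missing_dep, done, logical(1))]
    if (length(missing_dep) > 0)
      stop(sprintf("stage '%s' requires stage(s) %s to run first", stage,
                   paste(sQuote(missing_dep), collapse = ", ")))
    wf_log("info", cfg, "stage: ", stage)

    if (stage == "design") {
      res <- resource_set(cfg$resources$names, cfg$resources$rank_scores)
      scheme <- switch(cfg$scheme$type,
        hierarchical = build_hierarchical_scheme(res, cfg$scheme$total_carbon),
        full_subset = build_full_subset_scheme(res, cfg$scheme$total_carbon),
        stop("unknown scheme type: ", cfg$scheme$type))
      validate_scheme(scheme)
      write_scheme(scheme, file.path(out, "scheme.tsv"))
      add("scheme.tsv", "scheme.json")
    }

    if (stage == "simulate") {
      scheme <- read_scheme(file.path(out, "scheme.tsv"))
      params <- do.call(crm_params, cfg$crm)
      ens_args <- cfg$ensemble
      ens_args$scheme <- scheme
      ens_args$params <- params
      ens_args$seed <- seeds[["simulate"]]
      ens <- do.call(run_crm_ensemble, ens_args)
      utils::write.table(ens$summary, file.path(out, "ensemble_summary.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      utils::write.table(ens$rho, file.path(out, "ensemble_rho.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      utils::write.table(scaling_summary(ens),
                         file.path(out, "scaling_summary.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      saveRDS_path <- file.path(out, "abundances.tsv")
      ab <- data.frame(ens$summary[, c("replicate", "byproduct_count",
                                       "env_id")], ens$abundances)
      utils::write.table(ab, saveRDS_path, sep = "\t", quote = FALSE,
                         row.names = FALSE)
      jsonlite::write_json(ens$config, file.path(out, "ensemble_config.json"),
                           auto_unbox = TRUE, digits = NA, force = TRUE)
      add("ensemble_summary.tsv", "ensemble_rho.tsv", "scaling_summary.tsv",
          "abundances.tsv", "ensemble_config.json")
    }

    if (stage == "synth") {
      scheme <- read_scheme(file.path(out, "scheme.tsv"))
      summ <- utils::read.table(file.path(out, "ensemble_summary.tsv"),
                                sep = "\t", header = TRUE,
                                stringsAsFactors = FALSE)
      # per-environment mean simulated yield, rescaled to OD
      agg <- stats::aggregate(list(yield = summ$yield),
                              by = list(env_id = summ$env_id), FUN = mean)
      od <- cfu_od_convert(pmax(agg$yield, 0), "cfu_to_od")
      truth <- stats::setNames(od, agg$env_id)
      sp <- synth_community_plates(
        scheme, truth,
        replicate_noise_sd = cfg$synth$replicate_noise_sd,
        n_replicates = cfg$synth$n_replicates, blank_od = cfg$synth$blank_od,
        planted_EY = if (!is.null(cfg$synth$planted_EY))
          unlist(cfg$synth$planted_EY) else NULL,
        seed = seeds[["synth"]])
      write_plate_table(sp$plate, file.path(out, "plates.tsv"))
      # endpoint compositions of replicate 1, first byproduct count
      ab <- utils::read.table(file.path(out, "abundances.tsv"), sep = "\t",
                              header = TRUE, stringsAsFactors = FALSE)
      sub <- ab[ab$replicate == 1 & ab$byproduct_count ==
                  min(ab$byproduct_count), , drop = FALSE]
      comp <- t(as.matrix(sub[, -(1:3)]))
      colnames(comp) <- sub$env_id
      comp <- comp[, colSums(comp) > 0, drop = FALSE]
      tab <- synth_abundance_table(comp, read_depth = cfg$synth$read_depth,
                                   n_replicates = cfg$synth$n_replicates,
                                   seed = seeds[["synth"]] + 1L)
      write_abundance_table(tab, file.path(out, "abundances_16s.tsv"))
      jsonlite::write_json(sp$manifest, file.path(out, "synth_manifest.json"),
                           auto_unbox = TRUE, digits = NA, force = TRUE)
      add("plates.tsv", "abundances_16s.tsv", "synth_manifest.json")
    }

    if (stage == "preprocess") {
      plate <- read_plate_table(file.path(out, "plates.tsv"))
      yields <- correct_and_call_growth(plate, cfg$preprocess$growth_threshold,
                                        cfg$preprocess$alpha,
                                        cfg$preprocess$mad_cutoff)
      utils::write.table(yields, file.path(out, "yields.tsv"), sep = "\t",
                         quote = FALSE, row.names = FALSE)
      tab <- read_abundance_table(file.path(out, "abundances_16s.tsv"))
      comp <- average_replicates(tab)
      utils::write.table(
        data.frame(taxon = rownames(comp), comp, check.names = FALSE),
        file.path(out, "compositions.tsv"), sep = "\t", quote = FALSE,
        row.names = FALSE)
      add("yields.tsv", "compositions.tsv")
    }

    if (stage == "epistasis") {
      scheme <- read_scheme(file.path(out, "scheme.tsv"))
      yields <- utils::read.table(file.path(out, "yields.tsv"), sep = "\t",
                                  header = TRUE, stringsAsFactors = FALSE)
      meas <- data.frame(env_id = yields$environment_id,
                         yield = yields$yield,
                         growth_flag = yields$growth_flag,
                         stringsAsFactors = FALSE)
      recs <- epistasis_over_tree(scheme, meas, "yield")
      comp <- as.matrix(utils::read.table(file.path(out, "compositions.tsv"),
                                          sep = "\t", header = TRUE,
                                          row.names = 1, check.names = FALSE))
      thr <- cfg$preprocess$presence_threshold
      grown <- intersect(colnames(comp), meas$env_id[meas$growth_flag])
      dm <- data.frame(env_id = scheme$environments$env_id,
                       richness = 0, shannon = 0, stringsAsFactors = FALSE)
      for (e in grown) {
        i <- match(e, dm$env_id)
        dm$richness[i] <- species_richness(comp[, e], thr)
        dm$shannon[i] <- shannon_entropy(comp[, e] / sum(comp[, e]))
      }
      recs <- rbind(recs, epistasis_over_tree(scheme, dm, "richness"),
                    epistasis_over_tree(scheme, dm, "shannon"))
      utils::write.table(recs, file.path(out, "epistasis.tsv"), sep = "\t",
                         quote = FALSE, row.names = FALSE)
      add("epistasis.tsv")
    }

    if (stage == "classify") {
      scheme <- read_scheme(file.path(out, "scheme.tsv"))
      comp <- as.matrix(utils::read.table(file.path(out, "compositions.tsv"),
                                          sep = "\t", header = TRUE,
                                          row.names = 1, check.names = FALSE))
      surv <- survivor_sets(comp, cfg$preprocess$presence_threshold)
      for (e in setdiff(scheme$environments$env_id, names(surv)))
        surv[[e]] <- character(0)
      labels <- classify_over_tree(scheme, surv)
      utils::write.table(labels, file.path(out, "outcome_types.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      add("outcome_types.tsv")
    }

    if (stage == "cluster") {
      comp <- as.matrix(utils::read.table(file.path(out, "compositions.tsv"),
                                          sep = "\t", header = TRUE,
                                          row.names = 1, check.names = FALSE))
      cl <- tryCatch(cluster_environments(comp), error = function(e) NULL)
      if (is.null(cl)) {
        wf_log("warn", cfg, "clustering skipped: too few usable environments")
      } else {
        write_dendrogram_newick(cl, file.path(out, "env_dendrogram.nwk"))
        add("env_dendrogram.nwk")
      }
    }

    if (stage == "report") {
      rep <- summary_report(out)
      writeLines(rep$text, file.path(out, "report.txt"))
      add("report.txt")
    }
    mark(stage)
  }

  manifest <- list(
    files = lapply(stats::setNames(files, basename(files)), function(f)
      list(path = f, md5 = unname(tools::md5sum(f)))),
    config = cfg, seeds = as.list(seeds), stages = stages)
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  invisible(manifest)
}

#' Human-readable summary report of a workflow run
#'
#' Collects per-metric epistasis means and standard deviations, outcome-type
#' prevalences and the complexity-scaling tables from a run directory.
#'
#' @param run_dir Directory written by [run_workflow()].
#' @return A list with `text` (character vector of report lines),
#'   `epistasis` (per-metric summary or NULL), `outcomes`, `scaling`.
#' @export
summary_report <- function(run_dir) {
  lines <- c("Environmental-complexity analysis report", "")
  eps_file <- file.path(run_dir, "epistasis.tsv")
  eps_sum <- NULL
  if (file.exists(eps_file)) {
    eps <- utils::read.table(eps_file, sep = "\t", header = TRUE,
                             stringsAsFactors = FALSE)
    if (nrow(eps) == 0) {
      lines <- c(lines, "Epistasis: no composites")
    } else {
      eps_sum <- do.call(rbind, lapply(split(eps, eps$metric), function(d)
        data.frame(metric = d$metric[1], n = nrow(d), mean = mean(d$E),
                   sd = stats::sd(d$E))))
      lines <- c(lines, "Epistasis distributions (per metric):",
                 utils::capture.output(print(eps_sum, row.names = FALSE)), "")
    }
  }
  out_file <- file.path(run_dir, "outcome_types.tsv")
  outcomes <- NULL
  if (file.exists(out_file)) {
    lab <- utils::read.table(out_file, sep = "\t", header = TRUE,
                             stringsAsFactors = FALSE)
    tab <- table(factor(lab$type, levels = c("I", "II", "III", "IV")))
    outcomes <- stats::setNames(100 * as.numeric(tab) / max(1, sum(tab)),
                                names(tab))
    lines <- c(lines, "Outcome-type prevalences (%):",
               paste(sprintf("  Type %s: %.1f%%", names(outcomes), outcomes),
                     collapse = "\n"), "")
  }
  sc_file <- file.path(run_dir, "scaling_summary.tsv")
  scaling <- NULL
  if (file.exists(sc_file)) {
    scaling <- utils::read.table(sc_file, sep = "\t", header = TRUE,
                                 stringsAsFactors = FALSE)
    lines <- c(lines, "Scaling with environmental complexity:",
               utils::capture.output(print(
                 scaling[, c("complexity", "yield_mean", "richness_mean",
                             "shannon_mean")], row.names = FALSE)))
  }
  list(text = lines, epistasis = eps_sum, outcomes = outcomes,
       scaling = scaling)
}

#' Reproduce summary metrics from deposited experimental tables
#'
#' Integration pathway for previously deposited experimental tables: given a local
#' directory containing a taxon relative-abundance table in this package's
#' dialect (`abundances.tsv`, wide taxa-by-sample with `env|rep` columns) and
#' a scheme serialization (`scheme.tsv` + `scheme.json`), recomputes the
#' species-richness epistasis distribution and outcome-type prevalences. The
#' deposited tables are not bundled with the package; when the directory is
#' absent the function returns `NULL` with a message.
#'
#' @param data_dir Directory with `abundances.tsv` and `scheme.tsv`.
#' @param presence_threshold Presence threshold on relative abundance.
#' @return A list with `E_S` (data.frame), `E_S_mean`, `type_prevalence_pct`,
#'   or `NULL` when the directory or files are missing.
#' @export
reproduce_deposited <- function(data_dir,
                                presence_threshold = 1e-3) {
  need <- file.path(data_dir, c("abundances.tsv", "scheme.tsv"))
  if (!dir.exists(data_dir) || !all(file.exists(need))) {
    message("deposited tables not found under '", data_dir,
            "'; obtain them from the original data deposit")
    return(invisible(NULL))
  }
  scheme <- read_scheme(need[2])
  tab <- read_abundance_table(need[1])
  comp <- average_replicates(tab)
  meas <- data.frame(env_id = colnames(comp),
                     richness = apply(comp, 2, species_richness,
                                      threshold = presence_threshold),
                     stringsAsFactors = FALSE)
  es <- epistasis_over_tree(scheme, meas, "richness")
  surv <- survivor_sets(comp, presence_threshold)
  for (e in setdiff(scheme$environments$env_id, names(surv)))
    surv[[e]] <- character(0)
  lab <- classify_over_tree(scheme, surv)
  tabp <- table(factor(lab$type, levels = c("I", "II", "III", "IV")))
  list(E_S = es, E_S_mean = mean(es$E, na.rm = TRUE),
       type_prevalence_pct = stats::setNames(
         100 * as.numeric(tabp) / sum(tabp), names(tabp)))
}
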