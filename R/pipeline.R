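#' Default occupancy panel for the screen's five representative ligands
#'
#' The association constants and assay concentrations of the five
#' cluster-representative ligands used in the SPR validation: prednisone
#' (K = 1e3 1/M at 2.5 mM), warfarin (two sites, 2e5 and 5e4 1/M at 1 mM),
#' mefenamic acid (4e5 and 1e5 1/M at 250 uM), levothyroxine (1e5 1/M,
#' 4 sites, solubility-limited at 15 uM, evaluated with depletion against
#' 2.5--40 uM HSA) and propranolol (1e4 1/M at 1 mM).
#'
#' @return `data.frame` usable with [occupancy_table()].
#' @export
representative_ligand_panel <- function() {
  data.frame(
    ligand = c("prednisone", "warfarin", "warfarin", "mefenamic acid",
               "mefenamic acid", "levothyroxine", "levothyroxine",
               "propranolol"),
    site = c(1L, 1L, 2L, 1L, 2L, 1L, 1L, 1L),
    K = c(1e3, 2e5, 5e4, 4e5, 1e5, 1e5, 1e5, 1e4),
    ligand_conc = c(2.5e-3, 1e-3, 1e-3, 250e-6, 250e-6, 15e-6, 15e-6, 1e-3),
    hsa_conc = c(NA, NA, NA, NA, NA, 2.5e-6, 40e-6, NA),
    n_sites = c(1L, 1L, 1L, 1L, 1L, 4L, 4L, 2L),
    stringsAsFactors = FALSE
  )
}

read_run_config <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    config <- if (grepl("\\.ya?ml$", config)) {
      yaml::read_yaml(config)
    } else {
      jsonlite::read_json(config, simplifyVector = TRUE)
    }
  }
  stopifnot(is.list(config))
  defaults <- list(
    seed = 1L,
    out_dir = NULL,
    stages = c("filter", "cluster", "occupancy", "spr"),
    generator = list(),
    thresholds = list(),
    k = 5L,
    linkage = "average",
    top_m = 3L,
    occupancy = NULL,
    spr = list(
      baseline = list(ka1 = 2.7e2, kd1 = 0.216e-4, ka2 = 8.9e2, kd2 = 26e-4),
      ligand = NULL,
      rmax1 = 100, rmax2 = 100,
      t_assoc = 300, t_dissoc = 2400, dt = 2
    )
  )
  cfg <- modifyList(defaults, config)
  for (pth in c("ligand_table", "sites")) {
    p <- cfg$inputs[[pth]]
    if (!is.null(p) && !file.exists(p)) {
      stopf("configured input path does not exist: %s", p)
    }
  }
  cfg
}

#' Run the screening pipeline end to end
#'
#' Executes the configured stages in order -- generate/ingest, filter,
#' cluster + rank, occupancy, SPR simulate + fit -- writing one plain-text
#' artifact per stage under `out_dir` (if given) and returning a summary
#' report. Every artifact and the report are stamped with the seed and the
#' MD5 hash of the resolved configuration, and a fixed seed makes the whole
#' run reproducible.
#'
#' The configuration is a named list (or path to a YAML/JSON file) with
#' optional entries `seed`, `out_dir`, `stages` (subset of `"filter"`,
#' `"cluster"`, `"occupancy"`, `"spr"`), `generator` (arguments to
#' [generator_config()]), `thresholds` (arguments to
#' [filter_thresholds()]), `k`, `linkage`, `top_m`, `occupancy` (rows for
#' [occupancy_table()]; defaults to [representative_ligand_panel()]),
#' `spr` (baseline and optional ligand rate sets plus acquisition
#' settings), and `inputs` (paths to a ligand-table CSV and/or sites JSON
#' to ingest instead of generating).
#'
#' @param config Named list or path to a YAML/JSON config file.
#' @return An object of class `run_report`.
#' @export
#' @examples
#' rep <- run_pipeline(list(seed = 7,
#'                          generator = list(n_ligands = 60,
#'                                           sites_per_cluster = 4),
#'                          stages = c("filter", "cluster", "occupancy")))
#' rep$filter$survivors_after_stage
run_pipeline <- function(config = list()) {
  cfg <- read_run_config(config)
  gen <- do.call(generator_config,
                 modifyList(list(seed = cfg$seed), cfg$generator))
  out_dir <- cfg$out_dir
  if (!is.null(out_dir) && !dir.exists(out_dir)) {
    dir.create(out_dir, recursive = TRUE)
  }
  save_json <- function(x, name) {
    if (!is.null(out_dir)) {
      jsonlite::write_json(x, file.path(out_dir, name), auto_unbox = TRUE,
                           digits = NA, pretty = TRUE, force = TRUE)
    }
  }
  cfg_hash <- {
    tmp <- tempfile(fileext = ".json")
    on.exit(unlink(tmp), add = TRUE)
    jsonlite::write_json(cfg, tmp, auto_unbox = TRUE, force = TRUE,
                         digits = NA)
    unname(tools::md5sum(tmp))
  }
  report <- list(seed = cfg$seed, config_hash = cfg_hash,
                 stages_run = character(0))
  run_stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stopf("pipeline stage '%s' failed: %s", name, conditionMessage(e))
    })
  }

  if ("filter" %in% cfg$stages) {
    report$stages_run <- c(report$stages_run, "filter")
    ligands <- run_stage("filter", {
      if (!is.null(cfg$inputs$ligand_table)) {
        read_ligand_table(cfg$inputs$ligand_table)
      } else {
        gen_ligand_table(gen)
      }
    })
    thr <- do.call(filter_thresholds, cfg$thresholds)
    fr <- run_stage("filter", apply_filters(ligands, thr))
    if (!is.null(out_dir)) {
      write_ligand_table(ligands, file.path(out_dir, "ligands.csv"))
      write_filter_report(fr, file.path(out_dir, "filter_report.json"))
    }
    report$filter <- list(
      n_input = fr$n_input,
      survivors_after_stage = as.list(fr$survivors_after_stage),
      n_panel = length(fr$passing_ids)
    )
  }

  if ("cluster" %in% cfg$stages) {
    report$stages_run <- c(report$stages_run, "cluster")
    sites <- run_stage("cluster", {
      if (!is.null(cfg$inputs$sites)) {
        read_binding_sites(cfg$inputs$sites)
      } else {
        gen_binding_sites(gen)
      }
    })
    model <- run_stage("cluster", cluster_sites(sites, k = cfg$k,
                                                linkage = cfg$linkage))
    reps <- select_representatives(model, top_m = cfg$top_m)
    if (!is.null(out_dir)) {
      write_binding_sites(sites, file.path(out_dir, "sites.json"))
      write.csv(reps, file.path(out_dir, "representatives.csv"),
                row.names = FALSE)
      save_json(lapply(model$clusters, function(cl)
        list(n = cl$n, a = cl$a, freq = cl$freq)), "cluster_model.json")
    }
    report$cluster <- list(
      k = model$k,
      sizes = vapply(model$clusters, `[[`, integer(1), "n"),
      representatives = reps
    )
  }

  if ("occupancy" %in% cfg$stages) {
    report$stages_run <- c(report$stages_run, "occupancy")
    specs <- if (is.null(cfg$occupancy)) {
      representative_ligand_panel()
    } else {
      as.data.frame(cfg$occupancy, stringsAsFactors = FALSE)
    }
    occ <- run_stage("occupancy", occupancy_table(specs))
    if (!is.null(out_dir)) {
      write.csv(occ, file.path(out_dir, "occupancy.csv"), row.names = FALSE)
    }
    report$occupancy <- occ
  }

  if ("spr" %in% cfg$stages) {
    report$stages_run <- c(report$stages_run, "spr")
    sp <- cfg$spr
    fit_condition <- function(rates, label, seed_offset) {
      kp <- do.call(kinetic_params, as.list(rates))
      sgs <- lapply(seq_along(gen$analyte_concs), function(i) {
        gen_sensorgram(kp, sp$rmax1, sp$rmax2, gen$analyte_concs[i],
                       t_assoc = sp$t_assoc, t_dissoc = sp$t_dissoc,
                       dt = sp$dt, noise_sd = gen$noise_sd,
                       seed = cfg$seed + seed_offset + i)
      })
      if (!is.null(out_dir)) {
        for (i in seq_along(sgs)) {
          write_sensorgram(sgs[[i]], file.path(
            out_dir, sprintf("sensorgram_%s_%02d.csv", label, i)))
        }
      }
      run_stage("spr", fit_heterogeneous(sgs))
    }
    base_fit <- fit_condition(sp$baseline, "baseline", 1000L)
    report$spr <- list(baseline = list(estimates = as.list(base_fit$estimates),
                                       sds = as.list(base_fit$sds)))
    if (!is.null(sp$ligand)) {
      lig_fit <- fit_condition(sp$ligand, "ligand", 2000L)
      report$spr$ligand <- list(estimates = as.list(lig_fit$estimates),
                                sds = as.list(lig_fit$sds))
      report$spr$fold_change <- fold_change(lig_fit, base_fit)
      report$spr$delta_delta_g <- as.list(delta_delta_g(lig_fit, base_fit))
    }
    if (!is.null(out_dir)) {
      est <- data.frame(condition = "baseline",
                        t(base_fit$estimates), t(base_fit$sds))
      if (!is.null(sp$ligand)) {
        est <- rbind(est, data.frame(condition = "ligand",
                                     t(lig_fit$estimates), t(lig_fit$sds)))
      }
      write.csv(est, file.path(out_dir, "spr_estimates.csv"),
                row.names = FALSE)
    }
  }

  class(report) <- "run_report"
  save_json(unclass(report), "report.json")
  report
}

#' @export
print.run_report <- function(x, ...) {
  cat("Screening pipeline run (seed", x$seed, ", config",
      substr(x$config_hash, 1, 8), ")\n")
  cat("Stages:", paste(x$stages_run, collapse = " -> "), "\n")
  if (!is.null(x$filter)) {
    cat(sprintf("  filter: %d records in, %d in final panel\n",
                x$filter$n_input, x$filter$n_panel))
  }
  if (!is.null(x$cluster)) {
    cat("  cluster sizes:", paste(x$cluster$sizes, collapse = ", "), "\n")
  }
  if (!is.null(x$occupancy)) {
    cat("  occupancy rows:", nrow(x$occupancy), "(",
        paste(range(x$occupancy$percent), collapse = "-"), "% )\n")
  }
  if (!is.null(x$spr)) {
    cat(sprintf("  SPR baseline: KD1 = %.3g M, KD2 = %.3g M\n",
                x$spr$baseline$estimates$KD1, x$spr$baseline$estimates$KD2))
    if (!is.null(x$spr$fold_change)) {
      fc <- x$spr$fold_change
      cat(sprintf("  ligand effect: KD1 %s x%.1f, KD2 %s x%.1f\n",
                  fc$direction[1], fc$factor[1],
                  fc$direction[2], fc$factor[2]))
    }
  }
  invisible(x)
}
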