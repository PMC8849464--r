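pipeline_defaults <- function() {
  list(
    stages = c("simulate", "popgen", "outliers", "ibd", "optimize", "current"),
    out_dir = "landgen_out",
    seed = 1L,
    simulate = list(n_sites = 25, samples_per_site = 10, n_dual_sites = 7,
                    n_loci = 2500, n_outlier_loci = 5,
                    grid_shape = c(100, 100), cell_size = 250,
                    gaussian_field_range = 5000,
                    true_transform = list(variant = 1, shape = 0.3,
                                          max_resistance = 100),
                    covariance_scale = NULL, baseline_fst = 0.1,
                    ecotope_shift = 2, missing_rate = 0.02,
                    min_separation = 1000),
    popgen = list(n_perm = 999),
    outliers = list(n_trees = 5000, rf_threshold = 3, sd_thresholds = c(2, 3),
                    trim_low = 0.06, trim_high = 0.35, he_min = 0.1,
                    q_cut = 0.05, alpha = 0.05),
    ibd = list(n_perm = 9999),
    optimize = list(generations = 50, pop_mult = 20, patience = 10,
                    bootstrap_iterations = 500, bootstrap_frac = 0.85,
                    rho_warning = 0.29),
    current = list(connectivity = 8)
  )
}

## recursively apply defaults and reject unknown keys
merge_config <- function(defaults, user, path = "") {
  if (is.null(user)) return(defaults)
  unknown <- setdiff(names(user), names(defaults))
  if (length(unknown)) {
    stop("unknown config key(s): ",
         paste0(path, unknown, collapse = ", "))
  }
  for (k in names(user)) {
    if (is.list(defaults[[k]]) && !is.null(names(defaults[[k]]))) {
      defaults[[k]] <- merge_config(defaults[[k]], user[[k]],
                                    paste0(path, k, "."))
    } else {
      defaults[[k]] <- user[[k]]
    }
  }
  defaults
}

#' Validate a pipeline configuration file
#'
#' Reads a YAML (or JSON) configuration, applies defaults, and errors on
#' unknown keys or out-of-range values. An empty file yields the full default
#' configuration.
#'
#' @param path YAML/JSON config file, or `NULL` for pure defaults.
#' @return a validated `run_config` list.
#' @export
validate_config <- function(path = NULL) {
  user <- if (is.null(path)) list() else yaml::read_yaml(path)
  if (is.null(user)) user <- list()
  cfg <- merge_config(pipeline_defaults(), user)
  problems <- character(0)
  chk <- function(ok, msg) if (!ok) problems <<- c(problems, msg)
  chk(all(cfg$stages %in% pipeline_defaults()$stages),
      "stages contains unknown stage names")
  chk(is.numeric(cfg$seed) && length(cfg$seed) == 1, "seed must be an integer")
  chk(cfg$outliers$trim_low >= 0 && cfg$outliers$trim_low < 1,
      "outliers.trim_low out of [0, 1)")
  chk(cfg$outliers$trim_high >= 0 && cfg$outliers$trim_high < 1,
      "outliers.trim_high out of [0, 1)")
  chk(cfg$outliers$q_cut > 0 && cfg$outliers$q_cut < 1,
      "outliers.q_cut out of (0, 1)")
  chk(cfg$outliers$alpha > 0 && cfg$outliers$alpha < 1,
      "outliers.alpha out of (0, 1)")
  chk(cfg$simulate$baseline_fst > 0 && cfg$simulate$baseline_fst < 1,
      "simulate.baseline_fst out of (0, 1)")
  chk(cfg$simulate$missing_rate >= 0 && cfg$simulate$missing_rate < 1,
      "simulate.missing_rate out of [0, 1)")
  chk(cfg$optimize$bootstrap_frac > 0 && cfg$optimize$bootstrap_frac <= 1,
      "optimize.bootstrap_frac out of (0, 1]")
  if (length(problems)) {
    stop("invalid configuration:\n  ", paste(problems, collapse = "\n  "))
  }
  cfg$seed <- as.integer(cfg$seed)
  structure(cfg, class = "run_config")
}

stage_files_checksums <- function(files) {
  files <- files[file.exists(files)]
  as.list(tools::md5sum(files))
}

#' Run the landscape-genomics pipeline on synthetic data
#'
#' Executes the requested stages in dependency order — simulate, popgen,
#' outliers, ibd, optimize, current — writing each stage's outputs under the
#' configured directory and recording a manifest (config hash, package
#' version, per-stage output checksums, timings, seed registry). Identical
#' configurations reproduce byte-identical outputs for every deterministic
#' stage.
#'
#' @param config a `run_config` from [validate_config()] (or a path to one).
#' @return the manifest, invisibly; also written as `manifest.json`.
#' @export
run_pipeline <- function(config = validate_config()) {
  if (is.character(config)) config <- validate_config(config)
  out <- config$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(
    package_version = as.character(utils::packageVersion("landgenr")),
    config_hash = substr(tools::md5sum(
      writeLines_tmp(jsonlite::toJSON(unclass(config), auto_unbox = TRUE)))[[1]],
      1, 12),
    seed = config$seed, stages = list())
  seeds <- list()
  state <- new.env()

  run_stage <- function(name, fun) {
    if (!name %in% config$stages) return(invisible(NULL))
    t0 <- Sys.time()
    files <- fun()
    manifest$stages[[name]] <<- list(
      completed = TRUE,
      seconds = round(as.numeric(difftime(Sys.time(), t0, units = "secs")), 2),
      outputs = stage_files_checksums(files))
  }

  res <- try({
    run_stage("simulate", function() {
      seeds$simulate <<- config$seed
      cfgs <- config$simulate
      sc <- sim_config(n_sites = cfgs$n_sites,
                       samples_per_site = cfgs$samples_per_site,
                       n_dual_sites = cfgs$n_dual_sites,
                       n_loci = cfgs$n_loci,
                       n_outlier_loci = cfgs$n_outlier_loci,
                       grid_shape = unlist(cfgs$grid_shape),
                       cell_size = cfgs$cell_size,
                       gaussian_field_range = cfgs$gaussian_field_range,
                       true_transform = cfgs$true_transform,
                       covariance_scale = cfgs$covariance_scale,
                       baseline_fst = cfgs$baseline_fst,
                       ecotope_shift = cfgs$ecotope_shift,
                       missing_rate = cfgs$missing_rate,
                       min_separation = cfgs$min_separation,
                       seed = config$seed)
      ds <- simulate_landscape_dataset(sc)
      state$ds <- ds
      gfiles <- write_genotypes(ds$gm, out)
      utils::write.csv(ds$sites, file.path(out, "sites.csv"), row.names = FALSE)
      write_ascii_grid(ds$elevation, file.path(out, "elevation.asc"))
      write_ascii_grid(ds$truth$true_resistance,
                       file.path(out, "true_resistance.asc"))
      truth_json <- file.path(out, "truth.json")
      jsonlite::write_json(
        list(outlier_locus_ids = ds$truth$outlier_locus_ids,
             lambda = ds$truth$lambda, p0 = unname(ds$truth$p0)),
        truth_json, auto_unbox = TRUE, digits = NA)
      c(gfiles, file.path(out, c("sites.csv", "elevation.asc",
                                 "true_resistance.asc", "truth.json")))
    })

    run_stage("popgen", function() {
      ds <- state$ds
      seeds$popgen <<- substream_seed(config$seed, 2L)
      div <- diversity_stats(ds$gm, "site")
      utils::write.csv(div, file.path(out, "diversity.csv"), row.names = FALSE)
      gst <- gst_hedrick(ds$gm, "site")
      state$gst <- gst
      fst <- pairwise_fst_nei(ds$gm, "site", n_perm = config$popgen$n_perm,
                              seed = seeds$popgen)
      fstm <- fst_meirmans(ds$gm, "site")
      utils::write.csv(as.data.frame(unclass(gst)),
                       file.path(out, "gst_hedrick.csv"))
      utils::write.csv(as.data.frame(unclass(fst$dm)),
                       file.path(out, "fst_nei.csv"))
      utils::write.csv(as.data.frame(fst$q), file.path(out, "fst_nei_q.csv"))
      utils::write.csv(as.data.frame(unclass(fstm)),
                       file.path(out, "fst_meirmans.csv"))
      hf <- hierarchical_f(ds$gm, "ecotope", n_perm = config$popgen$n_perm,
                           seed = seeds$popgen)
      utils::write.csv(hf, file.path(out, "hierarchical_f.csv"),
                       row.names = FALSE)
      file.path(out, c("diversity.csv", "gst_hedrick.csv", "fst_nei.csv",
                       "fst_nei_q.csv", "fst_meirmans.csv",
                       "hierarchical_f.csv"))
    })

    run_stage("outliers", function() {
      ds <- state$ds
      seeds$outliers <<- substream_seed(config$seed, 3L)
      sub <- ds$gm  # domestic vs wild across all sites, spatially corrected
      res <- outlier_suite(sub, n_trees = config$outliers$n_trees,
                           rf_threshold = config$outliers$rf_threshold,
                           seed = seeds$outliers)
      tab <- data.frame(
        locus_id = colnames(sub$geno),
        importance = res$rf$importance,
        z_loading = res$rda$z,
        fst = res$outflank$table$fst, het = res$outflank$table$he,
        p = res$outflank$table$p, q = res$outflank$table$q,
        flag_rf = res$consensus$flags[, "rf"],
        flag_rda = res$consensus$flags[, "rda"],
        flag_outflank = res$consensus$flags[, "outflank"],
        flag_fsthet = res$consensus$flags[, "fsthet"],
        consensus_count = res$consensus$method_count)
      utils::write.table(tab, file.path(out, "outliers.tsv"), sep = "\t",
                         row.names = FALSE, quote = FALSE)
      jsonlite::write_json(
        list(n_ranked_rf = length(res$rf$ranked_loci),
             best_oob_er = if (is.null(res$purge)) NA else res$purge$best_oob_er,
             rda_p = res$rda$p,
             n_flagged = as.list(colSums(res$consensus$flags)),
             consensus_all = res$consensus$all_methods),
        file.path(out, "outliers_summary.json"), auto_unbox = TRUE,
        digits = NA)
      file.path(out, c("outliers.tsv", "outliers_summary.json"))
    })

    run_stage("ibd", function() {
      ds <- state$ds
      seeds$ibd <<- substream_seed(config$seed, 4L)
      res <- ibd_ecotope_analysis(ds$gm, n_perm = config$ibd$n_perm,
                                  seed = seeds$ibd)
      co <- summary(res$fit_interaction)$coefficients
      utils::write.csv(data.frame(term = rownames(co), co, row.names = NULL),
                       file.path(out, "ibd_coefficients.csv"),
                       row.names = FALSE)
      jsonlite::write_json(
        list(mantel = res$mantel,
             contrast = res$contrast,
             rho = res$fit_interaction$rho,
             logLik = res$fit_interaction$logLik),
        file.path(out, "ibd_summary.json"), auto_unbox = TRUE, digits = NA)
      file.path(out, c("ibd_coefficients.csv", "ibd_summary.json"))
    })

    run_stage("optimize", function() {
      ds <- state$ds
      seeds$optimize <<- substream_seed(config$seed, 5L)
      gst <- if (!is.null(state$gst)) state$gst else gst_hedrick(ds$gm, "site")
      surf <- list(elevation = list(raster = rescale_surface(ds$elevation),
                                    type = "continuous"))
      m_elev <- ga_optimise(surf, gst, ds$sites,
                            ga_config = list(
                              generations = config$optimize$generations,
                              pop_mult = config$optimize$pop_mult,
                              patience = config$optimize$patience,
                              seed = seeds$optimize))
      m_dist <- distance_model(gst, ds$sites)
      m_null <- null_model(gst)
      models <- list(m_elev, m_dist, m_null)
      state$best_resistance <- m_elev$resistance
      sel <- model_selection(models)
      utils::write.csv(sel, file.path(out, "model_selection.csv"),
                       row.names = FALSE)
      boot <- bootstrap_rank(models, ds$sites, gst,
                             frac = config$optimize$bootstrap_frac,
                             n_boot = config$optimize$bootstrap_iterations,
                             seed = seeds$optimize)
      utils::write.csv(boot, file.path(out, "bootstrap_rank.csv"),
                       row.names = FALSE)
      jsonlite::write_json(m_elev$params,
                           file.path(out, "optimised_parameters.json"),
                           auto_unbox = TRUE, digits = NA)
      file.path(out, c("model_selection.csv", "bootstrap_rank.csv",
                       "optimised_parameters.json"))
    })

    run_stage("current", function() {
      ds <- state$ds
      resistance <- if (!is.null(state$best_resistance))
        state$best_resistance else ds$truth$true_resistance
      cm <- current_map(resistance, ds$sites,
                        connectivity = config$current$connectivity)
      write_ascii_grid(cm$map, file.path(out, "current_map.asc"))
      utils::write.csv(as.data.frame(unclass(cm$r_eff)),
                       file.path(out, "pairwise_effective_resistance.csv"))
      file.path(out, c("current_map.asc",
                       "pairwise_effective_resistance.csv"))
    })
  }, silent = TRUE)

  if (inherits(res, "try-error")) {
    manifest$error <- attr(res, "condition")$message
  }
  manifest$seed_registry <- seeds
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (inherits(res, "try-error")) {
    stop("pipeline stage failed: ", manifest$error)
  }
  invisible(manifest)
}

## write a string to a temp file and return the path (for hashing)
writeLines_tmp <- function(x) {
  f <- tempfile()
  writeLines(x, f)
  f
}
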