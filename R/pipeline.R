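#' Pipeline configuration
#'
#' Collects every tunable of the workflow with its conventional default:
#' the five-record minimum, the AUC 0.75 / TSS 0.3 exclusion cutoffs, the
#' VIF 10 collinearity threshold, the 400 km dispersal cutoff, and the
#' 50 km analysis grid on a 10 km modelling raster. Synthetic-mode settings
#' (grid, autocorrelation, niche breadths, scenario roster and trend) define
#' the simulated study conditions.
#'
#' @param n_species number of virtual species.
#' @param grid_shape fine grid `(rows, cols)`.
#' @param cell_size_km fine cell edge (km).
#' @param coarse_km coarse analysis cell edge (km).
#' @param variable_names environmental layer names.
#' @param autocorr_length_km spatial autocorrelation length of the layers.
#' @param n_presence presence records sampled per species.
#' @param n_background background points per species.
#' @param min_records minimum unique presence cells per species.
#' @param auc_min,tss_min model exclusion cutoffs.
#' @param vif_max VIF selection threshold.
#' @param dispersal_km isolated-patch distance cutoff.
#' @param test_frac held-out evaluation fraction.
#' @param algorithms algorithm roster.
#' @param slices future time slices.
#' @param slice_scale named multiplier per slice applied to the trend.
#' @param gcms pseudo circulation-model ids.
#' @param rcps pseudo emission-pathway ids.
#' @param rcp_scale named multiplier per pathway applied to the trend.
#' @param trend per-layer climate trend (layer sd units); recycled.
#' @param gcm_noise_sd sd of the circulation-model perturbation field.
#' @param occupancy_threshold virtual-species occupancy threshold.
#' @param breadth_range niche breadth range (layer sd units).
#' @param min_range_cells minimum simulated true-range size (cells).
#' @param n_perm LCBD permutations.
#' @param vif_subsample max cells used for VIF before seeded subsampling.
#' @param extra_species optional list of [virtual_species()] appended to the
#'   simulated community (e.g. planted ground-truth cases).
#' @param seed master seed; all stage seeds derive from it.
#' @return a list of class `pipeline_config`.
#' @export
pipeline_config <- function(n_species = 20,
                            grid_shape = c(40, 40),
                            cell_size_km = 10,
                            coarse_km = 50,
                            variable_names = c("env1", "env2", "env3"),
                            autocorr_length_km = 50,
                            n_presence = 200,
                            n_background = 1000,
                            min_records = 5,
                            auc_min = 0.75,
                            tss_min = 0.3,
                            vif_max = 10,
                            dispersal_km = 400,
                            test_frac = 0.2,
                            algorithms = c("glm", "brt", "rf", "svm"),
                            slices = c("2050", "2070"),
                            slice_scale = c("2050" = 1.0, "2070" = 1.6),
                            gcms = c("gcmA", "gcmB"),
                            rcps = c("rcp_low", "rcp_high"),
                            rcp_scale = c(rcp_low = 0.4, rcp_high = 1.0),
                            trend = c(1.0, 0.5, 0),
                            gcm_noise_sd = 0.25,
                            occupancy_threshold = 0.3,
                            breadth_range = c(0.5, 1.5),
                            min_range_cells = 250,
                            n_perm = 999,
                            vif_subsample = 1e5,
                            extra_species = NULL,
                            seed = 1L) {
  cfg <- as.list(environment())
  cfg$trend <- rep_len(trend, length(variable_names))
  stopifnot(all(slices %in% names(slice_scale)),
            all(rcps %in% names(rcp_scale)),
            all(algorithms %in% c("glm", "brt", "rf", "svm")))
  structure(cfg, class = "pipeline_config")
}

#' Run the full synthetic-data experiment
#'
#' Executes every stage in order: climate simulation, virtual community and
#' occurrence sampling, rare-species filter, VIF variable selection,
#' per-species model fitting and evaluation for each algorithm, ensemble
#' means and consensus thresholds, binarisation, dispersal filtering of the
#' future projections, total-loss detection, and the alpha/beta diversity
#' summaries per time slice. Fully deterministic given `config$seed`.
#'
#' @param config a [pipeline_config()].
#' @param out_dir optional directory; when given, CSV artifacts and a JSON
#'   provenance manifest are written.
#' @param verbose print stage progress.
#' @return a list of class `enmdiv_run`; see the vignette for the layout.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = NULL,
                         verbose = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  say <- function(...) if (verbose) message(sprintf(...))
  master <- config$seed

  say("stage 1/6: simulating climate and virtual community")
  clim <- generate_climate(config$grid_shape, config$variable_names,
                           config$autocorr_length_km, config$cell_size_km,
                           seed = derive_seed(master, "climate"))
  species <- simulate_virtual_community(config$n_species, clim,
                                        config$breadth_range,
                                        config$occupancy_threshold,
                                        config$min_range_cells,
                                        seed = derive_seed(master, "community"))
  if (!is.null(config$extra_species)) {
    for (sp in config$extra_species) species[[sp$species_id]] <- sp
  }
  occs <- lapply(species, function(sp)
    sample_occurrences(sp, clim, config$n_presence,
                       seed = derive_seed(master, "occ", sp$species_id)))

  # future climates, one per slice x gcm x rcp member
  future_clims <- list()
  for (sl in config$slices) for (g in config$gcms) for (r in config$rcps) {
    future_clims[[paste(sl, g, r, sep = ".")]] <- shift_climate(
      clim, config$trend, gcm_noise_sd = config$gcm_noise_sd,
      rcp_scale = config$rcp_scale[[r]] * config$slice_scale[[sl]],
      slice = sl, gcm_id = g, rcp_id = r,
      seed = derive_seed(master, "gcm"))
  }
  # per-slice mean climate across members, as ground truth for recovery
  slice_mean_clim <- lapply(config$slices, function(sl) {
    members <- future_clims[grep(paste0("^", sl, "\\."), names(future_clims))]
    layers <- lapply(config$variable_names, function(v)
      Reduce(`+`, lapply(members, function(m) m$layers[[v]])) / length(members))
    names(layers) <- config$variable_names
    climate_stack(layers, config$cell_size_km, slice = sl,
                  gcm_id = "mean", rcp_id = "mean")
  })
  names(slice_mean_clim) <- config$slices

  say("stage 2/6: rare-species filter and VIF variable selection")
  occs <- filter_rare_species(occs, config$min_records)
  species <- species[names(occs)]
  cells <- grid_covariates(clim)
  if (nrow(cells) > config$vif_subsample) {
    set.seed(derive_seed(master, "vifsub"))
    cells <- cells[sample(nrow(cells), config$vif_subsample), , drop = FALSE]
  }
  vif <- select_variables(cells, threshold = config$vif_max)
  vars <- vif$retained

  say("stage 3/6: fitting %d species x %d algorithms",
      length(species), length(config$algorithms))
  eval_rows <- list()
  models <- list()
  for (sid in names(species)) {
    occ <- occs[[sid]]
    bg <- make_background(clim, occ$presences, config$n_background,
                          seed = derive_seed(master, "bg", sid))
    pts <- rbind(occ$presences, bg)
    y <- c(rep(1L, nrow(occ$presences)), rep(0L, nrow(bg)))
    xv <- extract_covariates(clim, pts, vars)
    split <- train_test_split(y, config$test_frac,
                              seed = derive_seed(master, "split", sid))
    models[[sid]] <- list()
    for (alg in config$algorithms) {
      fit <- enm_fit(xv[split$train, , drop = FALSE], y[split$train], alg,
                     seed = derive_seed(master, "fit", sid, alg))
      ev <- enm_evaluate(fit, xv[split$test, , drop = FALSE], y[split$test],
                         config$auc_min, config$tss_min)
      models[[sid]][[alg]] <- list(fit = fit, eval = ev)
      eval_rows[[paste(sid, alg)]] <- data.frame(
        species = sid, algorithm = alg, n_presence = nrow(occ$presences),
        auc = ev$auc, tss = ev$tss, threshold_eq = ev$threshold_eq,
        passed = ev$passed)
    }
  }
  eval_table <- do.call(rbind, c(eval_rows, make.row.names = FALSE))

  say("stage 4/6: ensembles, binarisation, dispersal filter")
  grid_x <- grid_covariates(clim, vars)
  future_x <- lapply(future_clims, grid_covariates, variables = vars)
  baseline_ranges <- list(); future_ranges <- list()
  unmodelable <- character(0)
  for (sid in names(species)) {
    passing <- Filter(function(m) m$eval$passed, models[[sid]])
    if (length(passing) == 0) {
      unmodelable <- c(unmodelable, sid)
      next
    }
    mk_map <- function(x, scen) lapply(names(passing), function(alg) {
      v <- matrix(predict(passing[[alg]]$fit, x),
                  config$grid_shape[1], config$grid_shape[2])
      suitability_map(sid, v, scen,
                      data.frame(algorithm = alg, gcm_id = scen$gcm_id,
                                 rcp_id = scen$rcp_id),
                      config$cell_size_km)
    })
    thr <- consensus_threshold(vapply(passing, function(m)
      m$eval$threshold_eq, 0))
    base_ens <- ensemble_mean(mk_map(grid_x, clim$scenario))
    baseline_ranges[[sid]] <- binarize(base_ens, thr)
    future_ranges[[sid]] <- list()
    for (sl in config$slices) {
      members <- list()
      for (key in names(future_clims)) {
        if (!startsWith(key, paste0(sl, "."))) next
        scen <- future_clims[[key]]$scenario
        members <- c(members, mk_map(future_x[[key]], scen))
      }
      ens <- ensemble_mean(members)
      rng <- binarize(ens, thr)
      future_ranges[[sid]][[sl]] <- dispersal_filter(
        rng, baseline_ranges[[sid]], occs[[sid]]$presences,
        max_km = config$dispersal_km)
    }
  }
  loss <- detect_total_loss(future_ranges)

  say("stage 5/6: diversity metrics per slice")
  grid <- grid_system(config$grid_shape, config$cell_size_km, config$coarse_km)
  pa <- list(baseline = build_pa_matrix(baseline_ranges, grid))
  for (sl in config$slices)
    pa[[sl]] <- build_pa_matrix(lapply(future_ranges, `[[`, sl), grid)
  rich <- lapply(pa, richness)
  rich_change <- list(); t_tests <- list()
  for (sl in config$slices) {
    rich_change[[sl]] <- richness_change(rich$baseline, rich[[sl]])
    t_tests[[sl]] <- tryCatch(
      paired_richness_test(rich$baseline, rich[[sl]]),
      error = function(e) NULL)
  }
  beta <- lapply(names(pa), function(sl) {
    m <- pa[[sl]][rowSums(pa[[sl]]) > 0, , drop = FALSE]
    if (nrow(m) < 2) return(NULL)
    # a slice can degenerate under extreme scenarios (all surviving sites
    # identical); beta diversity is then undefined for it
    res <- tryCatch(
      lcbd_permutation_test(pa[[sl]], n_perm = config$n_perm,
                            seed = derive_seed(master, "perm", sl)),
      error = function(e) NULL)
    if (is.null(res)) return(NULL)
    trip <- decompose_pairs(m)
    list(lcbd = res, triplets = trip, centroid = mean_triplet(trip))
  })
  names(beta) <- names(pa)

  say("stage 6/6: ground truth and recovery summaries")
  truth_range <- list(baseline = lapply(species, true_range, clim = clim))
  for (sl in config$slices)
    truth_range[[sl]] <- lapply(species, true_range,
                                clim = slice_mean_clim[[sl]])
  truth_rich <- lapply(truth_range, function(rl)
    richness(vapply(rl, aggregate_to_grid, logical(nrow(grid$sites)),
                    grid = grid)))
  # recovery compares the stacked prediction against the truth of the same
  # species set: species excluded by the evaluation filter cannot appear in
  # the stack, so their true ranges are left out of the reference too
  modelled <- names(baseline_ranges)
  truth_rich_modelled <- lapply(truth_range, function(rl)
    richness(vapply(rl[modelled], aggregate_to_grid,
                    logical(nrow(grid$sites)), grid = grid)))
  recovery <- vapply(names(pa), function(sl)
    stats::cor(rich[[sl]], truth_rich_modelled[[sl]], method = "spearman"),
    0)

  run <- structure(list(
    config = config, climate = clim, future_climates = future_clims,
    species = species, occurrences = occs, vif = vif, variables = vars,
    eval_table = eval_table, models = models,
    baseline_ranges = baseline_ranges, future_ranges = future_ranges,
    unmodelable = unmodelable, total_loss = loss,
    grid = grid, pa = pa, richness = rich, richness_change = rich_change,
    t_tests = t_tests, beta = beta,
    truth = list(ranges = truth_range, richness = truth_rich,
                 recovery_spearman = recovery)
  ), class = "enmdiv_run")
  if (!is.null(out_dir)) write_run(run, out_dir)
  run
}

#' @export
print.enmdiv_run <- function(x, ...) {
  cfg <- x$config
  cat(sprintf("enmdiv run: %d species on a %dx%d grid (%g km cells), seed %d\n",
              length(x$species), cfg$grid_shape[1], cfg$grid_shape[2],
              cfg$cell_size_km, cfg$seed))
  cat(sprintf("variables retained by VIF < %g: %s\n", cfg$vif_max,
              paste(x$variables, collapse = ", ")))
  agg <- stats::aggregate(cbind(auc, tss) ~ algorithm, x$eval_table, mean)
  cat("mean evaluation metrics by algorithm:\n")
  print(agg, row.names = FALSE, digits = 3)
  cat(sprintf("species passing in >= 1 algorithm: %d of %d\n",
              length(x$baseline_ranges), length(x$species)))
  bd_base <- if (is.null(x$beta$baseline)) NA_real_ else x$beta$baseline$lcbd$bdtotal
  for (sl in cfg$slices) {
    n_lost <- length(x$total_loss$by_slice[[sl]])
    bd <- if (is.null(x$beta[[sl]])) NA_real_ else x$beta[[sl]]$lcbd$bdtotal
    cat(sprintf("%s: %d species with no suitable area; BDtotal %.4f (baseline %.4f)\n",
                sl, n_lost, bd, bd_base))
  }
  cat("richness recovery (Spearman vs truth):",
      paste(sprintf("%s %.3f", names(x$truth$recovery_spearman),
                    x$truth$recovery_spearman), collapse = ", "), "\n")
  invisible(x)
}

#' Write run artifacts as plain-text files
#'
#' CSV tables (evaluation report, presence-absence matrices, richness and
#' LCBD per site, triplets, total-loss table, filter logs) plus a JSON
#' provenance manifest with the full configuration.
#'
#' @param run an `enmdiv_run`.
#' @param out_dir output directory.
#' @return invisibly, `out_dir`.
#' @export
write_run <- function(run, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(run$eval_table, file.path(out_dir, "model_evaluation.csv"),
                   row.names = FALSE)
  write_vif_report(run$vif, file.path(out_dir, "vif_report.csv"))
  write_occurrences(run$occurrences, file.path(out_dir, "occurrences.csv"))
  utils::write.csv(run$total_loss$table, file.path(out_dir, "total_loss.csv"),
                   row.names = FALSE)
  for (sl in names(run$pa)) {
    utils::write.csv(cbind(site_id = rownames(run$pa[[sl]]),
                           as.data.frame(run$pa[[sl]] * 1)),
                     file.path(out_dir, sprintf("pa_matrix_%s.csv", sl)),
                     row.names = FALSE)
    if (!is.null(run$beta[[sl]])) {
      b <- run$beta[[sl]]
      utils::write.csv(data.frame(site_id = names(b$lcbd$lcbd),
                                  lcbd = b$lcbd$lcbd,
                                  p_value = b$lcbd$p_value,
                                  significant = b$lcbd$significant),
                       file.path(out_dir, sprintf("lcbd_%s.csv", sl)),
                       row.names = FALSE)
      utils::write.csv(b$triplets,
                       file.path(out_dir, sprintf("triplets_%s.csv", sl)),
                       row.names = FALSE)
    }
  }
  rich <- data.frame(site_id = run$grid$sites$site_id,
                     x_km = run$grid$sites$x_km, y_km = run$grid$sites$y_km)
  for (sl in names(run$richness)) rich[[paste0("richness_", sl)]] <- run$richness[[sl]]
  utils::write.csv(rich, file.path(out_dir, "richness.csv"), row.names = FALSE)
  removals <- do.call(rbind, lapply(names(run$future_ranges), function(sid) {
    do.call(rbind, lapply(names(run$future_ranges[[sid]]), function(sl) {
      log <- run$future_ranges[[sid]][[sl]]$removal_log
      if (nrow(log) == 0) return(NULL)
      cbind(species = sid, slice = sl, log)
    }))
  }))
  if (!is.null(removals))
    utils::write.csv(removals, file.path(out_dir, "dispersal_removals.csv"),
                     row.names = FALSE)
  manifest <- run$config
  class(manifest) <- NULL
  manifest$extra_species <- lapply(manifest$extra_species, unclass)
  jsonlite::write_json(
    list(config = manifest, r_version = R.version.string,
         package_version = as.character(utils::packageVersion("enmdiv"))),
    file.path(out_dir, "manifest.json"), auto_unbox = TRUE, digits = NA,
    null = "null")
  invisible(out_dir)
}

plot_site_map <- function(grid, values, main, palette = grDevices::hcl.colors(21)) {
  nr <- max(grid$sites$coarse_row); nc <- max(grid$sites$coarse_col)
  m <- matrix(NA_real_, nr, nc)
  m[cbind(grid$sites$coarse_row, grid$sites$coarse_col)] <- values
  graphics::image(t(m)[, nr:1, drop = FALSE], col = palette, axes = FALSE,
                  main = main)
}

#' Render figures and tables for a completed run
#'
#' Writes PNG analogues of the standard output set: per-slice richness maps,
#' gain/loss maps, LCBD maps with their significance masks, richness ladder
#' plots pairing sites across slices, and ternary decomposition plots, plus
#' the summary CSVs of [write_run()].
#'
#' @param run an `enmdiv_run`.
#' @param out_dir output directory.
#' @return invisibly, the written figure paths.
#' @export
render_outputs <- function(run, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_run(run, out_dir)
  paths <- character(0)
  png_to <- function(name, expr, width = 720, height = 640) {
    p <- file.path(out_dir, name)
    grDevices::png(p, width = width, height = height)
    on.exit(grDevices::dev.off(), add = TRUE)
    expr()
    paths <<- c(paths, p)
  }
  slices <- names(run$pa)
  for (sl in slices)
    png_to(sprintf("richness_%s.png", sl), function()
      plot_site_map(run$grid, run$richness[[sl]],
                    sprintf("Species richness (%s)", sl)))
  for (sl in names(run$richness_change))
    png_to(sprintf("richness_change_%s.png", sl), function()
      plot_site_map(run$grid, run$richness_change[[sl]]$delta,
                    sprintf("Richness change baseline to %s", sl),
                    palette = grDevices::hcl.colors(21, "Blue-Red 2", rev = TRUE)))
  for (sl in slices) {
    if (is.null(run$beta[[sl]])) next
    b <- run$beta[[sl]]$lcbd
    vals <- rep(NA_real_, nrow(run$grid$sites))
    vals[match(names(b$lcbd), run$grid$sites$site_id)] <- b$lcbd
    png_to(sprintf("lcbd_%s.png", sl), function()
      plot_site_map(run$grid, vals, sprintf("LCBD (%s)", sl)))
    sig <- rep(NA_real_, nrow(run$grid$sites))
    sig[match(names(b$lcbd), run$grid$sites$site_id)] <- as.numeric(b$significant)
    png_to(sprintf("lcbd_significant_%s.png", sl), function()
      plot_site_map(run$grid, sig, sprintf("Significant LCBD, p < 0.05 (%s)", sl),
                    palette = c("grey85", "firebrick")))
    png_to(sprintf("ternary_%s.png", sl), function()
      plot_ternary(run$beta[[sl]]$triplets,
                   main = sprintf("Beta-diversity decomposition (%s)", sl)))
  }
  png_to("richness_ladder.png", function() {
    graphics::matplot(t(do.call(cbind, run$richness)), type = "l", lty = 1,
                      col = grDevices::grey(0.4, 0.4),
                      xlab = "slice", ylab = "richness", axes = FALSE,
                      main = "Per-site richness across slices")
    graphics::axis(2); graphics::axis(1, at = seq_along(run$richness),
                                      labels = names(run$richness))
    graphics::box()
  })
  invisible(paths)
}
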