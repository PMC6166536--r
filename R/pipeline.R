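#' Build and validate a pipeline configuration
#'
#' Assembles the full configuration of an end-to-end run on synthetic data:
#' per-group biofilm structure, growth, expression, and DPD parameters,
#' analysis settings, and the contrasts to test. All fields are validated
#' before any stage runs, and the configuration round-trips through YAML
#' (`yaml_path`) so a run manifest suffices to reproduce a report.
#'
#' @param groups Named list; each entry describes one condition with fields
#'   `height_um` (mean column height), `height_sd_um` (between-column SD),
#'   `gap_frac` (fraction of columns with an internal gap),
#'   `gap_height_um`, `doubling_time_min`, `fold` (true target-gene fold vs
#'   the calibrator), `dpd_ng_ml` (supernatant DPD), `od600`.
#' @param calibrator Group label used as the qPCR fold-1 baseline.
#' @param contrasts List of length-2 character vectors: pairwise group
#'   comparisons to test on every biofilm metric.
#' @param n_stacks Replicate stacks per group.
#' @param nx,ny,nz,voxel Stack geometry (see [make_slab_stack()]).
#' @param noise Named list of noise levels: `imaging_sd` (counts),
#'   `growth_sd` (BCA units), `ct_sd` (cycles), `area_cv` (fraction).
#' @param qpcr_efficiency Amplification factor per cycle.
#' @param standards_ng_ml Calibration standard concentrations.
#' @param molar_mass Analyte molar mass (g/mol) for the uM conversion.
#' @param seed Integer master seed; all stage seeds derive from it.
#' @param out_dir Output directory for CSV tables and the manifest.
#' @param yaml_path Optional path to a YAML file to load the configuration
#'   from instead of the arguments.
#' @return A validated object of class `pipeline_config`.
#' @export
pipeline_config <- function(groups = NULL, calibrator = NULL,
                            contrasts = list(), n_stacks = 3L,
                            nx = 32L, ny = 32L, nz = 40L,
                            voxel = c(0.1, 0.1, 0.5),
                            noise = list(imaging_sd = 8, growth_sd = 0.01,
                                         ct_sd = 0.2, area_cv = 0.02),
                            qpcr_efficiency = 2,
                            standards_ng_ml = c(25, 50, 100, 175, 250),
                            molar_mass = 132.12,
                            seed = 1L, out_dir = tempfile("biofilmetry_run_"),
                            yaml_path = NULL) {
  if (!is.null(yaml_path)) {
    cfg <- yaml::read_yaml(yaml_path)
    cfg$contrasts <- lapply(cfg$contrasts, unlist)
    cfg$voxel <- unlist(cfg$voxel)
    cfg$standards_ng_ml <- unlist(cfg$standards_ng_ml)
    return(do.call(pipeline_config, cfg))
  }
  if (is.null(groups) || is.null(names(groups)))
    stop("`groups` must be a named list of condition descriptions")
  req <- c("height_um", "height_sd_um", "gap_frac", "gap_height_um",
           "doubling_time_min", "fold", "dpd_ng_ml", "od600")
  for (g in names(groups)) {
    miss <- setdiff(req, names(groups[[g]]))
    if (length(miss))
      stop("group '", g, "' is missing field(s): ", paste(miss, collapse = ", "))
  }
  if (is.null(calibrator) || !calibrator %in% names(groups))
    stop("`calibrator` must name one of the groups")
  for (ct in contrasts)
    if (!all(ct %in% names(groups)))
      stop("contrast refers to unknown group(s): ", paste(ct, collapse = " vs "))
  if (!is.numeric(seed) || length(seed) != 1) stop("`seed` must be one integer")
  structure(
    list(groups = groups, calibrator = calibrator, contrasts = contrasts,
         n_stacks = as.integer(n_stacks), nx = as.integer(nx),
         ny = as.integer(ny), nz = as.integer(nz), voxel = voxel,
         noise = noise, qpcr_efficiency = qpcr_efficiency,
         standards_ng_ml = standards_ng_ml, molar_mass = molar_mass,
         seed = as.integer(seed), out_dir = out_dir),
    class = "pipeline_config"
  )
}

#' A ready-made demonstration configuration
#'
#' Four conditions emulating the wild-type host alone and associated with
#' its epibiont, plus a receptor-deletion co-culture: the associated
#' wild-type condition has taller, rougher biofilms, a 4.7-fold target-gene
#' induction, and unchanged DPD; the synthase-deletion condition abolishes
#' DPD production.
#'
#' @param seed Master seed.
#' @param out_dir Output directory.
#' @return A `pipeline_config`.
#' @export
demo_config <- function(seed = 1L, out_dir = tempfile("biofilmetry_demo_")) {
  grp <- function(h, hsd, gap, fold, dpd)
    list(height_um = h, height_sd_um = hsd, gap_frac = gap,
         gap_height_um = 1, doubling_time_min = 60, fold = fold,
         dpd_ng_ml = dpd, od600 = 1)
  pipeline_config(
    groups = list(
      host_mono = grp(19.3, 2.5, 0.1, 1, 145),
      host_epibiont = grp(31.8, 3.5, 0.1, 4.7, 145),
      receptor_mut_epibiont = grp(22.0, 2.5, 0.1, 1, 145),
      synthase_mut_epibiont = grp(20.3, 2.5, 0.1, 1, 0)
    ),
    calibrator = "host_mono",
    contrasts = list(c("host_mono", "host_epibiont"),
                     c("host_epibiont", "receptor_mut_epibiont"),
                     c("host_epibiont", "synthase_mut_epibiont")),
    nz = 90L,
    seed = seed, out_dir = out_dir
  )
}

# deterministic stage seeds derived from the master seed (kept < 2^31)
stage_seed <- function(seed, k) (as.integer(seed) * 101L + k * 7919L) %% 2000000000L

# one synthetic stack for a group: heights ~ N(mean, sd) quantized, a
# random subset of columns carrying one internal gap just above the base
simulate_group_stack <- function(gspec, cfg, seed) {
  set.seed(seed)
  hm <- matrix(stats::rnorm(cfg$ny * cfg$nx, gspec$height_um,
                            gspec$height_sd_um), cfg$ny, cfg$nx)
  dz <- cfg$voxel[3]
  hm <- pmin(pmax(hm, 2 * dz + gspec$gap_height_um + dz), cfg$nz * dz)
  gaps <- list()
  if (gspec$gap_frac > 0) {
    cols <- matrix(stats::runif(cfg$ny * cfg$nx) < gspec$gap_frac,
                   cfg$ny, cfg$nx)
    if (any(cols))
      gaps <- list(list(columns = cols, from_um = dz,
                        to_um = dz + gspec$gap_height_um))
  }
  make_structured_stack(hm, gaps = gaps, nz = cfg$nz, voxel = cfg$voxel,
                        noise_sd = cfg$noise$imaging_sd, seed = seed + 1L)
}

#' Run the end-to-end pipeline on synthetic data
#'
#' Executes all stages in order -- biofilm simulation and morphometrics,
#' growth-curve generation and generation-time estimation, qPCR fold
#' quantification, GC-MS calibration and DPD quantification, and the
#' pairwise and ANOVA statistics on the biofilm metrics -- writing one CSV
#' per stage plus a JSON run manifest (seed, configuration, file digests)
#' into `config$out_dir`. Deterministic given the config's seed.
#'
#' @param config A [pipeline_config].
#' @return Invisibly, a list of the stage tables
#'   (`biofilm`, `growth`, `expression`, `dpd`, `stats`, `manifest`).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  cfg <- config
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  gnames <- names(cfg$groups)

  ## stage 1: biofilm morphometrics
  biofilm <- do.call(rbind, lapply(seq_along(gnames), function(i) {
    g <- gnames[i]
    do.call(rbind, lapply(seq_len(cfg$n_stacks), function(r) {
      sim <- simulate_group_stack(cfg$groups[[g]], cfg,
                                  stage_seed(cfg$seed, i * 100L + r))
      cbind(data.frame(group = g, replicate = r),
            as.data.frame(compute_metrics(sim$stack)))
    }))
  }))
  message("biofilm stage: ", nrow(biofilm), " stacks quantified")

  ## stage 2: growth kinetics
  growth <- do.call(rbind, lapply(seq_along(gnames), function(i) {
    g <- gnames[i]
    sim <- make_growth_series(
      doubling_time_min = cfg$groups[[g]]$doubling_time_min,
      noise_sd = cfg$noise$growth_sd, seed = stage_seed(cfg$seed, 5000L + i))
    gt <- generation_time(sim$curve)
    data.frame(group = g, generation_time_min = as.numeric(gt),
               max_bca = max_bca(sim$curve))
  }))
  message("growth stage: ", nrow(growth), " curves analysed")

  ## stage 3: relative expression
  folds <- vapply(cfg$groups, function(g) g$fold, 0)
  ctsim <- make_ct_table(folds, efficiency = cfg$qpcr_efficiency,
                         noise_sd = cfg$noise$ct_sd, replicates = 3L,
                         seed = stage_seed(cfg$seed, 6000L))
  expression <- relative_expression(ctsim$table, calibrator = cfg$calibrator,
                                    efficiency = cfg$qpcr_efficiency)
  message("expression stage: ", nrow(ctsim$table), " Ct rows in, ",
          nrow(expression), " groups out")

  ## stage 4: GC-MS quantification
  std <- make_gcms_samples(cfg$standards_ng_ml, noise_cv = cfg$noise$area_cv,
                           seed = stage_seed(cfg$seed, 7000L))
  std_resp <- normalized_response(std$areas$area_245_348,
                                  std$areas$area_249_352)
  cal <- fit_calibration(cfg$standards_ng_ml, std_resp)
  smp <- make_gcms_samples(vapply(cfg$groups, function(g) g$dpd_ng_ml, 0),
                           od600 = vapply(cfg$groups, function(g) g$od600, 0),
                           noise_cv = cfg$noise$area_cv,
                           seed = stage_seed(cfg$seed, 7001L))
  smp_resp <- normalized_response(smp$areas$area_245_348,
                                  smp$areas$area_249_352, smp$areas$od600)
  dpd <- cbind(data.frame(group = gnames),
               quantify_dpd(smp_resp, cal, molar_mass = cfg$molar_mass))
  message("gcms stage: calibration R^2 = ", signif(cal$r_squared, 4),
          "; ", nrow(dpd), " samples quantified")

  ## stage 5: statistics on biofilm metrics
  metrics <- c("max_thickness_um", "biovolume_um3", "compactness",
               "roughness_variance_um2", "continuity_ratio")
  stats_tab <- do.call(rbind, lapply(metrics, function(m) {
    an <- one_way_anova(split(biofilm[[m]], biofilm$group))
    an$metric <- m; an$group_a <- NA; an$group_b <- NA
    pw <- do.call(rbind, lapply(cfg$contrasts, function(ct) {
      tt <- t_test_two_tailed(biofilm[[m]][biofilm$group == ct[1]],
                              biofilm[[m]][biofilm$group == ct[2]])
      data.frame(statistic = tt$statistic, df1 = tt$df, df2 = NA,
                 p_value = tt$p_value, contrast = tt$contrast, metric = m,
                 group_a = ct[1], group_b = ct[2], stringsAsFactors = FALSE)
    }))
    rbind(an[, c("statistic", "df1", "df2", "p_value", "contrast",
                 "metric", "group_a", "group_b")], pw)
  }))
  stats_tab$stars <- significance_stars(stats_tab$p_value)

  ## write outputs + manifest
  paths <- c(biofilm = "biofilm_metrics.csv", growth = "growth.csv",
             expression = "expression.csv", dpd = "dpd.csv",
             stats = "stats.csv")
  tabs <- list(biofilm = biofilm, growth = growth, expression = expression,
               dpd = dpd, stats = stats_tab)
  for (k in names(paths))
    utils::write.csv(tabs[[k]], file.path(cfg$out_dir, paths[k]),
                     row.names = FALSE)
  cfg_path <- file.path(cfg$out_dir, "config.yaml")
  cfg_plain <- unclass(cfg)
  cfg_plain$out_dir <- NULL
  yaml::write_yaml(cfg_plain, cfg_path)
  manifest <- list(
    package_version = as.character(utils::packageVersion("biofilmetry")),
    seed = cfg$seed,
    config_md5 = unname(tools::md5sum(cfg_path)),
    outputs = as.list(file.path(cfg$out_dir, paths))
  )
  jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(c(tabs, list(manifest = manifest)))
}
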