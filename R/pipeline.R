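stage_names <- c("apms", "fish", "rip", "mst",
                 "simulate_apms", "simulate_fish", "simulate_rip",
                 "simulate_mst")

# Known config keys per stage; unknown keys are a configuration error.
stage_schema <- list(
  apms = c("input", "samples", "group", "bait", "intensity_prefix",
           "min_peptides", "min_events", "impute", "shift", "width",
           "s0", "fdr_q", "n_permutations"),
  fish = c("dapi", "cy5", "pixel_size", "bit_depth", "condition",
           "per_cell", "min_cells", "mask_params", "write_masks"),
  rip = c("input_a", "input_b", "baits", "min_fold", "max_fdr", "min_reads",
          "count_rule", "method"),
  mst = c("input", "target_total", "model"),
  simulate_apms = c("n_background", "n_spiked", "effect_log2",
                    "n_reps_per_group", "noise_sd", "dropout"),
  simulate_fish = c("n_cells", "nucleus_radius_um", "cyto_outer_radius_um",
                    "nc_ratio", "noise_sd", "pixel_size", "condition"),
  simulate_rip = c("n_genes_per_type", "dispersion", "n_reps"),
  simulate_mst = c("kd", "noise_frac", "n_replicates")
)

validate_config <- function(stage, params) {
  unknown <- setdiff(names(params), stage_schema[[stage]])
  if (length(unknown))
    stop("configuration error: unknown key(s) for stage '", stage, "': ",
         paste(unknown, collapse = ", "), call. = FALSE)
  params
}

#' Run one pipeline stage end to end
#'
#' Dispatches on the stage name, validates the configuration against the
#' stage's schema before any computation, executes the analysis, writes the
#' declared outputs atomically (temp file + rename) into `out_dir`, and
#' finishes with a JSON run manifest capturing the resolved parameters, the
#' seed and the package version, so a rerun from the manifest reproduces the
#' outputs bit for bit.
#'
#' @param stage one of `"apms"`, `"fish"`, `"rip"`, `"mst"`,
#'   `"simulate_apms"`, `"simulate_fish"`, `"simulate_rip"`,
#'   `"simulate_mst"`.
#' @param config named list of stage parameters, or a path to a YAML file
#'   holding them (a top-level block named after the stage is used if
#'   present).
#' @param out_dir output directory (created if missing).
#' @param seed integer master seed; stage-specific child seeds are derived
#'   from it.
#' @param overrides named list overriding config values (CLI flags take
#'   precedence over the file).
#' @return invisibly, a list with the written `paths` and the `manifest`.
#' @export
run_stage <- function(stage, config = list(), out_dir = ".", seed = 1L,
                      overrides = list()) {
  stage <- match.arg(stage, stage_names)
  if (is.character(config) && length(config) == 1L) {
    cfg <- yaml::read_yaml(config)
    if (!is.null(cfg[[stage]])) cfg <- cfg[[stage]]
  } else cfg <- config
  cfg <- modifyList(as.list(cfg), as.list(overrides))
  cfg <- validate_config(stage, cfg)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  runner <- switch(stage,
    apms = stage_apms, fish = stage_fish, rip = stage_rip, mst = stage_mst,
    simulate_apms = stage_sim_apms, simulate_fish = stage_sim_fish,
    simulate_rip = stage_sim_rip, simulate_mst = stage_sim_mst)
  res <- runner(cfg, out_dir, child_seed(seed, stage))
  manifest <- list(stage = stage, seed = seed,
                   parameters = cfg[order(names(cfg))],
                   outputs = res$paths,
                   package = "altcbc",
                   version = as.character(packageVersion("altcbc")))
  mp <- file.path(out_dir, paste0(stage, "_manifest.json"))
  write_json_atomic(manifest, mp)
  invisible(list(paths = c(res$paths, manifest = mp), manifest = manifest,
                 result = res$result))
}

stage_apms <- function(cfg, out_dir, seed) {
  for (k in c("input", "samples", "group", "bait"))
    if (is.null(cfg[[k]]))
      stop("configuration error: '", k, "' is required", call. = FALSE)
  tab <- read_protein_groups(cfg$input, samples = cfg$samples,
                             group = cfg$group, bait = cfg$bait,
                             intensity_prefix = cfg$intensity_prefix %||%
                               "LFQ intensity ")
  n0 <- nrow(tab$intensities)
  tab <- filter_proteins(tab, cfg$min_peptides %||% 2L, cfg$min_events %||% 3L)
  message(sprintf("apms: %d of %d proteins pass filters", nrow(tab$intensities),
                  n0))
  tab <- log_transform_impute(tab, shift = cfg$shift %||% 1.8,
                              width = cfg$width %||% 0.3, seed = seed,
                              impute = cfg$impute %||% TRUE)
  rec <- permutation_fdr(tab, s0 = cfg$s0 %||% 0.1,
                         fdr_q = cfg$fdr_q %||% 0.05,
                         n_permutations = cfg$n_permutations %||% 250L,
                         seed = seed)
  message(sprintf("apms: %d significant proteins (cutoff %.3g)",
                  sum(rec$significant), attr(rec, "cutoff")))
  vp <- file.path(out_dir, "volcano.tsv")
  write_tsv_atomic(as.data.frame(rec), vp)
  rp <- file.path(out_dir, "apms_run.json")
  write_json_atomic(list(cutoff = attr(rec, "cutoff"),
                         fdr_at_cutoff = attr(rec, "fdr_at_cutoff"),
                         n_significant = sum(rec$significant),
                         params = attr(rec, "params")[
                           c("s0", "fdr_q", "n_permutations", "B")],
                         seed = seed), rp)
  list(paths = c(volcano = vp, report = rp), result = rec)
}

stage_fish <- function(cfg, out_dir, seed) {
  for (k in c("dapi", "cy5", "pixel_size"))
    if (is.null(cfg[[k]]))
      stop("configuration error: '", k, "' is required", call. = FALSE)
  stopifnot(length(cfg$dapi) == length(cfg$cy5))
  imgs <- lapply(seq_along(cfg$dapi), function(i)
    read_cell_images(cfg$dapi[[i]], cfg$cy5[[i]], cfg$pixel_size,
                     cfg$bit_depth %||% 8L,
                     cfg$condition %||% NA_character_))
  summ <- measure_nc_ratio(imgs, per_cell = cfg$per_cell %||% TRUE,
                           min_cells = cfg$min_cells %||% 125L,
                           mask_params = cfg$mask_params %||% list())
  message(sprintf("fish: %d cells, mean N/C ratio %.3f", summ$n_cells,
                  summ$mean))
  cp <- file.path(out_dir, "cells.tsv")
  write_tsv_atomic(summ$cells, cp)
  sp <- file.path(out_dir, "nc_summary.tsv")
  write_tsv_atomic(data.frame(condition = summ$condition,
                              n_cells = summ$n_cells, mean_ratio = summ$mean,
                              sd_ratio = summ$sd), sp)
  paths <- c(cells = cp, summary = sp)
  if (isTRUE(cfg$write_masks)) {
    masks <- image_masks(imgs[[1]], cfg$mask_params %||% list())
    write_mask_tiffs(masks, out_dir)
  }
  list(paths = paths, result = summ)
}

stage_rip <- function(cfg, out_dir, seed) {
  for (k in c("input_a", "input_b"))
    if (is.null(cfg[[k]]))
      stop("configuration error: '", k, "' is required", call. = FALSE)
  baits <- cfg$baits %||% c("NCBP2", "NCBP3")
  classify <- function(path) {
    rec <- read_transcript_table(path)
    n0 <- nrow(rec)
    rec <- exclude_contaminant_classes(rec)
    message(sprintf("rip: %d of %d genes after contaminant-class removal",
                    nrow(rec), n0))
    rec <- differential_test(rec, method = cfg$method %||% "t")
    classify_enriched(rec, min_fold = cfg$min_fold %||% 2,
                      max_fdr = cfg$max_fdr %||% 0.01,
                      min_reads = cfg$min_reads %||% 10,
                      count_rule = cfg$count_rule %||% "min")
  }
  calls_a <- classify(cfg$input_a)
  calls_b <- classify(cfg$input_b)
  bd <- breakdown_and_preference(calls_a, calls_b, baits)
  paths <- c(calls_a = file.path(out_dir, paste0("calls_", baits[1], ".tsv")),
             calls_b = file.path(out_dir, paste0("calls_", baits[2], ".tsv")),
             breakdown = file.path(out_dir, "breakdown.tsv"),
             scatter = file.path(out_dir, "scatter.tsv"))
  write_tsv_atomic(calls_a, paths[["calls_a"]])
  write_tsv_atomic(calls_b, paths[["calls_b"]])
  write_tsv_atomic(bd$breakdown, paths[["breakdown"]])
  write_tsv_atomic(enrichment_scatter(calls_a, calls_b), paths[["scatter"]])
  list(paths = paths, result = bd)
}

stage_mst <- function(cfg, out_dir, seed) {
  if (is.null(cfg$input))
    stop("configuration error: 'input' is required", call. = FALSE)
  df <- read.delim(cfg$input, stringsAsFactors = FALSE)
  need <- c("ligand_total", "fnorm", "replicate")
  if (length(setdiff(need, names(df))))
    stop("configuration error: MST input needs columns ",
         paste(need, collapse = ", "), call. = FALSE)
  fit <- fit_binding_series(df, target_total = cfg$target_total %||% 0.05,
                            model = cfg$model %||% "quadratic")
  message(sprintf("mst: Kd = %.4g +/- %.4g uM (n = %d)", fit$combined$kd,
                  fit$combined$se, fit$combined$n))
  rp <- file.path(out_dir, "kd_fit.json")
  write_json_atomic(list(
    kd = fit$combined$kd, se = fit$combined$se, n = fit$combined$n,
    replicates = lapply(fit$fits, function(f)
      list(kd = f$kd, f_unbound = f$f_unbound, f_bound = f$f_bound,
           converged = f$converged, flagged = f$flagged))), rp)
  curve <- do.call(rbind, lapply(seq_along(fit$fits), function(i) {
    s <- df[df$replicate == unique(df$replicate)[i], ]
    data.frame(replicate = s$replicate, ligand_total = s$ligand_total,
               fnorm = s$fnorm,
               fitted = sort_by_conc(fit$fits[[i]]$fitted, s$ligand_total))
  }))
  cp <- file.path(out_dir, "fitted_curve.tsv")
  write_tsv_atomic(curve, cp)
  list(paths = c(report = rp, curve = cp), result = fit)
}

# fitted values from fit_kd are in ascending-concentration order; map back.
sort_by_conc <- function(fitted_sorted, conc) {
  fitted_sorted[match(conc, sort(conc))]
}

stage_sim_apms <- function(cfg, out_dir, seed) {
  sim <- gen_apms(n_background = cfg$n_background %||% 480L,
                  n_spiked = cfg$n_spiked %||% 20L,
                  effect_log2 = cfg$effect_log2 %||% 4,
                  n_reps_per_group = cfg$n_reps_per_group %||% 3L,
                  noise_sd = cfg$noise_sd %||% 0.3,
                  dropout = cfg$dropout, seed = seed)
  tab <- sim$table
  nr <- sum(tab$group == "bait")
  df <- data.frame(`Protein IDs` = rownames(tab$intensities),
                   Peptides = tab$peptide_count,
                   Reverse = ifelse(tab$reverse, "+", ""),
                   `Potential contaminant` = ifelse(tab$contaminant, "+", ""),
                   check.names = FALSE, stringsAsFactors = FALSE)
  ints <- tab$intensities
  ints[is.na(ints)] <- 0
  colnames(ints) <- paste0("LFQ intensity ", colnames(tab$intensities))
  df <- cbind(df, as.data.frame(ints, check.names = FALSE))
  tp <- file.path(out_dir, "protein_groups.tsv")
  write_tsv_atomic(df, tp)
  gp <- file.path(out_dir, "apms_ground_truth.json")
  write_json_atomic(sim$ground_truth, gp)
  list(paths = c(table = tp, ground_truth = gp), result = sim)
}

stage_sim_fish <- function(cfg, out_dir, seed) {
  sim <- gen_fish_images(n_cells = cfg$n_cells %||% 130L,
                         nucleus_radius_um = cfg$nucleus_radius_um %||% 5,
                         cyto_outer_radius_um = cfg$cyto_outer_radius_um %||% 9,
                         nc_ratio = cfg$nc_ratio %||% 2,
                         noise_sd = cfg$noise_sd %||% 0,
                         pixel_size = cfg$pixel_size %||% 0.5,
                         condition = cfg$condition %||% "sim", seed = seed)
  maxv <- 2^sim$image$bit_depth - 1
  dp <- file.path(out_dir, "dapi.tiff")
  cp <- file.path(out_dir, "cy5.tiff")
  tiff::writeTIFF(sim$image$dapi / maxv, dp)
  tiff::writeTIFF(sim$image$cy5 / maxv, cp)
  gp <- file.path(out_dir, "fish_ground_truth.json")
  gt <- sim$ground_truth
  gt$centers <- NULL  # pixel coordinates omitted from the manifest-size JSON
  write_json_atomic(gt, gp)
  list(paths = c(dapi = dp, cy5 = cp, ground_truth = gp), result = sim)
}

stage_sim_rip <- function(cfg, out_dir, seed) {
  sim <- gen_ripseq(n_genes_per_type = cfg$n_genes_per_type %||% 50L,
                    dispersion = cfg$dispersion %||% 0.2,
                    n_reps = cfg$n_reps %||% 3L, seed = seed)
  baits <- setdiff(names(sim), "ground_truth")
  paths <- c()
  for (b in baits) {
    p <- file.path(out_dir, paste0("ripseq_", b, ".tsv"))
    write_tsv_atomic(sim[[b]], p)
    paths[b] <- p
  }
  gp <- file.path(out_dir, "rip_ground_truth.json")
  write_json_atomic(sim$ground_truth, gp)
  paths["ground_truth"] <- gp
  list(paths = paths, result = sim)
}

stage_sim_mst <- function(cfg, out_dir, seed) {
  sim <- gen_mst(kd = cfg$kd %||% 15.8, noise_frac = cfg$noise_frac %||% 0.01,
                 n_replicates = cfg$n_replicates %||% 3L, seed = seed)
  sp <- file.path(out_dir, "mst_series.tsv")
  write_tsv_atomic(sim$series, sp)
  gp <- file.path(out_dir, "mst_ground_truth.json")
  write_json_atomic(sim$ground_truth, gp)
  list(paths = c(series = sp, ground_truth = gp), result = sim)
}
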