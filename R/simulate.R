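#' Simulate a bait-versus-control AP-MS intensity table
#'
#' Background proteins share their group means (log2-normal intensities
#' around protein-specific baselines); spiked true interactors are shifted by
#' `effect_log2` in the bait group. Missingness is intensity-dependent: the
#' dropout probability follows a logistic curve in log2 intensity,
#' `plogis(qlogis(base_rate) - slope * (x - midpoint))`, so a slope of zero
#' gives a uniform `base_rate` and positive slopes censor low-intensity
#' values preferentially. A handful of decoy (reverse) and contaminant rows
#' and a low-evidence (single-peptide) row are included so the quality
#' filters have work to do.
#'
#' @param n_background,n_spiked numbers of background and spiked proteins.
#' @param effect_log2 bait-group shift of spiked proteins (log2 units,
#'   default 4).
#' @param n_reps_per_group replicates per group (default 3).
#' @param noise_sd replicate noise in log2 units (default 0.3).
#' @param dropout list with `base_rate`, `slope`, `midpoint` (`NULL` =
#'   global mean log2 intensity); default: no dropout.
#' @param baseline_range range of protein baseline log2 intensities.
#' @param seed integer seed.
#' @return list with `table` (an [intensity_table()]) and `ground_truth`
#'   (spiked ids, effect size, all generating parameters and the seed).
#' @export
gen_apms <- function(n_background = 480L, n_spiked = 20L, effect_log2 = 4,
                     n_reps_per_group = 3L, noise_sd = 0.3,
                     dropout = list(base_rate = 0, slope = 0, midpoint = NULL),
                     baseline_range = c(23, 33), seed = 1L) {
  stopifnot(n_reps_per_group >= 2L, n_background >= 0L, n_spiked >= 0L,
            noise_sd >= 0)
  dropout <- modifyList(list(base_rate = 0, slope = 0, midpoint = NULL),
                        dropout %||% list())
  if (dropout$base_rate < 0 || dropout$base_rate >= 1 || dropout$slope < 0)
    stop("invalid dropout parameters", call. = FALSE)
  n <- n_background + n_spiked
  out <- with_seed(seed, {
    baseline <- runif(n, baseline_range[1], baseline_range[2])
    nr <- n_reps_per_group
    X <- matrix(rnorm(n * 2 * nr, mean = baseline, sd = noise_sd),
                nrow = n, ncol = 2 * nr)
    if (n_spiked > 0L)
      X[seq_len(n_spiked) + n_background, seq_len(nr)] <-
        X[seq_len(n_spiked) + n_background, seq_len(nr)] + effect_log2
    if (dropout$base_rate > 0) {
      mid <- dropout$midpoint %||% mean(X)
      pmiss <- plogis(qlogis(dropout$base_rate) - dropout$slope * (X - mid))
      X[matrix(rbinom(length(X), 1L, pmiss) == 1L, nrow(X))] <- NA_real_
    }
    ids <- sprintf("protein_%04d", seq_len(n))
    spiked_ids <- if (n_spiked > 0L) ids[seq_len(n_spiked) + n_background]
                  else character(0)
    peptides <- sample(2:30, n, replace = TRUE)
    # decoy/contaminant/low-evidence rows exercising the filters
    extra_log2 <- matrix(rnorm(3 * 2 * nr, 26, noise_sd), nrow = 3)
    X <- rbind(X, extra_log2)
    ids <- c(ids, "decoy_rev_0001", "contaminant_0001", "one_peptide_0001")
    peptides <- c(peptides, 5L, 12L, 1L)
    reverse <- c(rep(FALSE, n), TRUE, FALSE, FALSE)
    contam <- c(rep(FALSE, n), FALSE, TRUE, FALSE)
    m <- 2^X
    rownames(m) <- ids
    colnames(m) <- c(sprintf("bait_%d", seq_len(nr)),
                     sprintf("control_%d", seq_len(nr)))
    tab <- intensity_table(m, group = rep(c("bait", "control"), each = nr),
                           bait = "bait", peptide_count = peptides,
                           reverse = reverse, contaminant = contam)
    list(table = tab,
         ground_truth = list(
           spiked_ids = spiked_ids, effect_log2 = effect_log2,
           n_background = n_background, n_spiked = n_spiked,
           n_reps_per_group = nr, noise_sd = noise_sd,
           dropout = dropout, baseline_range = baseline_range, seed = seed))
  })
  out
}

#' Simulate a two-channel FISH field of cells
#'
#' Cells are non-overlapping disks on a jittered grid: a nuclear disk
#' (bright in DAPI) surrounded by a cytoplasmic annulus. The Cy5 channel
#' carries a uniform cytoplasmic density and a nuclear density of
#' `nc_ratio` times that; optional additive Gaussian noise is clipped to the
#' bit depth. Nuclear and cytoplasmic pixels are painted from the same disk
#' geometry used for the DAPI channel, so noise-free masks recover the
#' ground-truth regions exactly.
#'
#' @param n_cells number of cells (default 130).
#' @param nucleus_radius_um,cyto_outer_radius_um disk radii in micrometres
#'   (defaults 5 and 9).
#' @param nc_ratio ground-truth nuclear/cytoplasmic Cy5 density ratio.
#' @param noise_sd additive noise standard deviation in raw counts.
#' @param pixel_size pixel edge in micrometres (default 0.5).
#' @param cyto_level cytoplasmic Cy5 intensity (default 40 counts).
#' @param dapi_level nuclear DAPI intensity (default 200 counts).
#' @param bit_depth image bit depth (default 8).
#' @param condition condition label.
#' @param seed integer seed.
#' @return list with `image` (a [cell_image_set()]) and `ground_truth`.
#' @export
gen_fish_images <- function(n_cells = 130L, nucleus_radius_um = 5,
                            cyto_outer_radius_um = 9, nc_ratio = 2,
                            noise_sd = 0, pixel_size = 0.5,
                            cyto_level = 40, dapi_level = 200,
                            bit_depth = 8L, condition = "sim", seed = 1L) {
  stopifnot(cyto_outer_radius_um > nucleus_radius_um, n_cells >= 1L,
            nc_ratio > 0)
  maxv <- 2^bit_depth - 1
  if (nc_ratio * cyto_level > maxv)
    stop("nc_ratio * cyto_level exceeds the dynamic range", call. = FALSE)
  r_out_px <- cyto_outer_radius_um / pixel_size
  r_nuc_px <- nucleus_radius_um / pixel_size
  spacing <- ceiling(2 * r_out_px + 4)
  ncol_grid <- ceiling(sqrt(n_cells))
  nrow_grid <- ceiling(n_cells / ncol_grid)
  nr <- nrow_grid * spacing + spacing
  nc <- ncol_grid * spacing + spacing
  jitter_max <- max(floor((spacing - 2 * r_out_px) / 2) - 1, 0)
  with_seed(seed, {
    dapi <- matrix(0, nr, nc)
    cy5 <- matrix(0, nr, nc)
    centers <- matrix(NA_real_, n_cells, 2)
    k <- 0L
    for (gi in seq_len(nrow_grid)) for (gj in seq_len(ncol_grid)) {
      if (k >= n_cells) break
      k <- k + 1L
      cy <- gi * spacing - spacing / 2 + spacing / 2 +
        if (jitter_max > 0) runif(1, -jitter_max, jitter_max) else 0
      cx <- gj * spacing - spacing / 2 + spacing / 2 +
        if (jitter_max > 0) runif(1, -jitter_max, jitter_max) else 0
      centers[k, ] <- c(cy, cx)
      rows <- pmax(1, floor(cy - r_out_px)):pmin(nr, ceiling(cy + r_out_px))
      cols <- pmax(1, floor(cx - r_out_px)):pmin(nc, ceiling(cx + r_out_px))
      dist2 <- outer((rows - cy)^2, (cols - cx)^2, `+`)
      in_cell <- dist2 <= r_out_px^2
      in_nuc <- dist2 <= r_nuc_px^2
      cy5[rows, cols][in_cell & !in_nuc] <- cyto_level
      cy5[rows, cols][in_nuc] <- nc_ratio * cyto_level
      dapi[rows, cols][in_nuc] <- dapi_level
    }
    if (noise_sd > 0) {
      cy5 <- cy5 + rnorm(length(cy5), 0, noise_sd)
      dapi <- dapi + rnorm(length(dapi), 0, noise_sd)
    }
    clip <- function(m) {
      m[m < 0] <- 0; m[m > maxv] <- maxv; round(m)
    }
    img <- cell_image_set(clip(dapi), clip(cy5), pixel_size, bit_depth,
                          condition)
    list(image = img,
         ground_truth = list(
           n_cells = n_cells, nc_ratio = nc_ratio,
           nucleus_radius_um = nucleus_radius_um,
           cyto_outer_radius_um = cyto_outer_radius_um,
           noise_sd = noise_sd, pixel_size = pixel_size,
           cyto_level = cyto_level, dapi_level = dapi_level,
           centers = centers, seed = seed))
  })
}

#' Simulate per-gene RIP-seq quantification tables for two baits
#'
#' Gene baseline expression is log-normal; each RNA type carries a
#' multiplicative enrichment factor per bait (1 = not bound). Replicate FPKM
#' values add log-normal noise of spread `dispersion`, and read counts are
#' Poisson draws consistent with FPKM (`depth` reads per FPKM unit).
#' Ribosomal and mitochondrial decoy genes are included for the
#' contaminant-class filter.
#'
#' @param types_with_enrichment named list: per RNA type, a named numeric
#'   vector of enrichment factors per bait. The default emulates a design
#'   where snRNA/lincRNA/antisense RNAs are bound by one bait only and
#'   mRNAs by both.
#' @param n_genes_per_type genes per RNA type (default 50).
#' @param dispersion replicate log-normal sdlog (default 0.2).
#' @param n_reps replicates per library (default 3).
#' @param baseline_meanlog,baseline_sdlog log-normal baseline parameters.
#' @param depth expected reads per FPKM unit (default 10).
#' @param n_decoys decoy genes per contaminant class (default 5).
#' @param seed integer seed.
#' @return list with one record `data.frame` per bait (named as in
#'   `types_with_enrichment` factors) and `ground_truth`.
#' @export
gen_ripseq <- function(types_with_enrichment = list(
                         snRNA = c(NCBP2 = 8, NCBP3 = 1),
                         lincRNA = c(NCBP2 = 8, NCBP3 = 1),
                         antisense = c(NCBP2 = 8, NCBP3 = 1),
                         protein_coding = c(NCBP2 = 8, NCBP3 = 8)),
                       n_genes_per_type = 50L, dispersion = 0.2,
                       n_reps = 3L, baseline_meanlog = log(30),
                       baseline_sdlog = 1, depth = 10, n_decoys = 5L,
                       seed = 1L) {
  stopifnot(n_reps >= 3L, dispersion > 0, n_genes_per_type >= 1L)
  baits <- unique(unlist(lapply(types_with_enrichment, names)))
  stopifnot(length(baits) >= 1L)
  with_seed(seed, {
    types <- rep(names(types_with_enrichment), each = n_genes_per_type)
    if (n_decoys > 0L)
      types <- c(types, rep(c("rRNA", "mitochondrial"), each = n_decoys))
    n <- length(types)
    gene_id <- sprintf("gene_%04d", seq_len(n))
    base <- exp(rnorm(n, baseline_meanlog, baseline_sdlog))
    factor_for <- function(type, bait) {
      f <- types_with_enrichment[[type]]
      if (is.null(f) || is.na(f[bait])) 1 else unname(f[bait])
    }
    draw <- function(mu) {
      fpkm <- matrix(mu * exp(rnorm(n * n_reps, 0, dispersion) -
                                dispersion^2 / 2), n, n_reps)
      counts <- matrix(rpois(n * n_reps, fpkm * depth), n, n_reps)
      list(fpkm = fpkm, counts = counts)
    }
    tables <- list()
    for (bait in baits) {
      fac <- vapply(types, factor_for, numeric(1), bait = bait)
      b <- draw(base * fac)
      ctl <- draw(base)
      df <- data.frame(gene_id = gene_id, rna_type = types,
                       stringsAsFactors = FALSE)
      for (i in seq_len(n_reps)) df[[paste0("fpkm_bait_", i)]] <- b$fpkm[, i]
      for (i in seq_len(n_reps)) df[[paste0("fpkm_control_", i)]] <- ctl$fpkm[, i]
      for (i in seq_len(n_reps)) df[[paste0("count_bait_", i)]] <- b$counts[, i]
      for (i in seq_len(n_reps)) df[[paste0("count_control_", i)]] <- ctl$counts[, i]
      tables[[bait]] <- df
    }
    tables$ground_truth <- list(
      types_with_enrichment = types_with_enrichment,
      n_genes_per_type = n_genes_per_type, dispersion = dispersion,
      n_reps = n_reps, depth = depth, n_decoys = n_decoys,
      baseline_meanlog = baseline_meanlog, baseline_sdlog = baseline_sdlog,
      seed = seed)
    tables
  })
}

#' Simulate replicate MST titration series
#'
#' Normalized fluorescence on the standard 16-point post-mixing grid (see
#' [make_dilution_series()]), generated from the 1:1 ligand-depletion
#' isotherm at the given Kd with multiplicative Gaussian noise.
#'
#' @param kd ground-truth dissociation constant (uM, default 15.8).
#' @param noise_frac multiplicative noise fraction (default 0.01).
#' @param n_replicates number of replicate series (default 3).
#' @param f_unbound,f_bound plateau normalized-fluorescence values.
#' @param start,n,target_stock dilution-series parameters (see
#'   [make_dilution_series()]).
#' @param seed integer seed.
#' @return list with `series` (data.frame: `ligand_total`, `target_total`,
#'   `fnorm`, `replicate`) and `ground_truth`.
#' @export
gen_mst <- function(kd = 15.8, noise_frac = 0.01, n_replicates = 3L,
                    f_unbound = 1, f_bound = 0.6, start = 204, n = 16L,
                    target_stock = 0.1, seed = 1L) {
  stopifnot(kd > 0, noise_frac >= 0, n_replicates >= 1L)
  grid <- make_dilution_series(start, n, target_stock)
  with_seed(seed, {
    series <- do.call(rbind, lapply(seq_len(n_replicates), function(r) {
      fb <- fraction_bound(grid$ligand_total, grid$target_total[1], kd)
      y <- f_unbound + (f_bound - f_unbound) * fb
      y <- y * (1 + rnorm(length(y), 0, noise_frac))
      data.frame(ligand_total = grid$ligand_total,
                 target_total = grid$target_total,
                 fnorm = y, replicate = r)
    }))
    list(series = series,
         ground_truth = list(kd = kd, noise_frac = noise_frac,
                             n_replicates = n_replicates,
                             f_unbound = f_unbound, f_bound = f_bound,
                             start = start, n = n,
                             target_stock = target_stock, seed = seed))
  })
}
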