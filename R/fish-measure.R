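#' Construct a calibrated two-channel cell image
#'
#' @param dapi,cy5 numeric matrices of raw intensities, same shape.
#' @param pixel_size pixel edge length in micrometres.
#' @param bit_depth image bit depth (default 8).
#' @param condition condition label for downstream statistics.
#' @return an object of class `cell_image_set`.
#' @export
cell_image_set <- function(dapi, cy5, pixel_size, bit_depth = 8L,
                           condition = NA_character_) {
  stopifnot(is.matrix(dapi), is.matrix(cy5), all(dim(dapi) == dim(cy5)),
            pixel_size > 0)
  maxv <- 2^bit_depth - 1
  if (any(dapi < 0 | dapi > maxv) || any(cy5 < 0 | cy5 > maxv))
    stop("intensities outside [0, 2^bit_depth - 1]", call. = FALSE)
  structure(list(dapi = dapi, cy5 = cy5, pixel_size = pixel_size,
                 bit_depth = as.integer(bit_depth),
                 condition = as.character(condition)),
            class = "cell_image_set")
}

#' Read a two-channel image from TIFF files
#'
#' `tiff::readTIFF()` returns intensities scaled to `[0, 1]`; they are
#' rescaled back to raw counts using `bit_depth`.
#'
#' @param dapi_path,cy5_path paths to single-channel TIFFs.
#' @param pixel_size pixel edge length in micrometres.
#' @param bit_depth bit depth of the stored data (default 8).
#' @param condition condition label.
#' @return a [cell_image_set()].
#' @export
read_cell_images <- function(dapi_path, cy5_path, pixel_size, bit_depth = 8L,
                             condition = NA_character_) {
  rd <- function(p) {
    m <- tiff::readTIFF(p)
    if (length(dim(m)) == 3L) m <- m[, , 1L]
    round(m * (2^bit_depth - 1))
  }
  cell_image_set(rd(dapi_path), rd(cy5_path), pixel_size, bit_depth, condition)
}

#' Write mask rasters to TIFF for audit
#'
#' @param masks a `mask_set` from [combine_masks()].
#' @param dir output directory.
#' @param prefix file-name prefix.
#' @return invisibly, the written paths.
#' @export
write_mask_tiffs <- function(masks, dir, prefix = "mask") {
  stopifnot(inherits(masks, "mask_set"))
  paths <- character(0)
  for (nm in names(masks)) {
    p <- file.path(dir, paste0(prefix, "_", nm, ".tiff"))
    tiff::writeTIFF(masks[[nm]] * 1, p)
    paths <- c(paths, p)
  }
  invisible(paths)
}

# Compute the four masks for one image with the given parameters.
image_masks <- function(img, mask_params = list()) {
  p <- modifyList(list(threshold_low_pct = 13, threshold_high_pct = 100,
                       nucleus_min_area = 50, fill = TRUE,
                       intensity_low = 6, intensity_high = 255,
                       total_min_area = 100,
                       threshold_mode = "range"), mask_params)
  nuc <- mask_nuclei(img$dapi, img$pixel_size, p$threshold_low_pct,
                     p$threshold_high_pct, p$nucleus_min_area, p$fill,
                     img$bit_depth, p$threshold_mode)
  tot <- mask_total(img$cy5, img$pixel_size, p$intensity_low,
                    p$intensity_high, p$total_min_area)
  combine_masks(nuc, tot)
}

# Per-cell Cy5 measurements for one image: each stained-nucleus component is
# paired with the cytoplasm pixels of its containing whole-cell component.
measure_cells_one <- function(img, masks) {
  px_area <- img$pixel_size^2
  cell_lab <- label_components(masks$total)
  nuc_lab <- label_components(masks$cy5_nuclei)
  n_nuc <- max(nuc_lab)
  rows <- vector("list", n_nuc)
  for (k in seq_len(n_nuc)) {
    nuc_px <- nuc_lab == k
    host <- cell_lab[nuc_px]
    host <- host[host > 0L]
    host_id <- if (length(host)) as.integer(names(which.max(table(host))))
               else NA_integer_
    cyto_px <- if (is.na(host_id)) matrix(FALSE, nrow(nuc_lab), ncol(nuc_lab))
               else masks$cytoplasm & cell_lab == host_id
    nuc_area <- sum(nuc_px) * px_area
    cyto_area <- sum(cyto_px) * px_area
    nuc_int <- sum(img$cy5[nuc_px])
    cyto_int <- sum(img$cy5[cyto_px])
    rows[[k]] <- data.frame(
      cell_id = k, condition = img$condition,
      nuclear_area_um2 = nuc_area, nuclear_intensity = nuc_int,
      cytoplasmic_area_um2 = cyto_area, cytoplasmic_intensity = cyto_int)
  }
  do.call(rbind, rows)
}

#' Measure the nuclear/cytoplasmic poly(A) signal ratio
#'
#' For each image, Cy5 intensity and area are summed within the cytoplasm and
#' stained-nuclei masks; densities are intensity per square micrometre and
#' the ratio is nuclear density over cytoplasmic density. With
#' `per_cell = TRUE` (default) the ratio is computed for every cell (a
#' stained-nucleus component paired with the cytoplasm of its whole-cell
#' component); otherwise one ratio per image. Cells with zero cytoplasmic
#' area or intensity are dropped with a message. Fewer than `min_cells`
#' ratios triggers a warning (or an error, configurable).
#'
#' @param images a [cell_image_set()] or list of them (one condition).
#' @param per_cell per-cell (default) or per-image ratios.
#' @param min_cells minimum number of cells expected (default 125).
#' @param on_undercount `"warn"` (default) or `"error"`.
#' @param mask_params named list overriding mask parameters (see
#'   [mask_nuclei()], [mask_total()]).
#' @return an object of class `nc_ratio_summary`: list with `ratios`,
#'   `cells` (per-cell table), `n_cells`, `mean`, `sd`, `condition`.
#' @export
measure_nc_ratio <- function(images, per_cell = TRUE, min_cells = 125L,
                             on_undercount = c("warn", "error"),
                             mask_params = list()) {
  on_undercount <- match.arg(on_undercount)
  if (inherits(images, "cell_image_set")) images <- list(images)
  cells <- list(); dropped <- 0L
  for (i in seq_along(images)) {
    img <- images[[i]]
    masks <- image_masks(img, mask_params)
    if (per_cell) {
      tab <- measure_cells_one(img, masks)
    } else {
      px_area <- img$pixel_size^2
      tab <- data.frame(
        cell_id = 1L, condition = img$condition,
        nuclear_area_um2 = sum(masks$cy5_nuclei) * px_area,
        nuclear_intensity = sum(img$cy5[masks$cy5_nuclei]),
        cytoplasmic_area_um2 = sum(masks$cytoplasm) * px_area,
        cytoplasmic_intensity = sum(img$cy5[masks$cytoplasm]))
    }
    if (is.null(tab)) next
    tab$image <- i
    ok <- tab$cytoplasmic_area_um2 > 0 & tab$cytoplasmic_intensity > 0 &
      tab$nuclear_area_um2 > 0
    dropped <- dropped + sum(!ok)
    cells[[i]] <- tab[ok, , drop = FALSE]
  }
  cells <- do.call(rbind, cells)
  if (dropped > 0L)
    message(dropped, " cell(s) dropped (zero cytoplasmic area or intensity)")
  if (is.null(cells) || nrow(cells) == 0L)
    stop("no measurable cells", call. = FALSE)
  cells$nuclear_density <- cells$nuclear_intensity / cells$nuclear_area_um2
  cells$cytoplasmic_density <-
    cells$cytoplasmic_intensity / cells$cytoplasmic_area_um2
  cells$ratio <- cells$nuclear_density / cells$cytoplasmic_density
  if (nrow(cells) < min_cells) {
    msg <- sprintf("only %d cells measured (minimum expected: %d)",
                   nrow(cells), min_cells)
    if (on_undercount == "error") stop(msg, call. = FALSE) else warning(msg)
  }
  structure(list(ratios = cells$ratio, cells = cells,
                 n_cells = nrow(cells),
                 mean = mean(cells$ratio), sd = sd(cells$ratio),
                 condition = images[[1]]$condition),
            class = "nc_ratio_summary")
}

#' @export
print.nc_ratio_summary <- function(x, ...) {
  cat(sprintf("N/C ratio (%s): %.3f +/- %.3f sd, n = %d cells\n",
              x$condition, x$mean, x$sd, x$n_cells))
  invisible(x)
}

#' One-way ANOVA with Tukey's post-test on per-condition N/C ratios
#'
#' Fixed-effects one-way analysis of variance across conditions followed by
#' Tukey's honest significant difference test (studentized-range
#' distribution) for all pairwise comparisons. Degenerate input in which all
#' values are identical yields `F = 0`, `p = 1` and no significant pairs.
#'
#' @param ratios either a named list of numeric vectors (one per condition),
#'   a data.frame with columns `ratio` and `condition`, or a list of
#'   `nc_ratio_summary` objects.
#' @return a list of class `anova_tukey`: `F`, `p`, `df_between`,
#'   `df_within`, and `tukey` (data.frame: pair, diff, lwr, upr, p_adj).
#' @export
anova_tukey <- function(ratios) {
  if (is.data.frame(ratios)) {
    df <- data.frame(ratio = ratios$ratio,
                     condition = as.character(ratios$condition))
  } else if (is.list(ratios) && all(vapply(ratios, inherits, TRUE,
                                           "nc_ratio_summary"))) {
    df <- do.call(rbind, lapply(ratios, function(s)
      data.frame(ratio = s$ratios, condition = s$condition)))
  } else if (is.list(ratios)) {
    if (is.null(names(ratios))) stop("condition list must be named",
                                     call. = FALSE)
    df <- do.call(rbind, lapply(names(ratios), function(nm)
      data.frame(ratio = ratios[[nm]], condition = nm)))
  } else stop("unsupported input", call. = FALSE)
  counts <- table(df$condition)
  if (length(counts) < 2L) stop("need at least 2 conditions", call. = FALSE)
  if (any(counts < 2L))
    stop("condition(s) with fewer than 2 cells: ",
         paste(names(counts)[counts < 2L], collapse = ", "), call. = FALSE)
  df$condition <- factor(df$condition)
  k <- nlevels(df$condition); n <- nrow(df)
  if (var(df$ratio) == 0) {
    pairs <- combn(levels(df$condition), 2,
                   function(p) paste(p[2], p[1], sep = "-"))
    tk <- data.frame(pair = pairs, diff = 0, lwr = 0, upr = 0, p_adj = 1,
                     stringsAsFactors = FALSE)
    return(structure(list(F = 0, p = 1, df_between = k - 1, df_within = n - k,
                          tukey = tk), class = "anova_tukey"))
  }
  fit <- aov(ratio ~ condition, data = df)
  an <- anova(fit)
  tk <- TukeyHSD(fit)$condition
  tukey <- data.frame(pair = rownames(tk), diff = tk[, "diff"],
                      lwr = tk[, "lwr"], upr = tk[, "upr"],
                      p_adj = tk[, "p adj"], row.names = NULL,
                      stringsAsFactors = FALSE)
  structure(list(F = an[["F value"]][1], p = an[["Pr(>F)"]][1],
                 df_between = an[["Df"]][1], df_within = an[["Df"]][2],
                 tukey = tukey), class = "anova_tukey")
}

#' @export
print.anova_tukey <- function(x, ...) {
  cat(sprintf("One-way ANOVA: F(%d, %d) = %.3f, p = %.3g\n",
              x$df_between, x$df_within, x$F, x$p))
  print(x$tukey, digits = 4)
  invisible(x)
}
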