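#' Label connected components of a binary raster
#'
#' Vectorised label propagation: every foreground pixel starts with a unique
#' label and repeatedly takes the minimum label over its neighbourhood until
#' a fixed point is reached, then labels are renumbered 1..k in raster order.
#' Foreground connectivity is 8-connected by default (diagonal contact joins
#' objects), matching common 2-D segmentation practice.
#'
#' @param mask logical (or 0/1) matrix.
#' @param connectivity 8 (default) or 4.
#' @return an integer matrix; 0 is background, components are numbered 1..k.
#' @export
label_components <- function(mask, connectivity = 8L) {
  stopifnot(is.matrix(mask), connectivity %in% c(4L, 8L))
  mask <- mask != 0
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(seq_len(nr * nc), nr, nc)
  lab[!mask] <- 0L
  shifts <- list(c(1, 0), c(-1, 0), c(0, 1), c(0, -1))
  if (connectivity == 8L)
    shifts <- c(shifts, list(c(1, 1), c(1, -1), c(-1, 1), c(-1, -1)))
  repeat {
    new <- lab
    for (s in shifts) {
      shifted <- shift_matrix(lab, s[1], s[2])
      upd <- mask & shifted > 0L & (new == 0L | shifted < new)
      new[upd] <- shifted[upd]
    }
    if (identical(new, lab)) break
    lab <- new
  }
  vals <- sort(unique(lab[lab > 0L]))
  lab[] <- match(lab, c(0L, vals), nomatch = 1L) - 1L
  lab
}

# Shift a matrix by (dr, dc), padding with 0.
shift_matrix <- function(m, dr, dc) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(0L, nr, nc)
  rs <- seq_len(nr) - dr; cs <- seq_len(nc) - dc
  rok <- rs >= 1 & rs <= nr; cok <- cs >= 1 & cs <= nc
  out[rok, cok] <- m[rs[rok], cs[cok]]
  out
}

#' Fill interior holes of a binary mask
#'
#' Background components that do not touch the image border are interior
#' holes and are set to foreground. With 8-connected foreground the
#' complement is labelled 4-connected (the standard dual pairing, so a
#' one-pixel diagonal "crack" does not leak a hole to the border).
#'
#' @param mask logical matrix.
#' @param connectivity foreground connectivity (8 or 4).
#' @return the logical mask with holes filled.
#' @export
fill_holes <- function(mask, connectivity = 8L) {
  mask <- mask != 0
  bg_conn <- if (connectivity == 8L) 4L else 8L
  bg <- label_components(!mask, bg_conn)
  border <- unique(c(bg[1, ], bg[nrow(bg), ], bg[, 1], bg[, ncol(bg)]))
  border <- border[border > 0L]
  mask | (bg > 0L & !(bg %in% border))
}

# Drop components smaller than min_pixels.
remove_small <- function(mask, min_pixels, connectivity = 8L) {
  if (min_pixels <= 1) return(mask != 0)
  lab <- label_components(mask, connectivity)
  if (max(lab) == 0L) return(mask != 0)
  sizes <- tabulate(lab[lab > 0L])
  keep <- which(sizes >= min_pixels)
  matrix(lab %in% keep, nrow(mask), ncol(mask))
}

#' Mask nuclei from the DAPI channel
#'
#' Pixels whose intensity lies within `[threshold_low_pct, threshold_high_pct]`
#' percent of the channel's full dynamic range (e.g. 13% of 255 for 8-bit
#' data) become foreground; components smaller than `min_area` are removed
#' and interior holes of the survivors are filled. Both threshold bounds are
#' inclusive. `threshold_mode = "percentile"` switches to percentiles of the
#' observed intensities instead of the fixed dynamic range.
#'
#' @param dapi numeric matrix of raw DAPI intensities.
#' @param pixel_size pixel edge length in micrometres.
#' @param threshold_low_pct,threshold_high_pct threshold range in percent
#'   (defaults 13 and 100).
#' @param min_area minimum object area in square micrometres (default 50).
#' @param fill logical: fill holes in surviving objects (default `TRUE`).
#' @param bit_depth bit depth defining the dynamic range (default 8).
#' @param threshold_mode `"range"` (percent of full dynamic range, default)
#'   or `"percentile"` (percentile of observed intensities).
#' @return a logical nucleus mask.
#' @export
mask_nuclei <- function(dapi, pixel_size, threshold_low_pct = 13,
                        threshold_high_pct = 100, min_area = 50,
                        fill = TRUE, bit_depth = 8L,
                        threshold_mode = c("range", "percentile")) {
  stopifnot(is.matrix(dapi), pixel_size > 0,
            threshold_low_pct >= 0, threshold_high_pct <= 100,
            threshold_low_pct <= threshold_high_pct)
  threshold_mode <- match.arg(threshold_mode)
  if (threshold_mode == "range") {
    full <- 2^bit_depth - 1
    lo <- threshold_low_pct / 100 * full
    hi <- threshold_high_pct / 100 * full
  } else {
    lo <- quantile(dapi, threshold_low_pct / 100, names = FALSE)
    hi <- quantile(dapi, threshold_high_pct / 100, names = FALSE)
  }
  m <- dapi >= lo & dapi <= hi
  min_pixels <- min_area / pixel_size^2
  if (min_pixels < 1)
    warning("min_area is smaller than one pixel; size filter has no effect")
  m <- remove_small(m, min_pixels)
  if (fill) m <- fill_holes(m)
  m
}

#' Mask whole cells (cytoplasm including nuclei) from the Cy5 channel
#'
#' Absolute intensity thresholding with inclusive bounds (defaults 6-255),
#' followed by a minimum-object-size filter; no hole filling.
#'
#' @param cy5 numeric matrix of raw Cy5 intensities.
#' @param pixel_size pixel edge length in micrometres.
#' @param intensity_low,intensity_high inclusive absolute thresholds
#'   (defaults 6 and 255).
#' @param min_area minimum object area in square micrometres (default 100).
#' @return a logical whole-cell mask.
#' @export
mask_total <- function(cy5, pixel_size, intensity_low = 6,
                       intensity_high = 255, min_area = 100) {
  stopifnot(is.matrix(cy5), pixel_size > 0, intensity_low <= intensity_high)
  m <- cy5 >= intensity_low & cy5 <= intensity_high
  remove_small(m, min_area / pixel_size^2)
}

#' Combine nucleus and whole-cell masks into the four measurement regions
#'
#' The cytoplasm mask is the exclusive combination (symmetric difference) of
#' the nucleus and whole-cell masks; the stained-nuclei mask is the
#' whole-cell mask minus the cytoplasm mask. When every nucleus lies inside
#' the whole-cell mask this reduces to plain subtraction, and the two derived
#' masks partition the whole-cell mask.
#'
#' @param nuclei logical nucleus mask (mask 1).
#' @param total logical whole-cell mask (mask 2).
#' @return an object of class `mask_set`: list with logical rasters
#'   `nuclei`, `total`, `cytoplasm` (mask 3), `cy5_nuclei` (mask 4).
#' @export
combine_masks <- function(nuclei, total) {
  stopifnot(is.matrix(nuclei), is.matrix(total),
            all(dim(nuclei) == dim(total)))
  nuclei <- nuclei != 0; total <- total != 0
  if (!any(total)) stop("empty whole-cell mask: no cell signal", call. = FALSE)
  cytoplasm <- xor(nuclei, total)
  cy5_nuclei <- total & !cytoplasm
  structure(list(nuclei = nuclei, total = total,
                 cytoplasm = cytoplasm, cy5_nuclei = cy5_nuclei),
            class = "mask_set")
}

#' @export
print.mask_set <- function(x, ...) {
  a <- vapply(x, sum, numeric(1))
  cat("mask_set (pixels): ",
      paste(names(a), a, sep = "=", collapse = ", "), "\n")
  invisible(x)
}
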