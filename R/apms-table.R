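#' Construct a protein-by-sample label-free intensity table
#'
#' The container for AP-MS quantification: one row per protein group, one
#' column per sample, with missing quantifications as `NA`. Intensities must
#' be strictly positive where present (they are raw, not yet log-transformed).
#'
#' @param intensities numeric matrix (proteins x samples) with `NA` for
#'   missing values; rownames are protein ids, colnames sample names.
#' @param group character/factor of length `ncol(intensities)` assigning each
#'   sample to exactly one of two groups.
#' @param bait label of the bait group; the other level is the control.
#' @param peptide_count non-negative integer per protein.
#' @param reverse,contaminant logical flags per protein (decoy hits and known
#'   contaminants, respectively).
#' @param log2_transformed internal marker; user tables start on the raw scale.
#' @return an object of class `intensity_table`.
#' @seealso [read_protein_groups()], [filter_proteins()],
#'   [log_transform_impute()]
#' @export
intensity_table <- function(intensities, group, bait,
                            peptide_count = rep(2L, nrow(intensities)),
                            reverse = rep(FALSE, nrow(intensities)),
                            contaminant = rep(FALSE, nrow(intensities)),
                            log2_transformed = FALSE) {
  intensities <- as.matrix(intensities)
  storage.mode(intensities) <- "double"
  group <- as.character(group)
  if (length(group) != ncol(intensities))
    stop("'group' must assign every sample to a group", call. = FALSE)
  lv <- unique(group)
  if (length(lv) != 2L)
    stop("exactly two groups are required, got: ", paste(lv, collapse = ", "),
         call. = FALSE)
  if (!bait %in% lv) stop("bait group '", bait, "' not found", call. = FALSE)
  if (any(table(group) < 1L)) stop("a group has zero samples", call. = FALSE)
  if (!log2_transformed && any(intensities <= 0, na.rm = TRUE))
    stop("intensities must be strictly positive where present", call. = FALSE)
  if (length(peptide_count) != nrow(intensities) ||
      any(peptide_count < 0, na.rm = TRUE))
    stop("'peptide_count' must be a non-negative integer per protein",
         call. = FALSE)
  if (is.null(rownames(intensities)))
    rownames(intensities) <- sprintf("protein_%04d", seq_len(nrow(intensities)))
  if (is.null(colnames(intensities)))
    colnames(intensities) <- make.unique(paste0(group, "_", seq_along(group)))
  structure(list(
    intensities = intensities,
    group = group,
    bait = bait,
    control = setdiff(lv, bait),
    peptide_count = as.integer(peptide_count),
    reverse = as.logical(reverse),
    contaminant = as.logical(contaminant),
    log2_transformed = isTRUE(log2_transformed)
  ), class = "intensity_table")
}

#' @export
print.intensity_table <- function(x, ...) {
  cat(sprintf("intensity_table: %d proteins x %d samples (%s: %d, %s: %d)%s\n",
              nrow(x$intensities), ncol(x$intensities),
              x$bait, sum(x$group == x$bait),
              x$control, sum(x$group == x$control),
              if (x$log2_transformed) ", log2 scale" else ""))
  cat(sprintf("  missing values: %d (%.1f%%)\n", sum(is.na(x$intensities)),
              100 * mean(is.na(x$intensities))))
  invisible(x)
}

#' @export
dim.intensity_table <- function(x) dim(x$intensities)

#' Read a MaxQuant-style protein-groups table
#'
#' Parses the tab-separated proteinGroups dialect: per-sample intensity
#' columns found by prefix, a peptide-count column, and the `"+"` convention
#' for the reverse/contaminant flag columns.
#'
#' @param path path to the tab-separated table.
#' @param samples character vector of sample names; column
#'   `paste0(intensity_prefix, sample)` must exist for each.
#' @param group group label per sample (two levels).
#' @param bait label of the bait group.
#' @param intensity_prefix prefix of the intensity columns
#'   (default `"LFQ intensity "`).
#' @param id_col,peptides_col,reverse_col,contaminant_col column names of the
#'   protein id, peptide count, and flag columns.
#' @return an [intensity_table()]. Zero intensities are treated as missing, as
#'   is conventional for label-free output.
#' @export
read_protein_groups <- function(path, samples, group, bait,
                                intensity_prefix = "LFQ intensity ",
                                id_col = "Protein IDs",
                                peptides_col = "Peptides",
                                reverse_col = "Reverse",
                                contaminant_col = "Potential contaminant") {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  cols <- paste0(intensity_prefix, samples)
  missing_cols <- setdiff(c(id_col, peptides_col, cols), names(df))
  if (length(missing_cols))
    stop("malformed table, missing columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  m <- as.matrix(df[, cols, drop = FALSE])
  storage.mode(m) <- "double"
  m[m <= 0] <- NA_real_
  colnames(m) <- samples
  rownames(m) <- make.unique(as.character(df[[id_col]]))
  flag <- function(col) {
    if (col %in% names(df)) trimws(as.character(df[[col]])) == "+"
    else rep(FALSE, nrow(df))
  }
  intensity_table(m, group = group, bait = bait,
                  peptide_count = df[[peptides_col]],
                  reverse = flag(reverse_col),
                  contaminant = flag(contaminant_col))
}

#' Filter proteins by identification quality and quantification coverage
#'
#' Keeps proteins identified by at least `min_peptides` peptides that carry at
#' least `min_events` non-missing quantifications within at least one of the
#' two experimental groups; reverse (decoy) and contaminant entries are
#' removed unconditionally.
#'
#' @param table an [intensity_table()].
#' @param min_peptides minimum peptide count (default 2).
#' @param min_events minimum quantification events in at least one group
#'   (default 3).
#' @return the filtered [intensity_table()].
#' @export
filter_proteins <- function(table, min_peptides = 2L, min_events = 3L) {
  stopifnot(inherits(table, "intensity_table"),
            min_peptides >= 0, min_events >= 1)
  obs <- !is.na(table$intensities)
  in_bait <- table$group == table$bait
  events_bait <- rowSums(obs[, in_bait, drop = FALSE])
  events_ctrl <- rowSums(obs[, !in_bait, drop = FALSE])
  keep <- table$peptide_count >= min_peptides &
    pmax(events_bait, events_ctrl) >= min_events &
    !table$reverse & !table$contaminant
  subset_table(table, keep)
}

subset_table <- function(table, keep) {
  out <- table
  out$intensities <- table$intensities[keep, , drop = FALSE]
  out$peptide_count <- table$peptide_count[keep]
  out$reverse <- table$reverse[keep]
  out$contaminant <- table$contaminant[keep]
  out
}

#' Log-transform intensities and optionally impute missing values
#'
#' Observed intensities are replaced by their base-2 logarithm. If
#' `impute = TRUE`, each missing cell is drawn independently from a normal
#' distribution centred `shift` standard deviations below the per-sample mean
#' of the observed log2 intensities, with standard deviation `width` times the
#' per-sample standard deviation — the conventional downshifted-Gaussian model
#' for left-censored label-free missingness. With `impute = FALSE` missing
#' cells stay missing and downstream tests use observed values only.
#'
#' @param table an [intensity_table()] on the raw scale.
#' @param shift downshift in units of per-sample standard deviations
#'   (default 1.8).
#' @param width imputation spread as a fraction of the per-sample standard
#'   deviation (default 0.3); must be positive.
#' @param seed integer seed for the imputation draws.
#' @param impute draw values for missing cells? (default `TRUE`)
#' @return an [intensity_table()] on the log2 scale.
#' @export
log_transform_impute <- function(table, shift = 1.8, width = 0.3,
                                 seed = NULL, impute = TRUE) {
  stopifnot(inherits(table, "intensity_table"), width > 0, shift >= 0)
  if (table$log2_transformed) stop("table is already log2-transformed",
                                   call. = FALSE)
  m <- log2(table$intensities)
  if (impute && anyNA(m)) {
    n_obs <- colSums(!is.na(m))
    if (any(n_obs < 2L))
      stop("cannot impute: sample(s) with fewer than 2 observed values: ",
           paste(colnames(m)[n_obs < 2L], collapse = ", "), call. = FALSE)
    m <- with_seed(seed, {
      for (j in seq_len(ncol(m))) {
        miss <- is.na(m[, j])
        if (any(miss)) {
          mu <- mean(m[, j], na.rm = TRUE)
          s <- sd(m[, j], na.rm = TRUE)
          m[miss, j] <- rnorm(sum(miss), mean = mu - shift * s,
                              sd = width * s)
        }
      }
      m
    })
  }
  out <- table
  out$intensities <- m
  out$log2_transformed <- TRUE
  out
}
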