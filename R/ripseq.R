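#' Read a per-gene transcript quantification table
#'
#' Tab-separated table with columns `gene_id`, `rna_type`, and per-replicate
#' FPKM and read-count columns named `fpkm_bait_<i>`, `fpkm_control_<i>`,
#' `count_bait_<i>`, `count_control_<i>`.
#'
#' @param path path to the TSV.
#' @return a `data.frame` of transcript records.
#' @export
read_transcript_table <- function(path) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  need <- c("gene_id", "rna_type")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("malformed table, missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (!length(rip_cols(df, "fpkm_bait")) || !length(rip_cols(df, "fpkm_control")))
    stop("malformed table: no fpkm_bait_*/fpkm_control_* columns",
         call. = FALSE)
  df
}

rip_cols <- function(records, prefix) {
  grep(paste0("^", prefix, "_[0-9]+$"), names(records), value = TRUE)
}

#' Remove contaminant RNA classes
#'
#' Drops records whose RNA type is ribosomal or mitochondrial, the classes
#' dominated by carry-over rather than specific binding.
#'
#' @param records transcript records (`data.frame` with `rna_type`).
#' @param classes RNA types to drop (default `c("rRNA", "mitochondrial")`).
#' @return the filtered records.
#' @export
exclude_contaminant_classes <- function(records,
                                        classes = c("rRNA", "mitochondrial")) {
  stopifnot("rna_type" %in% names(records))
  records[!(records$rna_type %in% classes), , drop = FALSE]
}

#' Pseudocount fold enrichment
#'
#' `(fpkm_bait_mean + 2) / (fpkm_control_mean + 2)`; the pseudocount of 2
#' FPKM stabilises ratios of lowly expressed genes and makes the score
#' defined when the control signal is zero (bait = control = 0 gives exactly
#' 1).
#'
#' @param fpkm_bait_mean,fpkm_control_mean non-negative per-gene mean FPKM
#'   across replicates (vectorised).
#' @param pseudocount the pseudocount (default 2).
#' @return the fold-enrichment score(s).
#' @export
fold_enrichment <- function(fpkm_bait_mean, fpkm_control_mean,
                            pseudocount = 2) {
  stopifnot(all(fpkm_bait_mean >= 0), all(fpkm_control_mean >= 0))
  (fpkm_bait_mean + pseudocount) / (fpkm_control_mean + pseudocount)
}

#' Per-gene differential test between bait and control replicates
#'
#' A two-sided equal-variance t-test on `log2(FPKM + pseudocount)` across
#' replicates, with Benjamini-Hochberg FDR correction over all tested genes.
#' This is an explicit, pluggable substitute for the external isoform-aware
#' caller used upstream of tables like these; a permutation alternative
#' (exact enumeration of replicate relabelings, available from 4 replicates
#' per side) can be selected with `method = "permutation"`.
#'
#' @param records transcript records with `fpkm_bait_*` and `fpkm_control_*`
#'   columns (at least 2 replicates per side).
#' @param method `"t"` (default) or `"permutation"`.
#' @param pseudocount pseudocount for the log transform (default 2).
#' @return `records` with columns `p` and `fdr` appended.
#' @export
differential_test <- function(records, method = c("t", "permutation"),
                              pseudocount = 2) {
  method <- match.arg(method)
  bcols <- rip_cols(records, "fpkm_bait")
  ccols <- rip_cols(records, "fpkm_control")
  if (length(bcols) < 2L || length(ccols) < 2L)
    stop("need at least 2 replicates per side", call. = FALSE)
  B <- log2(as.matrix(records[, bcols, drop = FALSE]) + pseudocount)
  C <- log2(as.matrix(records[, ccols, drop = FALSE]) + pseudocount)
  nb <- ncol(B); nc <- ncol(C)
  mB <- rowMeans(B); mC <- rowMeans(C)
  vB <- apply(B, 1, var); vC <- apply(C, 1, var)
  sp2 <- ((nb - 1) * vB + (nc - 1) * vC) / (nb + nc - 2)
  se <- sqrt(sp2 * (1 / nb + 1 / nc))
  tval <- ifelse(se > 0, (mB - mC) / se,
                 ifelse(mB == mC, 0, sign(mB - mC) * Inf))
  if (method == "t") {
    p <- 2 * pt(-abs(tval), nb + nc - 2)
  } else {
    if (nb < 4L || nc < 4L)
      stop("permutation test requires at least 4 replicates per side",
           call. = FALSE)
    X <- cbind(B, C)
    asg <- combn(nb + nc, nb, simplify = FALSE)
    tnull <- vapply(asg, function(a) {
      Bi <- X[, a, drop = FALSE]; Ci <- X[, -a, drop = FALSE]
      vb <- apply(Bi, 1, var); vc <- apply(Ci, 1, var)
      s2 <- ((nb - 1) * vb + (nc - 1) * vc) / (nb + nc - 2)
      s <- sqrt(s2 * (1 / nb + 1 / nc))
      ifelse(s > 0, (rowMeans(Bi) - rowMeans(Ci)) / s, 0)
    }, numeric(nrow(X)))
    p <- rowMeans(abs(tnull) >= abs(tval) - 1e-12)
  }
  records$p <- pmin(1, p)
  records$fdr <- p.adjust(records$p, method = "BH")
  records
}

#' Classify genes as bait-enriched
#'
#' A gene is enriched when all three conditions hold strictly:
#' fold enrichment > `min_fold`, FDR < `max_fdr`, and the per-gene read count
#' reaches `min_reads` in every bait replicate (`count_rule = "min"`,
#' default) or summed over bait replicates (`count_rule = "sum"`).
#'
#' @param records transcript records carrying `fdr` (see
#'   [differential_test()]) plus `fpkm_*` and `count_bait_*` columns.
#' @param min_fold fold-enrichment threshold, exclusive (default 2).
#' @param max_fdr FDR threshold, exclusive (default 0.01).
#' @param min_reads read-count threshold, inclusive (default 10).
#' @param count_rule `"min"` (default) or `"sum"` over bait replicates.
#' @param pseudocount pseudocount for the enrichment score (default 2).
#' @return `records` with `fold_enrichment` and `enriched` appended.
#' @export
classify_enriched <- function(records, min_fold = 2, max_fdr = 0.01,
                              min_reads = 10, count_rule = c("min", "sum"),
                              pseudocount = 2) {
  count_rule <- match.arg(count_rule)
  if (!"fdr" %in% names(records))
    stop("run differential_test() first", call. = FALSE)
  bcols <- rip_cols(records, "fpkm_bait")
  ccols <- rip_cols(records, "fpkm_control")
  kcols <- rip_cols(records, "count_bait")
  if (!length(kcols)) stop("no count_bait_* columns", call. = FALSE)
  fb <- rowMeans(records[, bcols, drop = FALSE])
  fc <- rowMeans(records[, ccols, drop = FALSE])
  records$fold_enrichment <- fold_enrichment(fb, fc, pseudocount)
  counts <- as.matrix(records[, kcols, drop = FALSE])
  count_ok <- if (count_rule == "min") apply(counts, 1, min) >= min_reads
              else rowSums(counts) >= min_reads
  records$enriched <- records$fold_enrichment > min_fold &
    records$fdr < max_fdr & count_ok
  records
}

#' RNA-type breakdown and per-gene bait preference for two baits
#'
#' Genes are labelled `both`, `<bait_a>-only`, or `<bait_b>-only` from their
#' enriched flags; within each label the RNA-type composition is reported as
#' percentages. Additionally, the per-gene preference ratio
#' `fold_enrichment_b / fold_enrichment_a` is flagged preferential when it
#' exceeds 2 or falls below 0.5 (strictly).
#'
#' @param calls_a,calls_b classified records (see [classify_enriched()]) for
#'   the two baits, on a shared gene universe.
#' @param baits labels for the two baits (default `c("NCBP2", "NCBP3")`,
#'   matching `calls_a` and `calls_b`).
#' @return a list of class `type_breakdown`: `breakdown` (data.frame:
#'   category, rna_type, n, percent), `genes` (per-gene category and
#'   preference), `counts` per category.
#' @export
breakdown_and_preference <- function(calls_a, calls_b,
                                     baits = c("NCBP2", "NCBP3")) {
  shared <- intersect(calls_a$gene_id, calls_b$gene_id)
  if (!length(shared)) stop("disjoint gene universes", call. = FALSE)
  a <- calls_a[match(shared, calls_a$gene_id), ]
  b <- calls_b[match(shared, calls_b$gene_id), ]
  category <- rep(NA_character_, length(shared))
  category[a$enriched & b$enriched] <- "both"
  category[a$enriched & !b$enriched] <- paste0(baits[1], "-only")
  category[!a$enriched & b$enriched] <- paste0(baits[2], "-only")
  pref_ratio <- b$fold_enrichment / a$fold_enrichment
  genes <- data.frame(gene_id = shared, rna_type = a$rna_type,
                      category = category,
                      preference_ratio = pref_ratio,
                      preferential = pref_ratio > 2 | pref_ratio < 0.5,
                      stringsAsFactors = FALSE)
  enr <- genes[!is.na(genes$category), ]
  breakdown <- do.call(rbind, lapply(split(enr, enr$category), function(g) {
    tt <- table(g$rna_type)
    data.frame(category = g$category[1], rna_type = names(tt),
               n = as.integer(tt), percent = 100 * as.integer(tt) / nrow(g),
               stringsAsFactors = FALSE)
  }))
  rownames(breakdown) <- NULL
  structure(list(breakdown = breakdown, genes = genes,
                 counts = table(factor(enr$category)), baits = baits),
            class = "type_breakdown")
}

#' @export
print.type_breakdown <- function(x, ...) {
  cat("Enriched genes per category:\n")
  print(x$counts)
  print(x$breakdown, digits = 3)
  invisible(x)
}

#' Scatter coordinates for a two-bait enrichment plot
#'
#' @param calls_a,calls_b classified records for the two baits.
#' @return data.frame: gene_id, rna_type, log2 fold enrichment for each bait.
#' @export
enrichment_scatter <- function(calls_a, calls_b) {
  shared <- intersect(calls_a$gene_id, calls_b$gene_id)
  a <- calls_a[match(shared, calls_a$gene_id), ]
  b <- calls_b[match(shared, calls_b$gene_id), ]
  data.frame(gene_id = shared, rna_type = a$rna_type,
             log2_enrichment_a = log2(a$fold_enrichment),
             log2_enrichment_b = log2(b$fold_enrichment),
             stringsAsFactors = FALSE)
}
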