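# Barcode-pool (TagModule microarray) fitness pipeline.
#
# Strain fitness is the difference of mean log2 tag intensities between the
# END and START samples of a competition culture, filtered for unreliable
# low-START strains, median-centred per pool, averaged per gene, and finally
# corrected for chromosomal-position trends and re-anchored so that the mode
# of the gene fitness distribution (the bulk of phenotypically silent genes)
# sits at zero.

#' Strain fitness from tag intensity tables
#'
#' `fitness = mean(END log2 intensities) - mean(START log2 intensities)` over
#' the strain's tags available in that pool's samples (uptag and downtag
#' averaged when both are present, as in full-tag mode). Strains with no tag
#' in either sample are dropped with a message.
#'
#' @param intensities data.frame `pool`, `tag_id`, `sample`
#'   (`START`/`END`), `log2_intensity` (see [simulate_microarray] /
#'   [read_intensities]).
#' @param strains strain records (see [build_barcoded_library]).
#' @return data.frame `strain_id`, `pool`, `fitness`, `start_mean`,
#'   `n_tags`, `included` (all `TRUE` here; see [filter_low_start]).
#' @export
strain_fitness <- function(intensities, strains) {
  stopifnot(all(c("pool", "tag_id", "sample", "log2_intensity") %in%
                  names(intensities)))
  out <- list()
  for (p in sort(unique(intensities$pool))) {
    tab <- intensities[intensities$pool == p, , drop = FALSE]
    st <- tab[tab$sample == "START", , drop = FALSE]
    en <- tab[tab$sample == "END", , drop = FALSE]
    if (anyDuplicated(st$tag_id) || anyDuplicated(en$tag_id))
      stop_tn("duplicated tag_id within a sample of pool %s", p)
    start_map <- stats::setNames(st$log2_intensity, st$tag_id)
    end_map <- stats::setNames(en$log2_intensity, en$tag_id)
    ps <- strains[strains[[paste0("pool", p)]], , drop = FALSE]
    up_s <- start_map[ps$uptag_id];  dn_s <- start_map[ps$downtag_id]
    up_e <- end_map[ps$uptag_id];    dn_e <- end_map[ps$downtag_id]
    # a tag is usable only if present in both samples
    use_up <- !is.na(up_s) & !is.na(up_e)
    use_dn <- !is.na(dn_s) & !is.na(dn_e)
    n_tags <- use_up + use_dn
    sm <- (ifelse(use_up, up_s, 0) + ifelse(use_dn, dn_s, 0)) / pmax(n_tags, 1L)
    em <- (ifelse(use_up, up_e, 0) + ifelse(use_dn, dn_e, 0)) / pmax(n_tags, 1L)
    drop <- n_tags == 0L
    if (any(drop))
      message(sprintf("pool %s: %d strain(s) with no tag in both samples dropped",
                      p, sum(drop)))
    out[[as.character(p)]] <- data.frame(
      strain_id = ps$strain_id[!drop],
      pool = as.integer(p),
      fitness = (em - sm)[!drop],
      start_mean = sm[!drop],
      n_tags = as.integer(n_tags[!drop]),
      included = TRUE,
      stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Exclude strains with low START signal
#'
#' Strains whose mean START log2 intensity is below `theta` are flagged
#' `included = FALSE`: their abundance estimates sit too close to array
#' background to yield a meaningful END/START ratio.
#'
#' @param fit strain fitness records (see [strain_fitness]).
#' @param theta log2 intensity threshold.
#' @return `fit` with `included` updated.
#' @export
filter_low_start <- function(fit, theta) {
  stopifnot(is.finite(theta) || is.infinite(theta))
  fit$included <- fit$included & fit$start_mean >= theta
  n <- tapply(fit$included, fit$pool, sum)
  message(sprintf("included strains after START filter: %s",
                  paste(sprintf("pool %s: %d", names(n), n), collapse = ", ")))
  fit
}

#' Median-zero normalization of strain fitness, per pool
#'
#' Subtracts the per-pool median of included strain fitness from every strain
#' of that pool, removing pool-wide composition and labelling offsets. Most
#' strains are phenotypically neutral in any one condition, so the median is
#' an estimate of the no-effect baseline.
#'
#' @param fit strain fitness records.
#' @return `fit` with `fitness` recentred; per-pool median of included
#'   strains is exactly 0 afterwards.
#' @export
normalize_strain_median <- function(fit) {
  for (p in unique(fit$pool)) {
    sel <- fit$pool == p
    inc <- sel & fit$included
    if (!any(inc)) stop_tn("empty pool %s after filtering", p)
    fit$fitness[sel] <- fit$fitness[sel] - stats::median(fit$fitness[inc])
  }
  fit
}

#' Gene fitness as the mean of strain fitness
#'
#' Unweighted mean over included strain measurements carrying insertions in
#' the gene, pools combined (a strain present in both pools contributes one
#' measurement per pool). Intergenic strains are aggregated per intergenic
#' label and flagged.
#'
#' @param fit strain fitness records (normalized; see
#'   [normalize_strain_median]).
#' @param strains strain records mapping `strain_id` to `feature`.
#' @return data.frame `gene_id`, `fitness`, `n_strains`, `intergenic`.
#' @export
gene_fitness <- function(fit, strains) {
  fit <- fit[fit$included, , drop = FALSE]
  feature <- strains$feature[match(fit$strain_id, strains$strain_id)]
  if (anyNA(feature)) stop_tn("strain_id missing from strain table")
  agg <- stats::aggregate(fit$fitness, by = list(gene_id = feature),
                          FUN = mean)
  cnt <- stats::aggregate(fit$fitness, by = list(gene_id = feature),
                          FUN = length)
  out <- data.frame(gene_id = agg$gene_id,
                    fitness = agg$x,
                    n_strains = as.integer(cnt$x),
                    intergenic = startsWith(agg$gene_id, "intergenic:"),
                    stringsAsFactors = FALSE)
  out[order(out$gene_id), , drop = FALSE]
}

#' Positional and mode-zero normalization of gene fitness
#'
#' Two steps: (1) subtract a running median of gene fitness over a centred
#' window of `window` genes in chromosome order (truncated at chromosome
#' edges), removing smooth chromosomal-position trends such as
#' replication-associated copy-number bias while being robust to isolated
#' strongly selected genes; (2) subtract the mode of the resulting values,
#' estimated as the argmax of a Gaussian kernel density on a 512-point grid
#' (Silverman bandwidth), so the bulk of no-phenotype genes is anchored at 0.
#' Intergenic entries have no well-defined gene order; they skip step 1 and
#' share the mode shift of step 2.
#'
#' @param gf gene fitness table (see [gene_fitness]).
#' @param ann a [tn_annotation] providing chromosome order.
#' @param window odd running-median window size in genes.
#' @return `gf` with `fitness` normalized.
#' @export
normalize_position_mode <- function(gf, ann, window = 251) {
  if (window %% 2 == 0) stop_tn("window must be odd")
  genic <- !gf$intergenic
  ord <- match(ann$gene_id, gf$gene_id[genic])
  present <- which(!is.na(ord))           # annotation rows with a measurement
  if (length(present) < 3L) {
    warning("fewer than 3 positioned genes; skipping positional step")
  } else {
    idx <- which(genic)[ord[present]]     # rows of gf in chromosome order
    for (ch in unique(ann$chrom[present])) {
      sel <- ann$chrom[present] == ch
      rows <- idx[sel]
      w <- min(window, 2L * floor((length(rows) - 1L) / 2L) + 1L)
      gf$fitness[rows] <- gf$fitness[rows] - running_median(gf$fitness[rows], w)
    }
  }
  gf$fitness <- gf$fitness - kde_mode(gf$fitness[genic])
  gf
}

#' Pool-agreement and operon-agreement quality metrics
#'
#' Strain correlation: Pearson correlation of fitness between the two pools
#' over strains present (and included) in both. Operon correlation: Pearson
#' correlation of gene fitness between adjacent genes predicted to lie in the
#' same operon. Both collapse when a handful of strains dominate the culture
#' (jackpot), because the remaining strains' signals sink into array
#' background and carry no reproducible information.
#'
#' @param fit strain fitness records.
#' @param gf gene fitness table.
#' @param strains strain records.
#' @param ann a [tn_annotation] with `operon_id`.
#' @return list of class `tn_quality`: `strain_correlation`, `n_shared`,
#'   `operon_correlation`, `n_operon_pairs` (correlations are `NA` with
#'   fewer than 3 pairs).
#' @export
quality_metrics <- function(fit, gf, strains, ann) {
  shared <- strains$strain_id[strains$pool1 & strains$pool2]
  f1 <- fit[fit$pool == 1L & fit$included & fit$strain_id %in% shared, ]
  f2 <- fit[fit$pool == 2L & fit$included & fit$strain_id %in% shared, ]
  common <- intersect(f1$strain_id, f2$strain_id)
  sc <- if (length(common) >= 3L) {
    stats::cor(f1$fitness[match(common, f1$strain_id)],
               f2$fitness[match(common, f2$strain_id)])
  } else NA_real_

  fmap <- stats::setNames(gf$fitness, gf$gene_id)
  adj <- which(ann$chrom[-1L] == ann$chrom[-nrow(ann)] &
                 !is.na(ann$operon_id[-1L]) &
                 ann$operon_id[-1L] == ann$operon_id[-nrow(ann)])
  a <- fmap[ann$gene_id[adj]]
  b <- fmap[ann$gene_id[adj + 1L]]
  ok <- !is.na(a) & !is.na(b)
  oc <- if (sum(ok) >= 3L) stats::cor(a[ok], b[ok]) else NA_real_

  structure(list(strain_correlation = unname(sc), n_shared = length(common),
                 operon_correlation = unname(oc), n_operon_pairs = sum(ok)),
            class = "tn_quality")
}

#' @export
print.tn_quality <- function(x, ...) {
  cat(sprintf("strain correlation: %.3f (%d shared strains)\n",
              x$strain_correlation, x$n_shared))
  cat(sprintf("operon correlation: %.3f (%d adjacent pairs)\n",
              x$operon_correlation, x$n_operon_pairs))
  invisible(x)
}

#' Full barcode-pool fitness pipeline
#'
#' [strain_fitness] -> [filter_low_start] -> [normalize_strain_median] ->
#' [gene_fitness] -> [normalize_position_mode], plus [quality_metrics].
#'
#' @param intensities intensity table.
#' @param strains strain records.
#' @param ann a [tn_annotation].
#' @param theta low-START threshold (default `-Inf`: keep everything).
#' @param window running-median window in genes.
#' @param normalize apply the normalization steps (disable only for
#'   noise-free oracle checks).
#' @return list: `strain_fitness`, `gene_fitness`, `quality`.
#' @export
barseq_pipeline <- function(intensities, strains, ann, theta = -Inf,
                            window = 251, normalize = TRUE) {
  fit <- strain_fitness(intensities, strains)
  fit <- filter_low_start(fit, theta)
  if (normalize) fit <- normalize_strain_median(fit)
  gf <- gene_fitness(fit, strains)
  if (normalize) gf <- normalize_position_mode(gf, ann, window = window)
  list(strain_fitness = fit,
       gene_fitness = gf,
       quality = quality_metrics(fit, gf, strains, ann))
}
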