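# Insertion-density (TnLE-seq) gene fitness.
#
# A gene's fitness is the log2 ratio of its unique-insertion density inside
# the 5-85% coding window to the genome-wide in-window density. Unique sites,
# not read counts, are the measurement: a site is evidence that a mutant in
# that gene survived to be sequenced, and site density rises (relative to the
# bulk) for genes whose disruption was selected for, because the bulk's sites
# drop below sequencing detection.

#' Count unique insertion sites per coding window
#'
#' Counts distinct insertion positions (strand ignored: a transposon on
#' either strand disrupts the gene) inside each gene's 5-85% window. A site
#' falling in the windows of two overlapping genes counts for both.
#'
#' @param insertions data.frame `chrom`, `position`, `strand`, `reads`.
#' @param ann a [tn_annotation].
#' @param f_lo,f_hi window fractions (see [coding_window]).
#' @return data.frame `gene_id`, `n_window`, `win_len`.
#' @export
count_in_window <- function(insertions, ann, f_lo = 0.05, f_hi = 0.85) {
  win <- coding_window(ann, f_lo, f_hi)
  keep <- win$win_len > 0L
  sites <- unique(insertions[, c("chrom", "position")])
  n <- integer(nrow(win))
  if (any(keep) && nrow(sites)) {
    wgr <- GenomicRanges::GRanges(ann$chrom[keep],
                                  IRanges::IRanges(win$win_start[keep],
                                                   win$win_end[keep]))
    sgr <- GenomicRanges::GRanges(sites$chrom,
                                  IRanges::IRanges(sites$position, sites$position))
    n[keep] <- GenomicRanges::countOverlaps(wgr, sgr, ignore.strand = TRUE)
  }
  data.frame(gene_id = win$gene_id, n_window = n, win_len = win$win_len,
             stringsAsFactors = FALSE)
}

#' Insertion-density gene fitness
#'
#' With `N` the total in-window unique sites and `Lambda` the summed window
#' lengths, `fitness = log2((n_window / win_len) / (N / Lambda))`. Genes with
#' no in-window site would be `-Inf`; they receive `pseudocount` sites and
#' are flagged (`flagged_zero`) as non-measurements.
#'
#' @param counts per-gene window counts (see [count_in_window]).
#' @param pseudocount sites substituted for zero-count genes.
#' @return data.frame `gene_id`, `n_window`, `win_len`, `fitness`,
#'   `flagged_zero`.
#' @export
tnle_gene_fitness <- function(counts, pseudocount = 1) {
  ok <- counts$win_len > 0L
  N <- sum(counts$n_window[ok])
  if (N == 0) stop_tn("no in-window insertions")
  Lambda <- sum(counts$win_len[ok])
  dens <- N / Lambda
  n_eff <- ifelse(counts$n_window == 0L, pseudocount, counts$n_window)
  fitness <- ifelse(ok, log2((n_eff / counts$win_len) / dens), NA_real_)
  data.frame(gene_id = counts$gene_id,
             n_window = counts$n_window,
             win_len = counts$win_len,
             fitness = fitness,
             flagged_zero = counts$n_window == 0L,
             stringsAsFactors = FALSE)
}

#' Convert log2 fitness to fold change and back
#'
#' @param f log2 fitness value(s).
#' @return `2^f`.
#' @export
fold_change <- function(f) 2^f

#' @rdname fold_change
#' @param fold fold change(s).
#' @return `log2(fold)`.
#' @export
log2_fold <- function(fold) log2(fold)

#' Genes with positive fitness and their insertion total
#'
#' Strictly positive fitness; pseudocount-flagged genes never qualify. The
#' summed unique in-window insertions of this set approximates the effective
#' founding population of a strongly selected enrichment culture.
#'
#' @param fit TnLE fitness table (see [tnle_gene_fitness]).
#' @return list: `genes` (character), `n_insertions` (integer),
#'   `n_genes`.
#' @export
positive_fitness_set <- function(fit) {
  sel <- !fit$flagged_zero & !is.na(fit$fitness) & fit$fitness > 0
  list(genes = fit$gene_id[sel],
       n_insertions = as.integer(sum(fit$n_window[sel])),
       n_genes = sum(sel))
}

#' Estimate population doublings of an enrichment culture
#'
#' `doublings = log2(final_cells / start_pool)`, where the starting pool size
#' is taken as the number of unique insertions in positive-fitness genes
#' (only those lineages contribute appreciably to the final population).
#'
#' @param final_cells cells in the final culture.
#' @param start_pool effective starting pool size (`>= 1`).
#' @param n_positive_genes optional count of positive-fitness genes, carried
#'   through for reporting.
#' @return list of class `tn_doublings`: `final_cells`, `start_pool`,
#'   `doublings`, `n_positive_genes`.
#' @export
estimate_doublings <- function(final_cells, start_pool,
                               n_positive_genes = NA_integer_) {
  if (start_pool < 1) stop_tn("start_pool must be >= 1")
  if (final_cells < start_pool) stop_tn("final_cells must be >= start_pool")
  structure(list(final_cells = final_cells,
                 start_pool = start_pool,
                 doublings = log2(final_cells / start_pool),
                 n_positive_genes = n_positive_genes),
            class = "tn_doublings")
}

#' @export
print.tn_doublings <- function(x, ...) {
  cat(sprintf("%.4g cells from an effective starting pool of %d: %.2f doublings\n",
              x$final_cells, as.integer(x$start_pool), x$doublings))
  invisible(x)
}

#' Full insertion-density fitness pipeline
#'
#' [count_in_window] -> [tnle_gene_fitness] -> [positive_fitness_set], with
#' an optional doublings estimate when `final_cells` is supplied.
#'
#' @param insertions insertion table.
#' @param ann a [tn_annotation].
#' @param pseudocount see [tnle_gene_fitness].
#' @param f_lo,f_hi window fractions.
#' @param final_cells optional final population size for
#'   [estimate_doublings].
#' @return list: `fitness`, `positive`, and `doublings` when requested.
#' @export
tnle_pipeline <- function(insertions, ann, pseudocount = 1,
                          f_lo = 0.05, f_hi = 0.85, final_cells = NULL) {
  counts <- count_in_window(insertions, ann, f_lo, f_hi)
  fit <- tnle_gene_fitness(counts, pseudocount)
  pos <- positive_fitness_set(fit)
  out <- list(fitness = fit, positive = pos)
  if (!is.null(final_cells))
    out$doublings <- estimate_doublings(final_cells, pos$n_insertions,
                                        pos$n_genes)
  out
}
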