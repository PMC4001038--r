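# Multi-condition assembly, candidate selection and homolog joins.

#' Assemble gene fitness tables into a gene x condition matrix
#'
#' Outer join over genes; cells absent from a condition stay `NA` (missing,
#' never 0).
#'
#' @param tables named list of gene fitness data.frames (`gene_id`,
#'   `fitness`), one per condition.
#' @param sources optional named character vector recording the pipeline
#'   (`"barseq"`/`"tnle"`) behind each condition.
#' @return data.frame of class `tn_condition_table`: `gene_id` plus one
#'   fitness column per condition; `sources` attribute.
#' @export
assemble_conditions <- function(tables, sources = NULL) {
  if (is.null(names(tables)) || anyDuplicated(names(tables)))
    stop_tn("tables must be uniquely named by condition")
  for (cond in names(tables)) {
    if (anyDuplicated(tables[[cond]]$gene_id))
      stop_tn("duplicated gene in condition %s", cond)
  }
  genes <- sort(unique(unlist(lapply(tables, `[[`, "gene_id"))))
  out <- data.frame(gene_id = genes, stringsAsFactors = FALSE)
  for (cond in names(tables)) {
    out[[cond]] <- tables[[cond]]$fitness[match(genes, tables[[cond]]$gene_id)]
  }
  structure(out, sources = sources,
            class = c("tn_condition_table", "data.frame"))
}

#' Candidate selection rule
#'
#' High fitness in every condition of `high` (anion consistency: both salts
#' of the stressor) and low fitness in every control of `low`. Strict
#' inequalities on both sides. The defaults encode the nitrate-resistance
#' rule: fitness > 2 in both nitrate salts, < 0.25 in the osmotic controls,
#' nitrite, and with no stress.
#'
#' @param high,low condition sets (disjoint).
#' @param t_high,t_low log2 fitness thresholds (`t_high > t_low`).
#' @return list of class `tn_candidate_rule`.
#' @export
candidate_rule <- function(high = c("NaNO3", "KNO3"), t_high = 2,
                           low = c("NaCl", "KCl", "NaNO2", "none"),
                           t_low = 0.25) {
  # infinite thresholds form degenerate select-all / select-none rules
  if (is.finite(t_high) && is.finite(t_low) && t_high <= t_low)
    stop_tn("t_high must exceed t_low")
  if (length(intersect(high, low))) stop_tn("high and low sets must be disjoint")
  structure(list(high = high, t_high = t_high, low = low, t_low = t_low),
            class = "tn_candidate_rule")
}

#' Select and rank candidate genes
#'
#' A gene qualifies when `fitness > t_high` in all `high` conditions and
#' `fitness < t_low` in all `low` conditions. Candidates are ranked by their
#' minimum fitness across the high conditions (a conservative,
#' anion-consistent score), ties broken by gene id. Genes with a missing
#' value in any rule condition are excluded from candidacy and listed in the
#' `incomplete` attribute.
#'
#' @param table a [assemble_conditions] table.
#' @param rule a [candidate_rule].
#' @return data.frame `gene_id`, `score`, plus the rule conditions' fitness
#'   columns, ranked; attribute `incomplete` lists excluded genes.
#' @export
select_candidates <- function(table, rule) {
  conds <- c(rule$high, rule$low)
  absent <- setdiff(conds, names(table))
  if (length(absent))
    stop_tn("rule condition(s) absent from table: %s",
            paste(absent, collapse = ", "))
  m <- as.matrix(table[, conds, drop = FALSE])
  complete <- stats::complete.cases(m)
  hi <- as.matrix(table[, rule$high, drop = FALSE])
  lo <- as.matrix(table[, rule$low, drop = FALSE])
  pass <- complete &
    apply(hi > rule$t_high, 1L, all) &
    apply(lo < rule$t_low, 1L, all)
  pass[is.na(pass)] <- FALSE
  out <- table[pass, c("gene_id", conds), drop = FALSE]
  out$score <- apply(as.matrix(out[, rule$high, drop = FALSE]), 1L, min)
  out <- out[order(-out$score, out$gene_id), c("gene_id", "score", conds)]
  rownames(out) <- NULL
  attr(out, "incomplete") <- table$gene_id[!complete]
  out
}

#' Join fitness tables of two genomes through a homolog map
#'
#' @param table_a,table_b [assemble_conditions] tables (or any data.frame
#'   with `gene_id` and the focal condition column).
#' @param map data.frame `gene_a`, `gene_b` of homolog pairs (unique).
#' @param condition focal condition present in both tables.
#' @return list: `pairs` (gene_a, gene_b, fitness_a, fitness_b),
#'   `concordance` (fraction of complete pairs with matching fitness sign;
#'   `NA` when no complete pair), `n_pairs`, `unmapped_a`, `unmapped_b`
#'   ("no homolog" genes).
#' @export
join_homologs <- function(table_a, table_b, map, condition) {
  stopifnot(all(c("gene_a", "gene_b") %in% names(map)))
  if (anyDuplicated(map[, c("gene_a", "gene_b")]))
    stop_tn("homolog pairs must be unique")
  dangle_a <- setdiff(map$gene_a, table_a$gene_id)
  dangle_b <- setdiff(map$gene_b, table_b$gene_id)
  if (length(dangle_a) || length(dangle_b))
    message(sprintf("homolog map has %d + %d ids absent from the tables",
                    length(dangle_a), length(dangle_b)))
  fa <- table_a[[condition]][match(map$gene_a, table_a$gene_id)]
  fb <- table_b[[condition]][match(map$gene_b, table_b$gene_id)]
  pairs <- data.frame(gene_a = map$gene_a, gene_b = map$gene_b,
                      fitness_a = fa, fitness_b = fb,
                      stringsAsFactors = FALSE)
  ok <- !is.na(fa) & !is.na(fb)
  concordance <- if (any(ok)) mean(sign(fa[ok]) == sign(fb[ok])) else NA_real_
  list(pairs = pairs, concordance = concordance, n_pairs = sum(ok),
       unmapped_a = setdiff(table_a$gene_id, map$gene_a),
       unmapped_b = setdiff(table_b$gene_id, map$gene_b))
}

#' Top-k genes by fitness in one condition
#'
#' Descending fitness; ties broken lexicographically by gene id; missing
#' values excluded.
#'
#' @param table a [assemble_conditions] table.
#' @param condition condition name.
#' @param k number of genes.
#' @return data.frame `gene_id`, `fitness`.
#' @export
rank_genes <- function(table, condition, k) {
  if (!condition %in% names(table))
    stop_tn("condition %s absent from table", condition)
  f <- table[[condition]]
  keep <- !is.na(f)
  ord <- order(-f[keep], table$gene_id[keep])
  idx <- which(keep)[ord][seq_len(min(k, sum(keep)))]
  data.frame(gene_id = table$gene_id[idx], fitness = f[idx],
             stringsAsFactors = FALSE)
}

#' Mutant library composition accounting
#'
#' Book-keeping for a two-pool barcoded library: distinct strains from pool
#' sizes and overlap, genes represented from per-multiplicity gene counts,
#' and coverage/homology fractions of the genome.
#'
#' @param n1,n2 pool sizes.
#' @param n_shared strains present in both pools.
#' @param genes_by_multiplicity optional integer vector of gene counts by
#'   representation class (e.g. once, twice, three-or-more).
#' @param genome_genes optional total genes in the genome.
#' @param homolog_genes optional genes with a homolog in the partner genome.
#' @return list: `distinct_strains`, and when computable
#'   `represented_genes`, `represented_percent`, `homolog_percent`.
#' @export
library_accounting <- function(n1, n2, n_shared,
                               genes_by_multiplicity = NULL,
                               genome_genes = NULL,
                               homolog_genes = NULL) {
  out <- list(distinct_strains = n1 + n2 - n_shared)
  if (!is.null(genes_by_multiplicity)) {
    out$represented_genes <- sum(genes_by_multiplicity)
    if (!is.null(genome_genes))
      out$represented_percent <- 100 * out$represented_genes / genome_genes
  }
  if (!is.null(homolog_genes) && !is.null(genome_genes))
    out$homolog_percent <- 100 * homolog_genes / genome_genes
  out
}
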