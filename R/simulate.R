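# Pooled growth-competition simulator.
#
# The growth model is deterministic exponential competition: strain i with
# selection coefficient s_i (relative rate rho_i = 1 + s_i) grows by
# a_i = x_i(0) * 2^((1+s_i) * D) over D reference doublings, and relative
# abundances are renormalized at the end. Observation noise enters only in the
# read-outs: additive hybridization background + log2-normal noise on array
# intensities, multinomial sampling on sequencing reads. All randomness is
# keyed off one master seed through labelled sub-streams (see derive_seed).

#' Simulate a synthetic bacterial genome annotation
#'
#' Gene lengths are lognormal around the configured mean (sdlog
#' `gene_length_sdlog`), genes are laid head-to-tail on one chromosome
#' separated by fixed intergenic gaps, strands are random, and operons are
#' consecutive same-strand runs with geometric run lengths (mean 2).
#'
#' @param config a [scenario_config].
#' @return a [tn_annotation].
#' @export
build_genome <- function(config) {
  stopifnot(config$n_genes >= 1)
  with_seed(derive_seed(config$seed, "genome"), {
    n <- config$n_genes
    mu <- log(config$mean_gene_length) - config$gene_length_sdlog^2 / 2
    len <- pmax(60L, as.integer(round(stats::rlnorm(n, mu, config$gene_length_sdlog))))
    gap <- as.integer(config$intergenic_gap)
    start <- cumsum(c(gap + 1L, utils::head(len, -1L) + gap))
    end <- start + len - 1L
    strand <- sample(c("+", "-"), n, replace = TRUE)
    # new operon whenever the strand flips, otherwise with prob 1/2
    new_op <- c(TRUE, strand[-1L] != strand[-n] | stats::runif(n - 1L) < 0.5)
    operon <- sprintf("op%04d", cumsum(new_op))
    genes <- data.frame(
      gene_id = sprintf("g%04d", seq_len(n)),
      chrom = "chr1",
      start = start, end = end, strand = strand,
      operon_id = operon,
      is_pseudo = FALSE,
      stringsAsFactors = FALSE)
    tn_annotation(genes, chrom_lengths = c(chr1 = max(end) + gap))
  })
}

#' Build a two-pool barcoded transposon mutant library
#'
#' Each distinct strain carries one insertion and one TagModule (an uptag and
#' a downtag, unique across the library); `overlap` strains are present in
#' both pools. Insertion positions are uniform over gene bodies (genes hit in
#' proportion to length) with an `intergenic_frac` fraction landing between
#' genes. Genes in `ensure_genes` are guaranteed `ensure_per_gene` shared
#' strains each, emulating a catalogued library known to cover them.
#'
#' @param ann a [tn_annotation].
#' @param n1,n2 pool sizes (number of strains per pool).
#' @param overlap number of strains present in both pools
#'   (`<= min(n1, n2)`).
#' @param seed integer seed.
#' @param intergenic_frac fraction of strains with intergenic insertions.
#' @param ensure_genes gene ids guaranteed coverage via shared strains.
#' @param ensure_per_gene shared strains per ensured gene.
#' @param rate_sd sd of per-strain idiosyncratic rate deviation (insertion
#'   position and barcode effects); `true_rate = 1 + N(0, rate_sd)`.
#' @param low_start_frac fraction of strains at depressed starting abundance.
#' @param low_start_factor relative starting abundance of those strains.
#' @return data.frame of strain records: `strain_id`, `chrom`, `position`,
#'   `feature`, `pool1`, `pool2`, `uptag_id`, `downtag_id`, `true_rate`,
#'   `start_weight`.
#' @export
build_barcoded_library <- function(ann, n1, n2, overlap, seed,
                                   intergenic_frac = 0.05,
                                   ensure_genes = character(),
                                   ensure_per_gene = 2L,
                                   rate_sd = 0,
                                   low_start_frac = 0,
                                   low_start_factor = 0.01) {
  if (overlap > min(n1, n2))
    stop_tn("overlap (%d) exceeds min(n1, n2) = %d", overlap, min(n1, n2))
  n_ens <- length(ensure_genes) * ensure_per_gene
  if (n_ens > overlap)
    stop_tn("ensured strains (%d) exceed the configured overlap (%d)", n_ens, overlap)
  with_seed(derive_seed(seed, "library"), {
    n_distinct <- n1 + n2 - overlap
    n_free <- n_distinct - n_ens

    # ensured strains: uniform positions within each ensured gene
    ens_rows <- match(ensure_genes, ann$gene_id)
    if (anyNA(ens_rows)) stop_tn("ensure_genes not in annotation")
    ens_idx <- rep(ens_rows, each = ensure_per_gene)
    ens_pos <- ann$start[ens_idx] +
      floor(stats::runif(n_ens) * (ann$end[ens_idx] - ann$start[ens_idx] + 1L))
    ens_chrom <- ann$chrom[ens_idx]

    # free strains: genic in proportion to gene length, or intergenic
    inter <- stats::runif(n_free) < intergenic_frac
    n_genic <- sum(!inter)
    gidx <- sample.int(nrow(ann), n_genic, replace = TRUE,
                       prob = ann$end - ann$start + 1)
    gpos <- ann$start[gidx] +
      floor(stats::runif(n_genic) * (ann$end[gidx] - ann$start[gidx] + 1L))
    # intergenic: uniform over the complement of gene bodies
    cl <- chrom_lengths(ann)
    gr <- GenomicRanges::GRanges(ann$chrom, IRanges::IRanges(ann$start, ann$end))
    GenomeInfoDb::seqlengths(gr) <- cl[GenomeInfoDb::seqlevels(gr)]
    gaps <- GenomicRanges::gaps(gr)
    gaps <- gaps[BiocGenerics::strand(gaps) == "*"]
    glen <- BiocGenerics::width(gaps)
    n_inter <- sum(inter)
    ii <- sample.int(length(gaps), n_inter, replace = TRUE, prob = glen)
    ipos <- BiocGenerics::start(gaps)[ii] +
      floor(stats::runif(n_inter) * glen[ii])
    ichrom <- as.character(GenomeInfoDb::seqnames(gaps))[ii]

    position <- integer(n_free)
    chrom_free <- character(n_free)
    position[!inter] <- gpos
    chrom_free[!inter] <- ann$chrom[gidx]
    position[inter] <- ipos
    chrom_free[inter] <- ichrom

    chrom <- c(ens_chrom, chrom_free)
    position <- c(ens_pos, position)

    strains <- data.frame(
      strain_id = sprintf("s%05d", seq_len(n_distinct)),
      chrom = chrom,
      position = as.integer(position),
      feature = map_position(ann, chrom, position),
      pool1 = FALSE, pool2 = FALSE,
      uptag_id = sprintf("u%05d", seq_len(n_distinct)),
      downtag_id = sprintf("d%05d", seq_len(n_distinct)),
      true_rate = 1 + stats::rnorm(n_distinct, 0, rate_sd),
      start_weight = 1,
      stringsAsFactors = FALSE)

    # ensured strains are shared; fill the remaining overlap with random free
    # strains, then split the rest between the two pools
    free <- setdiff(seq_len(n_distinct), seq_len(n_ens))
    shared_extra <- sample(free, overlap - n_ens)
    shared <- c(seq_len(n_ens), shared_extra)
    rest <- setdiff(seq_len(n_distinct), shared)
    only1 <- rest[seq_len(n1 - overlap)]
    only2 <- setdiff(rest, only1)
    strains$pool1[c(shared, only1)] <- TRUE
    strains$pool2[c(shared, only2)] <- TRUE

    if (low_start_frac > 0) {
      low <- stats::runif(n_distinct) < low_start_frac
      strains$start_weight[low] <- low_start_factor
    }
    strains
  })
}

#' Deterministic exponential growth competition
#'
#' `a_i = x_i(0) * 2^((1 + s_i) * D)`, renormalized to relative abundances at
#' the end; the true strain fitness `w_i = log2(x_i(END)/x_i(START))` is
#' returned for oracle checks.
#'
#' @param strains strain records (only `strain_id` and `start_weight` are
#'   used; `start_weight` sets relative starting abundances unless `x_start`
#'   is given).
#' @param s per-strain selection coefficients (relative rate is `1 + s`).
#' @param D reference doublings of a neutral strain (`>= 0`).
#' @param x_start optional starting relative abundances (positive; normalized
#'   internally).
#' @return list of class `tn_abundance`: `strain_id`, `x_start`, `x_end`, `w`.
#' @export
simulate_competition <- function(strains, s, D, x_start = NULL) {
  stopifnot(D >= 0)
  n <- nrow(strains)
  s <- rep_len(s, n)
  if (is.null(x_start)) x_start <- strains$start_weight %||% rep(1, n)
  if (any(x_start <= 0)) stop_tn("starting abundances must be positive")
  x_start <- x_start / sum(x_start)
  a <- x_start * 2^((1 + s) * D)
  x_end <- a / sum(a)
  structure(list(strain_id = strains$strain_id,
                 x_start = x_start, x_end = x_end,
                 w = log2(x_end / x_start)),
            class = "tn_abundance")
}

#' Simulate barcode microarray intensity tables
#'
#' Per tag, `log2_intensity = log2(scale * x + background) + N(0, sigma)`,
#' independent across tags and samples. The additive `background` models
#' nonspecific hybridization signal: strains whose abundance falls well below
#' `background/scale` become indistinguishable from noise, which is what
#' degrades pool-wide quality metrics in strong-selection (jackpot) cultures.
#' In `"array"` mode only uptags are emitted for pool 1 and only downtags for
#' pool 2 (one array per experiment); `"full"` mode emits both tags per pool.
#'
#' @param states named list `"1"`, `"2"` of `tn_abundance` objects, one per
#'   pool, aligned with that pool's strains.
#' @param strains strain records (see [build_barcoded_library]).
#' @param sigma log2 intensity noise sd (`>= 0`).
#' @param scale linear intensity per unit relative abundance.
#' @param background additive background intensity (linear scale).
#' @param seed integer seed.
#' @param mode `"array"` or `"full"`.
#' @return data.frame `pool`, `tag_id`, `sample` (`START`/`END`),
#'   `log2_intensity`.
#' @export
simulate_microarray <- function(states, strains, sigma, scale = 2e6,
                                background = 10, seed = 1,
                                mode = c("array", "full")) {
  mode <- match.arg(mode)
  stopifnot(sigma >= 0)
  with_seed(derive_seed(seed, "microarray"), {
    out <- list()
    for (p in c("1", "2")) {
      st <- states[[p]]
      if (is.null(st)) next
      pool_strains <- strains[strains[[paste0("pool", p)]], , drop = FALSE]
      stopifnot(identical(pool_strains$strain_id, st$strain_id))
      tags <- if (mode == "full") {
        list(pool_strains$uptag_id, pool_strains$downtag_id)
      } else if (p == "1") list(pool_strains$uptag_id) else list(pool_strains$downtag_id)
      for (tg in tags) {
        for (smp in c("START", "END")) {
          x <- if (smp == "START") st$x_start else st$x_end
          out[[length(out) + 1L]] <- data.frame(
            pool = as.integer(p),
            tag_id = tg,
            sample = smp,
            log2_intensity = log2(scale * x + background) +
              stats::rnorm(length(x), 0, sigma),
            stringsAsFactors = FALSE)
        }
      }
    }
    do.call(rbind, out)
  })
}

#' Simulate a TnLE-seq insertion table
#'
#' `n_sites` unique insertion positions are drawn uniformly over the genome;
#' each site inherits the selection coefficient of its containing gene
#' (intergenic sites are neutral), the pool undergoes the same exponential
#' competition over `D` doublings, and `total_reads` sequencing reads are
#' distributed multinomially with probabilities proportional to the
#' post-competition abundances. Sites receiving no reads are not observed.
#'
#' @param ann a [tn_annotation].
#' @param gene_s named numeric vector of per-gene selection coefficients
#'   (missing genes are neutral).
#' @param D doublings of the enrichment culture.
#' @param n_sites number of unique insertion sites created.
#' @param total_reads total sequencing reads (`>= n_sites` recommended).
#' @param seed integer seed.
#' @param condition condition label carried on the table.
#' @return data.frame `chrom`, `position`, `strand`, `reads` (observed sites
#'   only), with attributes `condition` and `true_s` (per observed site).
#' @export
simulate_tnle <- function(ann, gene_s, D, n_sites, total_reads, seed = 1,
                          condition = "stress") {
  stopifnot(n_sites >= 1, total_reads >= 1)
  cl <- chrom_lengths(ann)
  with_seed(derive_seed(seed, "tnle"), {
    # uniform unique positions over the (possibly multi-chromosome) genome
    tot <- sum(cl)
    flat <- sort(sample.int(tot, n_sites))
    bounds <- cumsum(cl)
    ci <- findInterval(flat - 1L, c(0, bounds), rightmost.closed = TRUE)
    chrom <- names(cl)[ci]
    position <- as.integer(flat - c(0, bounds)[ci])
    strand <- sample(c("+", "-"), n_sites, replace = TRUE)

    feat <- map_position(ann, chrom, position)
    # a site in overlapping genes inherits the first id; synthetic genomes
    # are non-overlapping so this is exact there
    first_gene <- sub(",.*$", "", feat)
    s <- ifelse(startsWith(feat, "intergenic:"), 0,
                unname(gene_s[first_gene]))
    s[is.na(s)] <- 0

    wgt <- 2^((1 + s) * D)
    reads <- as.integer(stats::rmultinom(1L, total_reads, wgt / sum(wgt)))
    keep <- reads >= 1L
    structure(data.frame(chrom = chrom[keep], position = position[keep],
                         strand = strand[keep], reads = reads[keep],
                         stringsAsFactors = FALSE),
              condition = condition,
              true_s = s[keep])
  })
}
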