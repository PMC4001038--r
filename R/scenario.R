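# Scenario configuration and the end-to-end experiment runner.

#' Scenario configuration for a simulated fitness-profiling study
#'
#' Bundles every tunable of the simulator. Defaults describe a mid-size
#' bacterial genome profiled with two overlapping barcoded pools and one
#' dense insertion library; see [nitrate_scenario] for the canonical
#' strong-selection study.
#'
#' @param seed master seed; every stochastic component derives its own
#'   labelled sub-stream from it.
#' @param n_genes number of genes.
#' @param mean_gene_length,gene_length_sdlog lognormal gene length model (bp).
#' @param intergenic_gap fixed gap between consecutive genes (bp).
#' @param n1,n2,overlap pool sizes and number of shared strains.
#' @param intergenic_frac fraction of library strains inserted between genes.
#' @param rate_sd sd of per-strain idiosyncratic rate deviation.
#' @param low_start_frac,low_start_factor fraction and relative abundance of
#'   strains underrepresented at inoculation.
#' @param sigma log2 intensity noise sd.
#' @param scale,background microarray gain and additive background.
#' @param conditions character vector of condition names.
#' @param doublings named vector of reference doublings per condition
#'   (unnamed scalar is recycled).
#' @param effects data.frame (`gene_index`, `condition`, `s`) of planted
#'   per-gene selection coefficients; a condition of `"*"` applies everywhere.
#' @param tnle_condition,tnle_doublings,tnle_sites,tnle_reads insertion-
#'   library read-out: condition profiled, enrichment doublings, unique
#'   sites created, total sequencing reads.
#' @param theta low-START exclusion threshold (log2 intensity); default
#'   `log2(4 * background)`.
#' @param position_window running-median window (genes) for the positional
#'   correction.
#' @return list of class `tn_scenario`.
#' @export
scenario_config <- function(seed = 1,
                            n_genes = 2400,
                            mean_gene_length = 900,
                            gene_length_sdlog = 0.3,
                            intergenic_gap = 100,
                            n1 = 2200, n2 = 2200, overlap = 400,
                            intergenic_frac = 0.05,
                            rate_sd = 0.45,
                            low_start_frac = 0.05,
                            low_start_factor = 0.01,
                            sigma = 0.3,
                            scale = 2e6,
                            background = 10,
                            conditions = c("NaNO3", "KNO3", "NaCl", "KCl",
                                           "NaNO2", "none"),
                            doublings = 3.3,
                            effects = NULL,
                            tnle_condition = "NaNO3",
                            tnle_doublings = 3.3,
                            tnle_sites = 8e5,
                            tnle_reads = 4e6,
                            theta = NULL,
                            position_window = 251) {
  if (overlap > min(n1, n2)) stop_tn("overlap exceeds min(n1, n2)")
  if (any(doublings < 0)) stop_tn("doublings must be >= 0")
  if (sigma < 0) stop_tn("sigma must be >= 0")
  if (is.null(names(doublings)))
    doublings <- stats::setNames(rep_len(doublings, length(conditions)), conditions)
  if (is.null(effects))
    effects <- data.frame(gene_index = integer(), condition = character(),
                          s = numeric(), stringsAsFactors = FALSE)
  if (is.null(theta)) theta <- log2(4 * background)
  structure(list(
    seed = seed, n_genes = n_genes,
    mean_gene_length = mean_gene_length,
    gene_length_sdlog = gene_length_sdlog,
    intergenic_gap = intergenic_gap,
    n1 = n1, n2 = n2, overlap = overlap,
    intergenic_frac = intergenic_frac,
    rate_sd = rate_sd,
    low_start_frac = low_start_frac, low_start_factor = low_start_factor,
    sigma = sigma, scale = scale, background = background,
    conditions = conditions, doublings = doublings,
    effects = effects,
    tnle_condition = tnle_condition, tnle_doublings = tnle_doublings,
    tnle_sites = tnle_sites, tnle_reads = tnle_reads,
    theta = theta, position_window = position_window),
    class = "tn_scenario")
}

#' Canonical nitrate-resistance scenario
#'
#' A 2400-gene genome in which a contiguous 9-gene cluster (selection
#' coefficients 2 to 4, evenly spaced) plus one distant regulator gene
#' (s = 3) carry strong positive selection under both nitrate salts
#' (`NaNO3`, `KNO3`) and are neutral under the osmotic/nitrite controls
#' (`NaCl`, `KCl`, `NaNO2`, `none`); 2% of the remaining genes are mildly
#' sick (s = -1) in every condition, the auxotroph analogue of a defined
#' medium. The middle cluster gene is flagged as a pseudogene (it is scored
#' like any other gene). The planted genes are guaranteed library coverage.
#'
#' @param seed master seed.
#' @param ... overrides passed to [scenario_config].
#' @return a `tn_scenario` with elements `planted_cluster`,
#'   `regulator_index`, `sick_index` identifying the planted gene indices.
#' @export
nitrate_scenario <- function(seed = 1, ...) {
  cfg <- scenario_config(seed = seed, ...)
  with_seed(derive_seed(seed, "plant"), {
    n <- cfg$n_genes
    cluster_start <- sample(seq(round(0.2 * n), round(0.6 * n)), 1L)
    cluster <- cluster_start:(cluster_start + 8L)
    regulator <- sample(setdiff(seq(round(0.7 * n), round(0.95 * n)),
                                cluster), 1L)
    planted <- c(cluster, regulator)
    sick <- sample(setdiff(seq_len(n), planted), round(0.02 * n))
    s_planted <- c(seq(2, 4, length.out = 9L), 3)
    eff <- rbind(
      do.call(rbind, lapply(c("NaNO3", "KNO3"), function(cond)
        data.frame(gene_index = planted, condition = cond, s = s_planted,
                   stringsAsFactors = FALSE))),
      data.frame(gene_index = sick, condition = "*", s = -1,
                 stringsAsFactors = FALSE))
    cfg$effects <- eff
    cfg$planted_cluster <- cluster
    cfg$regulator_index <- regulator
    cfg$planted_index <- planted
    cfg$sick_index <- sick
    cfg$pseudo_index <- cluster[5L]
    cfg
  })
}

#' Per-gene selection coefficients of a condition
#'
#' @param config a `tn_scenario`.
#' @param ann the annotation built from it (see [build_genome]).
#' @param condition condition name.
#' @return named numeric vector over all gene ids (0 = neutral).
#' @export
gene_selection <- function(config, ann, condition) {
  s <- stats::setNames(rep(0, nrow(ann)), ann$gene_id)
  eff <- config$effects
  eff <- eff[eff$condition %in% c(condition, "*"), , drop = FALSE]
  if (nrow(eff)) {
    acc <- tapply(eff$s, eff$gene_index, sum)
    idx <- as.integer(names(acc))
    s[idx] <- s[idx] + as.numeric(acc)
  }
  s
}

#' Run a full simulated fitness-profiling study
#'
#' Builds the genome and the barcoded library, competes each pool under every
#' condition, simulates the microarray read-out, runs the barcode fitness
#' pipeline per condition, simulates and scores the insertion-density
#' (TnLE-seq) read-out for `tnle_condition`, assembles the condition table
#' and applies the nitrate candidate rule. When `out_dir` is given, all
#' tables are written as TSV along with a `manifest.json` recording
#' parameters, outputs and checksums; re-running with the same config is
#' byte-identical.
#'
#' @param config a `tn_scenario` (see [nitrate_scenario]).
#' @param out_dir optional output directory.
#' @return list with elements `annotation`, `strains`, `barseq` (per
#'   condition: intensities, strain/gene fitness, quality), `tnle`
#'   (insertions + fitness table), `table` (condition x gene fitness),
#'   `candidates`, `truth` (per-gene true fitness per condition), `manifest`.
#' @export
run_scenario <- function(config, out_dir = NULL) {
  ann <- build_genome(config)
  ensured <- if (!is.null(config$planted_index))
    ann$gene_id[config$planted_index] else character()
  strains <- build_barcoded_library(
    ann, config$n1, config$n2, config$overlap, seed = config$seed,
    intergenic_frac = config$intergenic_frac,
    ensure_genes = ensured,
    rate_sd = config$rate_sd,
    low_start_frac = config$low_start_frac,
    low_start_factor = config$low_start_factor)

  barseq <- list()
  truth <- list()
  for (cond in config$conditions) {
    gs <- gene_selection(config, ann, cond)
    D <- config$doublings[[cond]]
    states <- list()
    fit_true <- list()
    for (p in c("1", "2")) {
      ps <- strains[strains[[paste0("pool", p)]], , drop = FALSE]
      s_strain <- (ps$true_rate - 1) +
        ifelse(startsWith(ps$feature, "intergenic:"), 0,
               gs[sub(",.*$", "", ps$feature)])
      s_strain[is.na(s_strain)] <- ps$true_rate[is.na(s_strain)] - 1
      states[[p]] <- simulate_competition(ps, s_strain, D)
      fit_true[[p]] <- data.frame(strain_id = ps$strain_id,
                                  pool = as.integer(p),
                                  w = states[[p]]$w,
                                  feature = ps$feature,
                                  stringsAsFactors = FALSE)
    }
    ints <- simulate_microarray(states, strains, sigma = config$sigma,
                                scale = config$scale,
                                background = config$background,
                                seed = derive_seed(config$seed, cond))
    res <- barseq_pipeline(ints, strains, ann, theta = config$theta,
                           window = config$position_window)
    res$condition <- cond
    res$truth <- do.call(rbind, fit_true)
    barseq[[cond]] <- res
    tw <- res$truth[!startsWith(res$truth$feature, "intergenic:"), ]
    truth[[cond]] <- stats::aggregate(w ~ feature, data = tw, FUN = mean)
  }

  tnle_gs <- gene_selection(config, ann, config$tnle_condition)
  ins <- simulate_tnle(ann, tnle_gs, D = config$tnle_doublings,
                       n_sites = config$tnle_sites,
                       total_reads = config$tnle_reads,
                       seed = config$seed,
                       condition = config$tnle_condition)
  tnle <- tnle_pipeline(ins, ann)

  gene_tabs <- lapply(barseq, `[[`, "gene_fitness")
  tab <- assemble_conditions(gene_tabs,
                             sources = stats::setNames(
                               rep("barseq", length(gene_tabs)),
                               names(gene_tabs)))
  candidates <- select_candidates(tab, candidate_rule())

  result <- list(annotation = ann, strains = strains, barseq = barseq,
                 tnle = c(list(insertions = ins), tnle),
                 table = tab, candidates = candidates,
                 truth = truth, config = config)

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    paths <- character()
    wr <- function(obj, name, fun) {
      p <- file.path(out_dir, name)
      fun(obj, p)
      paths[[name]] <<- p
      p
    }
    wr(ann, "annotation.tsv", write_annotation)
    wr(strains, "strains.tsv", write_strains)
    for (cond in names(barseq)) {
      wr(barseq[[cond]]$gene_fitness, sprintf("gene_fitness_%s.tsv", cond),
         write_gene_fitness)
    }
    wr(result$tnle$fitness, "tnle_fitness.tsv", write_tnle_fitness)
    wr(ins, "insertions.tsv", write_insertions)
    wr(tab, "condition_table.tsv", write_condition_table)
    wr(candidates, "candidates.tsv",
       function(x, p) utils::write.table(x, p, sep = "\t", quote = FALSE,
                                         row.names = FALSE))
    quality <- lapply(barseq, function(b) unclass(b$quality))
    jsonlite::write_json(quality, file.path(out_dir, "quality.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    paths[["quality.json"]] <- file.path(out_dir, "quality.json")
    manifest <- list(
      seed = config$seed,
      parameters = unclass(config)[c("n_genes", "mean_gene_length", "n1", "n2",
                                     "overlap", "sigma", "scale", "background",
                                     "rate_sd", "doublings", "tnle_sites",
                                     "tnle_reads", "theta", "position_window")],
      outputs = as.list(unname(paths)),
      checksums = as.list(tools::md5sum(unname(unlist(paths)))))
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    result$manifest <- manifest
  }
  result
}
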