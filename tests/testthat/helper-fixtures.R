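# Fixtures are built in code; the expensive nitrate study is built once per
# test run and shared across files.

.fixture_env <- new.env(parent = emptyenv())

# Hand-built five-gene annotation on one chromosome, incl. an operon pair.
tiny_annotation <- function() {
  tn_annotation(data.frame(
    gene_id = c("gA", "gB", "gC", "gD", "gE"),
    chrom = "chr1",
    start = c(1001L, 3001L, 5001L, 7001L, 9001L),
    end = c(2000L, 4000L, 6000L, 7600L, 10000L),
    strand = c("+", "+", "-", "-", "+"),
    operon_id = c("op1", "op1", "op2", "op2", NA),
    is_pseudo = c(FALSE, FALSE, FALSE, FALSE, TRUE),
    stringsAsFactors = FALSE), chrom_lengths = c(chr1 = 12000))
}

# Full nitrate-resistance study at the canonical scale, memoised.
nitrate_fixture <- function(seed = 1) {
  key <- paste0("nitrate_", seed)
  if (is.null(.fixture_env[[key]])) {
    cfg <- nitrate_scenario(seed = seed)
    res <- suppressMessages(run_scenario(cfg))
    res$planted_ids <- res$annotation$gene_id[cfg$planted_index]
    res$sick_ids <- res$annotation$gene_id[cfg$sick_index]
    .fixture_env[[key]] <- res
  }
  .fixture_env[[key]]
}

# Per-gene true fitness aligned with the strains the estimator kept.
included_truth <- function(res, condition) {
  b <- res$barseq[[condition]]
  fit <- b$strain_fitness
  tr <- b$truth
  key <- paste(fit$strain_id, fit$pool)
  inc <- fit$included[match(paste(tr$strain_id, tr$pool), key)]
  inc[is.na(inc)] <- FALSE
  tr <- tr[inc & !startsWith(tr$feature, "intergenic:"), , drop = FALSE]
  stats::aggregate(w ~ feature, data = tr, FUN = mean)
}

# Matched jackpot / neutral competition pair sharing library, noise and
# seeds; only the ten planted strain effects differ.
jackpot_pair <- function(seed = 1, n_strains = 2000, n_jackpot = 10,
                         s_jack = 5, D = 3.3) {
  key <- sprintf("jackpot_%d", seed)
  if (is.null(.fixture_env[[key]])) {
    cfg <- scenario_config(seed = seed, n_genes = 600, n1 = n_strains,
                           n2 = n_strains, overlap = 400)
    ann <- build_genome(cfg)
    strains <- build_barcoded_library(ann, cfg$n1, cfg$n2, cfg$overlap,
                                      seed = seed, rate_sd = cfg$rate_sd)
    set.seed(derive_seed(seed, "jackpot_pick"))
    pick <- sample(strains$strain_id, n_jackpot)
    run_one <- function(s_extra) {
      states <- list()
      for (p in c("1", "2")) {
        ps <- strains[strains[[paste0("pool", p)]], , drop = FALSE]
        s <- (ps$true_rate - 1) + ifelse(ps$strain_id %in% pick, s_extra, 0)
        states[[p]] <- simulate_competition(ps, s, D)
      }
      ints <- simulate_microarray(states, strains, sigma = cfg$sigma,
                                  scale = cfg$scale,
                                  background = cfg$background, seed = seed)
      suppressMessages(
        barseq_pipeline(ints, strains, ann, theta = cfg$theta, window = 51))
    }
    .fixture_env[[key]] <- list(neutral = run_one(0), jackpot = run_one(s_jack))
  }
  .fixture_env[[key]]
}
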