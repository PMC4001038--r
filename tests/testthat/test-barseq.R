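# Small hand-built pool: two strains in pool 1, two in pool 2.
toy_strains <- function() {
  data.frame(strain_id = c("s1", "s2", "s3", "s4"),
             chrom = "c", position = c(10L, 20L, 30L, 40L),
             feature = c("gA", "gA", "gB", "gB"),
             pool1 = c(TRUE, TRUE, FALSE, FALSE),
             pool2 = c(FALSE, FALSE, TRUE, TRUE),
             uptag_id = paste0("u", 1:4), downtag_id = paste0("d", 1:4),
             true_rate = 1, start_weight = 1, stringsAsFactors = FALSE)
}

toy_intensities <- function() {
  # s1 carries both tags (full-tag style), the rest one tag each
  rbind(
    data.frame(pool = 1L, tag_id = c("u1", "d1", "u2"), sample = "START",
               log2_intensity = c(8, 10, 7), stringsAsFactors = FALSE),
    data.frame(pool = 1L, tag_id = c("u1", "d1", "u2"), sample = "END",
               log2_intensity = c(9, 11, 7), stringsAsFactors = FALSE),
    data.frame(pool = 2L, tag_id = c("d3", "d4"), sample = "START",
               log2_intensity = c(6, 9), stringsAsFactors = FALSE),
    data.frame(pool = 2L, tag_id = c("d3", "d4"), sample = "END",
               log2_intensity = c(8, 9), stringsAsFactors = FALSE))
}

test_that("strain fitness is the difference of mean tag log2 intensities", {
  fit <- suppressMessages(strain_fitness(toy_intensities(), toy_strains()))
  f <- setNames(fit$fitness, fit$strain_id)
  expect_equal(unname(f["s1"]), 10 - 9)    # means of (9,11) vs (8,10)
  expect_equal(unname(f["s2"]), 0)         # unchanged tag
  expect_equal(unname(f["s3"]), 2)
  expect_equal(unname(f["s4"]), 0)
  expect_equal(fit$start_mean[fit$strain_id == "s1"], 9)
})

test_that("strains missing a tag in one sample are dropped with a message", {
  ints <- toy_intensities()
  ints <- ints[!(ints$tag_id == "u2" & ints$sample == "END"), ]
  expect_message(fit <- strain_fitness(ints, toy_strains()), "dropped")
  expect_false("s2" %in% fit$strain_id)
})

test_that("low-START filtering keeps everything at -Inf and empties above max", {
  fit <- suppressMessages(strain_fitness(toy_intensities(), toy_strains()))
  all_in <- suppressMessages(filter_low_start(fit, -Inf))
  expect_true(all(all_in$included))
  none <- suppressMessages(filter_low_start(fit, 100))
  expect_false(any(none$included))
  expect_error(normalize_strain_median(none), "empty pool")
})

test_that("low-abundance strains planted by the simulator are excluded", {
  res <- nitrate_fixture()
  cfg <- res$config
  fit <- res$barseq$NaNO3$strain_fitness
  low <- res$strains$strain_id[res$strains$start_weight < 1]
  is_low <- fit$strain_id %in% low
  expect_gte(mean(!fit$included[is_low]), 0.95)   # planted lows caught
  expect_lte(mean(!fit$included[!is_low]), 0.01)  # normal strains kept
})

test_that("median normalization zeroes each pool and removes pool offsets", {
  fit <- data.frame(strain_id = sprintf("s%d", 1:6),
                    pool = rep(1:2, each = 3),
                    fitness = c(1, 2, 3, -1, 0, 1) + rep(c(2, -2), each = 3),
                    start_mean = 10, n_tags = 1L, included = TRUE,
                    stringsAsFactors = FALSE)
  out <- normalize_strain_median(fit)
  expect_equal(out$fitness[1:3], c(-1, 0, 1))
  expect_equal(out$fitness[4:6], c(-1, 0, 1))
  expect_equal(median(out$fitness[out$pool == 1]), 0)
  expect_identical(normalize_strain_median(out)$fitness, out$fitness)
})

test_that("gene fitness is the unweighted mean over included strains", {
  fit <- data.frame(strain_id = c("s1", "s2", "s3", "s4"),
                    pool = c(1L, 1L, 2L, 2L),
                    fitness = c(3, 5, 7, 100),
                    start_mean = 10, n_tags = 1L,
                    included = c(TRUE, TRUE, TRUE, FALSE),
                    stringsAsFactors = FALSE)
  strains <- toy_strains()
  gf <- gene_fitness(fit, strains)
  expect_equal(gf$fitness[gf$gene_id == "gA"], 4)  # mean of 3 and 5
  expect_equal(gf$fitness[gf$gene_id == "gB"], 7)  # excluded strain ignored
  expect_equal(gf$n_strains[gf$gene_id == "gA"], 2L)
})

test_that("gene averaging matches a brute-force group-by on a simulated pool", {
  res <- nitrate_fixture()
  fit <- res$barseq$none$strain_fitness
  sub <- fit[fit$included, ][1:500, ]
  feature <- res$strains$feature[match(sub$strain_id, res$strains$strain_id)]
  brute <- tapply(sub$fitness, feature, mean)
  gf <- gene_fitness(sub, res$strains)
  expect_equal(gf$fitness, as.numeric(brute[gf$gene_id]), tolerance = 1e-12)
})

test_that("position/mode normalization removes drift but not jackpot genes", {
  ann <- build_genome(scenario_config(seed = 21, n_genes = 2400))
  n <- nrow(ann)
  set.seed(21)
  noise <- rnorm(n, 0, 0.3)
  drift <- seq(-1.5, 1.5, length.out = n)
  gf <- data.frame(gene_id = ann$gene_id, fitness = drift + noise,
                   n_strains = 1L, intergenic = FALSE,
                   stringsAsFactors = FALSE)
  out <- normalize_position_mode(gf, ann)
  expect_lt(abs(cor(out$fitness, seq_len(n))), 0.1)

  # constant field collapses to exactly zero
  flat <- gf; flat$fitness <- 2.7
  out0 <- normalize_position_mode(flat, ann)
  expect_equal(out0$fitness, rep(0, n))

  # ten contiguous jackpot genes barely move (robust running median)
  jack <- gf; jack$fitness <- noise
  jack$fitness[1000:1009] <- jack$fitness[1000:1009] + 8
  out1 <- normalize_position_mode(jack, ann)
  base <- gf; base$fitness <- noise
  base <- normalize_position_mode(base, ann)
  corr_jack <- jack$fitness - out1$fitness   # total correction per gene
  corr_base <- noise - base$fitness
  d <- corr_jack - corr_base                 # extra correction from outliers
  expect_lt(max(abs(d[1000:1009] - median(d))), 0.05)
})

test_that("pipeline is invariant to per-pool END intensity offsets", {
  ann <- build_genome(scenario_config(seed = 22, n_genes = 200))
  lib <- build_barcoded_library(ann, 400, 400, 100, seed = 22, rate_sd = 0.3)
  states <- lapply(c("1", "2"), function(p) {
    ps <- lib[lib[[paste0("pool", p)]], ]
    simulate_competition(ps, ps$true_rate - 1, D = 3.3)
  })
  names(states) <- c("1", "2")
  ints <- simulate_microarray(states, lib, sigma = 0.1, seed = 22)
  shifted <- ints
  bump <- shifted$pool == 1L & shifted$sample == "END"
  shifted$log2_intensity[bump] <- shifted$log2_intensity[bump] + 5
  a <- suppressMessages(barseq_pipeline(ints, lib, ann, window = 51))
  b <- suppressMessages(barseq_pipeline(shifted, lib, ann, window = 51))
  expect_equal(a$gene_fitness$fitness, b$gene_fitness$fitness,
               tolerance = 1e-9)
})

test_that("noise-free pipeline reproduces simulator truth", {
  ann <- build_genome(scenario_config(seed = 23, n_genes = 150))
  lib <- build_barcoded_library(ann, 300, 300, 80, seed = 23, rate_sd = 0.4)
  states <- lapply(c("1", "2"), function(p) {
    ps <- lib[lib[[paste0("pool", p)]], ]
    simulate_competition(ps, ps$true_rate - 1, D = 3.3)
  })
  names(states) <- c("1", "2")
  ints <- simulate_microarray(states, lib, sigma = 0, scale = 1e6,
                              background = 0, seed = 23)
  raw <- suppressMessages(barseq_pipeline(ints, lib, ann, normalize = FALSE))
  for (p in c("1", "2")) {
    ps <- raw$strain_fitness[raw$strain_fitness$pool == as.integer(p), ]
    expect_equal(ps$fitness,
                 states[[p]]$w[match(ps$strain_id, states[[p]]$strain_id)],
                 tolerance = 1e-9)
  }
  # with per-pool median normalization, truth is recovered up to a per-pool
  # additive constant
  norm <- suppressMessages(barseq_pipeline(ints, lib, ann, window = 51))
  for (p in c("1", "2")) {
    ps <- norm$strain_fitness[norm$strain_fitness$pool == as.integer(p), ]
    delta <- ps$fitness - states[[p]]$w[match(ps$strain_id,
                                              states[[p]]$strain_id)]
    expect_lt(diff(range(delta)), 1e-9)
  }
})

test_that("quality metrics behave on identical pools and operon structure", {
  strains <- data.frame(strain_id = sprintf("s%d", 1:5),
                        feature = "g", pool1 = TRUE, pool2 = TRUE,
                        stringsAsFactors = FALSE)
  fit <- rbind(
    data.frame(strain_id = strains$strain_id, pool = 1L,
               fitness = c(1, 2, 3, 4, 5), start_mean = 10, n_tags = 1L,
               included = TRUE, stringsAsFactors = FALSE),
    data.frame(strain_id = strains$strain_id, pool = 2L,
               fitness = c(1, 2, 3, 4, 5), start_mean = 10, n_tags = 1L,
               included = TRUE, stringsAsFactors = FALSE))
  ann <- tiny_annotation()
  gf <- data.frame(gene_id = ann$gene_id, fitness = c(1, 1.1, -2, -2.2, 0),
                   n_strains = 1L, intergenic = FALSE, stringsAsFactors = FALSE)
  q <- quality_metrics(fit, gf, strains, ann)
  expect_equal(q$strain_correlation, 1.0)
  expect_equal(q$n_shared, 5L)
  expect_equal(q$n_operon_pairs, 2L)      # (gA,gB) and (gC,gD)

  # fewer than 3 shared strains: undefined
  q2 <- quality_metrics(fit[fit$strain_id %in% c("s1", "s2"), ], gf,
                        strains, ann)
  expect_true(is.na(q2$strain_correlation))
})

test_that("per-operon effects raise operon correlation above the background", {
  cfg <- scenario_config(seed = 31, n_genes = 400)
  ann <- build_genome(cfg)
  set.seed(31)
  op_eff <- setNames(rnorm(length(unique(ann$operon_id)), 0, 1),
                     unique(ann$operon_id))
  gs_operon <- op_eff[ann$operon_id]
  gs_indep <- rnorm(nrow(ann), 0, 1)
  run_with <- function(gs) {
    lib <- build_barcoded_library(ann, 800, 800, 200, seed = 31)
    states <- list()
    for (p in c("1", "2")) {
      ps <- lib[lib[[paste0("pool", p)]], ]
      s <- ifelse(startsWith(ps$feature, "intergenic:"), 0,
                  unname(gs[match(sub(",.*$", "", ps$feature), ann$gene_id)]))
      s[is.na(s)] <- 0
      states[[p]] <- simulate_competition(ps, s, D = 1)
    }
    ints <- simulate_microarray(states, lib, sigma = 0.2, seed = 31)
    suppressMessages(barseq_pipeline(ints, lib, ann, window = 51))
  }
  q_op <- run_with(gs_operon)$quality
  q_ind <- run_with(gs_indep)$quality
  expect_gt(q_op$operon_correlation, 0.5)
  expect_gt(q_op$operon_correlation, q_ind$operon_correlation + 0.2)
  expect_lt(abs(q_ind$operon_correlation), 0.25)
})
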