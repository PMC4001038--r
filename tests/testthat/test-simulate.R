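test_that("synthetic genomes are sorted, non-overlapping and deterministic", {
  cfg <- scenario_config(seed = 3, n_genes = 2400)
  ann <- build_genome(cfg)
  expect_equal(nrow(ann), 2400)
  expect_true(all(diff(ann$start) > 0))
  expect_true(all(ann$start[-1L] > ann$end[-nrow(ann)]))  # exhaustive overlap check
  expect_true(all(ann$end <= chrom_lengths(ann)["chr1"]))
  ann2 <- build_genome(cfg)
  expect_identical(as.data.frame(ann), as.data.frame(ann2))
  # operon members are consecutive same-strand runs
  same_op <- ann$operon_id[-1L] == ann$operon_id[-nrow(ann)]
  expect_true(all(ann$strand[-1L][same_op] == ann$strand[-nrow(ann)][same_op]))
})

test_that("two-pool libraries respect size, overlap and tag uniqueness", {
  ann <- build_genome(scenario_config(seed = 4, n_genes = 60))
  lib <- build_barcoded_library(ann, 40, 40, 12, seed = 4)
  expect_equal(nrow(lib), 68)                   # 40 + 40 - 12 distinct
  expect_equal(sum(lib$pool1), 40)
  expect_equal(sum(lib$pool2), 40)
  expect_equal(sum(lib$pool1 & lib$pool2), 12)
  expect_false(anyDuplicated(lib$uptag_id[lib$pool1]) > 0)
  expect_false(anyDuplicated(lib$downtag_id[lib$pool2]) > 0)

  disjoint <- build_barcoded_library(ann, 30, 30, 0, seed = 4)
  expect_equal(sum(disjoint$pool1 & disjoint$pool2), 0)
  expect_error(build_barcoded_library(ann, 10, 40, 12, seed = 4), "overlap")
})

test_that("library accounting reproduces the two-pool arithmetic at scale", {
  ann <- build_genome(scenario_config(seed = 6, n_genes = 2400))
  lib <- build_barcoded_library(ann, 4069, 4056, 1174, seed = 6)
  expect_equal(nrow(lib), 6951)
  expect_equal(sum(lib$pool1), 4069)
  expect_equal(sum(lib$pool2), 4056)
})

test_that("competition matches the closed-form abundance oracle", {
  strains <- data.frame(strain_id = c("a", "b"), start_weight = 1)
  st <- simulate_competition(strains, s = c(0, 1), D = 3)
  expect_equal(st$x_end, c(8, 64) / 72, tolerance = 1e-12)
  expect_equal(st$w, c(log2(2 / 9), log2(16 / 9)), tolerance = 1e-12)

  # neutrality limits: D = 0, or all s equal
  neutral <- simulate_competition(strains, s = c(2, 2), D = 3.3)
  expect_equal(neutral$w, c(0, 0))
  frozen <- simulate_competition(strains, s = c(0, 5), D = 0)
  expect_equal(frozen$w, c(0, 0))
  expect_error(simulate_competition(strains, s = 0, D = 3,
                                    x_start = c(0, 1)), "positive")
})

test_that("abundances conserve mass and fitness matches an independent recomputation", {
  set.seed(10)
  n <- 500
  strains <- data.frame(strain_id = sprintf("s%03d", 1:n),
                        start_weight = runif(n, 0.5, 2))
  s <- rnorm(n, 0, 0.5)
  st <- simulate_competition(strains, s, D = 3.3)
  expect_lt(abs(sum(st$x_start) - 1), 1e-12)
  expect_lt(abs(sum(st$x_end) - 1), 1e-12)
  expect_equal(st$w, log2(st$x_end / st$x_start), tolerance = 1e-12)
})

test_that("a handful of strongly selected strains dominates the culture", {
  n <- 4000
  strains <- data.frame(strain_id = sprintf("s%04d", 1:n), start_weight = 1)
  s <- rep(0, n); s[1:10] <- 3
  st <- simulate_competition(strains, s, D = 3.3)
  expect_gt(sum(st$x_end[1:10]), 0.5)
})

test_that("microarray read-out is exact at zero noise and calibrated otherwise", {
  ann <- build_genome(scenario_config(seed = 8, n_genes = 200))
  lib <- build_barcoded_library(ann, 1000, 1000, 200, seed = 8, rate_sd = 0.5)
  states <- lapply(c("1", "2"), function(p) {
    ps <- lib[lib[[paste0("pool", p)]], ]
    simulate_competition(ps, ps$true_rate - 1, D = 3.3)
  })
  names(states) <- c("1", "2")
  noise_free <- simulate_microarray(states, lib, sigma = 0, scale = 1e6,
                                    background = 0, seed = 8)
  fit <- suppressMessages(strain_fitness(noise_free, lib))
  for (p in 1:2) {
    ps <- fit[fit$pool == p, ]
    expect_equal(ps$fitness,
                 states[[as.character(p)]]$w[match(ps$strain_id,
                                                   states[[as.character(p)]]$strain_id)],
                 tolerance = 1e-9)
  }
  expect_identical(simulate_microarray(states, lib, sigma = 0.3, seed = 8),
                   simulate_microarray(states, lib, sigma = 0.3, seed = 8))

  # END - START noise of a neutral pool has sd ~ sqrt(2) * sigma
  flat <- lapply(states, function(st) {
    st$x_end <- st$x_start
    st$w <- rep(0, length(st$w))
    st
  })
  noisy <- simulate_microarray(flat, lib, sigma = 0.3, scale = 1e6,
                               background = 0, seed = 9)
  nf <- suppressMessages(strain_fitness(noisy, lib))
  expect_lt(abs(sd(nf$fitness) - sqrt(2) * 0.3) / (sqrt(2) * 0.3), 0.1)
})

test_that("insertion libraries are deterministic with selection-driven read shares", {
  ann <- build_genome(scenario_config(seed = 12, n_genes = 100))
  gs <- setNames(rep(0, nrow(ann)), ann$gene_id)
  gs[50] <- 3
  ins <- simulate_tnle(ann, gs, D = 3.3, n_sites = 20000, total_reads = 2e5,
                       seed = 12)
  expect_identical(ins, simulate_tnle(ann, gs, D = 3.3, n_sites = 20000,
                                      total_reads = 2e5, seed = 12))
  expect_equal(sum(ins$reads), 2e5)
  expect_true(all(ins$reads >= 1))
  expect_false(anyDuplicated(ins[, c("chrom", "position")]) > 0)
  # the selected gene's read share far exceeds its site share
  feat <- map_position(ann, ins$chrom, ins$position)
  hit <- feat == ann$gene_id[50]
  read_share <- sum(ins$reads[hit]) / sum(ins$reads)
  site_share <- mean(hit)
  expect_gt(read_share, 10 * site_share)
})
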