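test_that("median-of-ratios size factors match hand computation and DESeq2", {
  m <- matrix(c(10, 20, 30, 40,
                10, 20, 30, 40), ncol = 2,
              dimnames = list(paste0("g", 1:4), c("a", "b")))
  expect_equal(unname(size_factors(m)), c(1, 1))

  # one column exactly 2x the other: by-hand median-of-ratios gives
  # factors sqrt(1/2) and sqrt(2) (reference = geometric mean)
  m2 <- cbind(a = c(10, 20, 30, 40), b = c(20, 40, 60, 80))
  rownames(m2) <- paste0("g", 1:4)
  sf <- size_factors(m2)
  expect_equal(unname(sf), c(sqrt(1 / 2), sqrt(2)))
  expect_equal(sf[["b"]] / sf[["a"]], 2)

  # invariant to gene reordering
  perm <- c(3, 1, 4, 2)
  expect_equal(size_factors(m2[perm, ]), sf)

  # independent cross-check on realistic counts
  g <- gen_counts(sim_config(seed = 2, n_genes = 500))
  expect_equal(unname(size_factors(g$total_counts)),
               unname(DESeq2::estimateSizeFactorsForMatrix(g$total_counts)),
               tolerance = 1e-9)

  expect_error(size_factors(diag(4)), "normalization error")
})

test_that("log2 fold changes recover planted mean shifts", {
  samples <- data.frame(sample = c("c1", "c2", "m1", "m2"),
                        condition = c("control", "control",
                                      "mutant1", "mutant1"))
  m <- matrix(1000L, nrow = 6, ncol = 4,
              dimnames = list(paste0("g", 1:6), samples$sample))
  expect_equal(unname(log2fc(m, samples, "mutant1")), rep(0, 6))

  # planted 4x shift on one high-count gene
  m2 <- m
  m2["g3", c("m1", "m2")] <- 4000L
  # disable normalisation (sf = 1) to isolate the estimator
  l <- log2fc(m2, samples, "mutant1", sf = rep(1, 4))
  expect_equal(unname(l[["g3"]]), 2, tolerance = 0.1)

  # all-zero gene: pseudocount cancels
  m3 <- m
  m3["g5", ] <- 0L
  expect_equal(unname(log2fc(m3, samples, "mutant1", sf = rep(1, 4))[["g5"]]), 0)

  expect_error(log2fc(m, samples, "mutant7"), "input error")
})

test_that("residual calls reproduce the closed-form normal tail under the null", {
  # perfectly collinear fold changes: degenerate residual SD, no calls
  fc0 <- data.frame(gene = paste0("g", 1:100),
                    lfc_total = seq(-2, 2, length.out = 100))
  fc0$lfc_dsrna <- 0.3 + 1.2 * fc0$lfc_total
  calls0 <- residual_calls(fc0)
  expect_true(all(calls0$call == "none"))

  # Gaussian null: flagged fraction ~ 2*(1 - Phi(2.5))
  set.seed(71)
  n <- 10000
  fc <- data.frame(gene = paste0("g", seq_len(n)),
                   lfc_total = rnorm(n, 0, 1))
  fc$lfc_dsrna <- 0.1 + 0.9 * fc$lfc_total + rnorm(n, 0, 0.25)
  calls <- residual_calls(fc, z_threshold = 2.5)
  p0 <- 2 * (1 - pnorm(2.5))
  flagged <- mean(calls$call != "none")
  expect_lt(abs(flagged - p0), 3 * sqrt(p0 * (1 - p0) / n))

  # OLS identity: residuals sum to ~0
  expect_lt(abs(sum(calls$residual)), 1e-8 * n)

  # calls invariant to gene order
  perm <- sample(n)
  calls_p <- residual_calls(fc[perm, ], z_threshold = 2.5)
  expect_identical(calls_p$call[order(calls_p$gene)],
                   calls$call[order(calls$gene)])

  # planted +2 shift on 1% of genes, residual SD 0.2: nearly all called
  set.seed(72)
  fc2 <- data.frame(gene = paste0("g", seq_len(n)),
                    lfc_total = rnorm(n, 0, 1))
  fc2$lfc_dsrna <- fc2$lfc_total + rnorm(n, 0, 0.2)
  planted <- sample(fc2$gene, n / 100)
  fc2$lfc_dsrna[fc2$gene %in% planted] <-
    fc2$lfc_dsrna[fc2$gene %in% planted] + 2
  calls2 <- residual_calls(fc2)
  hit <- calls2$gene[calls2$call == "enriched"]
  expect_gte(mean(planted %in% hit), 0.95)

  expect_error(residual_calls(fc0[1:2, ]), "input error")
  fc_const <- data.frame(gene = c("a", "b", "c"), lfc_total = c(1, 1, 1),
                         lfc_dsrna = c(1, 2, 3))
  expect_error(residual_calls(fc_const), "regression error")
})

test_that("consistency intersection partitions call sets", {
  mk <- function(genes, enr) {
    data.frame(gene = genes,
               call = ifelse(genes %in% enr, "enriched", "none"))
  }
  genes <- paste0("g", 1:20)
  a <- mk(genes, c("g1", "g2", "g3"))
  same <- consistent_calls(a, a)
  expect_identical(same$enriched$shared, c("g1", "g2", "g3"))
  expect_identical(unname(same$enriched$counts[c("m1_only", "m2_only")]),
                   c(0L, 0L))

  b <- mk(genes, c("g4", "g5"))
  disj <- consistent_calls(a, b)
  expect_identical(length(disj$enriched$shared), 0L)
  expect_identical(disj$enriched$counts[["m1_only"]], 3L)
  expect_identical(disj$enriched$counts[["m2_only"]], 2L)

  expect_error(consistent_calls(a, mk(paste0("h", 1:20), "h1")),
               "input error")
})

test_that("null generator calibration and planted recovery across the pipeline", {
  # type-I control: pooled flag rate over several null seeds within
  # Monte-Carlo error of the 2*(1-Phi(2.5)) tail
  p0 <- 2 * (1 - pnorm(2.5))
  n_genes <- 4000
  seeds <- 1:5
  flagged <- vapply(seeds, function(s) {
    g <- gen_counts(sim_config(seed = s, n_genes = n_genes,
                               frac_enriched = 0, frac_depleted = 0))
    e <- dsrna_enrichment(g$total_counts, g$dsrna_counts, g$samples)
    expect_identical(length(g$truth$enriched_ids), 0L)
    mean(e$calls$mutant1$call != "none")
  }, numeric(1))
  n_tot <- n_genes * length(seeds)
  expect_lt(abs(mean(flagged) - p0), 3 * sqrt(p0 * (1 - p0) / n_tot))

  # planted genes are recovered and consistent across mutants
  g <- gen_counts(sim_config(seed = 11, n_genes = 10000))
  e <- dsrna_enrichment(g$total_counts, g$dsrna_counts, g$samples,
                        gc = g$gene_gc)
  planted <- c(g$truth$enriched_ids, g$truth$depleted_ids)
  shared <- c(e$venn$enriched$shared, e$venn$depleted$shared)
  expect_gte(mean(planted %in% shared), 0.9)
  expect_gte(mean(g$truth$enriched_ids %in% e$venn$enriched$shared), 0.9)

  # replicate relabeling within a condition leaves calls unchanged
  g2 <- g
  swap <- c("total_control_2", "total_control_1")
  cols <- colnames(g2$total_counts)
  cols[match(c("total_control_1", "total_control_2"), cols)] <- swap
  colnames(g2$total_counts) <- cols
  e2 <- dsrna_enrichment(g2$total_counts, g2$dsrna_counts, g2$samples)
  expect_identical(e2$calls$mutant1$call, e$calls$mutant1$call)

  # power is monotone nondecreasing in the planted shift
  sens <- vapply(c(1, 2, 3), function(shift) {
    gs <- gen_counts(sim_config(seed = 13, n_genes = 3000,
                                enrichment_lfc_shift = shift))
    es <- dsrna_enrichment(gs$total_counts, gs$dsrna_counts, gs$samples)
    hits <- es$calls$mutant1$gene[es$calls$mutant1$call == "enriched"]
    mean(gs$truth$enriched_ids %in% hits)
  }, numeric(1))
  expect_true(all(diff(sens) >= 0))
})

test_that("G/C composition test separates planted sets from the background", {
  expect_equal(unname(gc_proportion(c(a = "GGCC", b = "AATT"))), c(1, 0))
  expect_equal(unname(gc_proportion(c(x = "GATC"))), 0.5)

  # planted sets sit at gc_high, background at gc_low
  set.seed(81)
  all_genes <- paste0("g", 1:1100)
  gc <- setNames(c(rbeta(100, 0.6 * 150, 0.4 * 150),
                   rbeta(1000, 0.4 * 150, 0.6 * 150)), all_genes)
  enriched <- all_genes[1:100]
  expect_warning(res <- gc_test(enriched, character(0), all_genes, gc),
                 "empty depleted set")
  row <- res[res$set == "enriched", ]
  expect_lt(row$p_value, 0.001)
  expect_gt(row$median_gc, row$median_gc_all)

  # a set compared against a universe with the same distribution: no signal
  null_set <- sample(all_genes[101:1100], 50)
  res0 <- suppressWarnings(gc_test(null_set, character(0),
                                   all_genes[101:1100], gc))
  expect_gt(res0$p_value[res0$set == "enriched"], 0.01)

  expect_error(gc_test("gX", character(0), c(all_genes, "gX"), gc),
               "input error")
})

test_that("count generator is deterministic and negative-binomial", {
  a <- gen_counts(sim_config(seed = 4, n_genes = 300))
  b <- gen_counts(sim_config(seed = 4, n_genes = 300))
  expect_identical(a$total_counts, b$total_counts)
  expect_identical(a$dsrna_counts, b$dsrna_counts)

  expect_error(gen_counts(sim_config(seed = 1, n_reps = 1)),
               "configuration error")

  g0 <- gen_counts(sim_config(seed = 5, n_genes = 200, frac_enriched = 0,
                              frac_depleted = 0))
  expect_identical(g0$truth$enriched_ids, character(0))
  expect_identical(g0$truth$depleted_ids, character(0))

  # moment check of the dispersion: over 1,000 genes, pooled moment
  # estimator of phi from depth-corrected control replicates
  cfg <- sim_config(seed = 6, n_genes = 1000, n_reps = 6,
                    frac_enriched = 0, frac_depleted = 0)
  g <- gen_counts(cfg)
  ctrl <- g$samples$sample[g$samples$assay == "total" &
                            g$samples$condition == "control"]
  norm <- sweep(g$total_counts[, ctrl], 2, g$truth$depth[ctrl], "/")
  mu <- rowMeans(norm)
  v <- apply(norm, 1, var)
  phi_hat <- sum(v - mu) / sum(mu^2)
  expect_equal(phi_hat, cfg$nb_dispersion, tolerance = 0.25)

  # written matrices round-trip through the TSV reader
  dir <- withr::local_tempdir()
  gw <- gen_counts(sim_config(seed = 7, n_genes = 100), dir = dir)
  expect_identical(read_counts(file.path(dir, "total_counts.tsv")),
                   gw$total_counts)
  sheet <- read.delim(file.path(dir, "samples.tsv"))
  expect_identical(sheet$sample, gw$samples$sample)
})
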