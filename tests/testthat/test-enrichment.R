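test_that("igg_filter computes mean-ratio fold changes with a kept boundary", {
  des <- toy_design()
  m <- toy_matrix(c("HIGH", "EDGE", "LOW", "BRG1"), des, value = 1)
  m["HIGH", !des$is_control & des$ip_target == "BRG1"] <- 3.0
  m["EDGE", !des$is_control & des$ip_target == "BRG1"] <- 1.5
  m["LOW", !des$is_control & des$ip_target == "BRG1"] <- 1.49
  res <- igg_filter(m, des, c("BRG1", "MLS"), igg_fc_min = 1.5)
  expect_equal(unname(res$fold_change["HIGH"]), 3.0)
  expect_true("HIGH" %in% res$retained)
  expect_true("EDGE" %in% res$retained)   # rule removes strictly < 1.5
  expect_false("LOW" %in% res$retained)
  expect_error(igg_filter(m, des, c("BRG1", "EWS")), "IgG")
})

test_that("igg_filter retained set equals an independent recount", {
  sim <- small_sim(seed = 13, n_proteins = 400)
  imp <- impute_lowest_detected(sim$matrix)
  res <- igg_filter(imp, sim$design, c("DDIT3", "MLS"))
  ip_cols <- grep("^DDIT3_MLS", colnames(imp))
  igg_cols <- grep("^IgG_MLS", colnames(imp))
  oracle <- rownames(imp)[vapply(seq_len(nrow(imp)), function(i) {
    mean(imp[i, ip_cols]) / mean(imp[i, igg_cols]) >= 1.5
  }, logical(1))]
  expect_setequal(res$retained, oracle)
})

test_that("intersection keeps shared proteins and rejects empty results", {
  expect_setequal(intersect_for_comparison(c("A", "B", "C"), c("B", "C", "D")),
                  c("B", "C"))
  expect_setequal(intersect_for_comparison(c("A", "B"), c("A", "B")),
                  c("A", "B"))
  expect_error(intersect_for_comparison("A", "B"), "empty intersection")
})

test_that("bait normalization divides each column by its bait abundance", {
  des <- toy_design()
  m <- toy_matrix(c("BRG1", "X2", "Y"), des, value = 1)
  bait_cols <- des$sample_id[!des$is_control]
  m["BRG1", bait_cols] <- c(2, 4, 8, 2, 4, 8)
  m["X2", bait_cols] <- 2 * m["BRG1", bait_cols]
  m["Y", bait_cols] <- rlnorm(6)
  norm <- bait_normalize(m, des, "BRG1")
  expect_equal(unname(norm["BRG1", bait_cols]), rep(1, 6))
  expect_equal(unname(norm["X2", bait_cols]), rep(2, 6))
  # element-wise oracle division
  expect_equal(norm["Y", bait_cols],
               m["Y", bait_cols] / m["BRG1", bait_cols])
  # IgG columns untouched
  expect_equal(norm["Y", des$sample_id[des$is_control]],
               m["Y", des$sample_id[des$is_control]])
  expect_equal(attr(norm, "provenance"), "normalized")
  # zero bait abundance names the offending replicate
  m["BRG1", "DDIT3_MLS_r2"] <- 0
  expect_error(bait_normalize(m, des, "BRG1"), "DDIT3_MLS_r2")
  expect_error(bait_normalize(m, des, "NOSUCH"), "not found")
})

test_that("bait normalization resolves the bait through catalog aliases", {
  des <- toy_design()
  m <- toy_matrix(c("SMARCA4", "OTHER"), des, value = 4)
  norm <- bait_normalize(m, des, "BRG1", catalog = load_catalog())
  expect_equal(unname(norm["SMARCA4", des$sample_id[!des$is_control]]),
               rep(1, 6))
})

test_that("differential enrichment: fold change, symmetry, degeneracy", {
  a <- matrix(c(1.0, 1.2, 1.4), 1, dimnames = list("P", NULL))
  b <- matrix(c(0.5, 0.6, 0.7), 1, dimnames = list("P", NULL))
  tab <- differential_enrichment(a, b)
  expect_equal(tab$fold_change, 2.0)
  # swapping sides inverts the fold change and preserves the p-value
  rev_tab <- differential_enrichment(b, a)
  expect_equal(rev_tab$fold_change, 1 / tab$fold_change)
  expect_equal(rev_tab$p_value, tab$p_value)
  # zero variance both sides, equal means: degenerate, p = 1
  cst <- matrix(1, 1, 3, dimnames = list("P", NULL))
  deg <- differential_enrichment(cst, cst)
  expect_true(deg$degenerate)
  expect_equal(deg$p_value, 1)
  expect_equal(deg$significant_in, factor("none", levels = c("a", "b", "none")))
  # zero mean denominator: flagged, excluded from FC
  z <- matrix(0, 1, 3, dimnames = list("P", NULL))
  nz <- matrix(c(1, 1.1, 0.9), 1, dimnames = list("P", NULL))
  zz <- differential_enrichment(nz, z)
  expect_true(is.na(zz$fold_change))
  expect_error(differential_enrichment(a, matrix(1, 2, 3)), "row names")
})

test_that("antisymmetry holds across a full simulated comparison", {
  sim <- small_sim(seed = 19, n_proteins = 300)
  tab <- run_comparison(sim)
  imp <- impute_lowest_detected(sim$matrix)
  norm <- bait_normalize(imp, sim$design, "BRG1")
  cols_a <- grep("^DDIT3_MLS", colnames(norm), value = TRUE)
  cols_b <- grep("^BRG1_MLS", colnames(norm), value = TRUE)
  swapped <- differential_enrichment(norm[tab$protein, cols_b],
                                     norm[tab$protein, cols_a])
  expect_equal(swapped$fold_change, 1 / tab$fold_change)
  expect_equal(swapped$p_value, tab$p_value, tolerance = 1e-12)
  expect_equal(as.character(swapped$significant_in)[tab$significant_in == "a"],
               rep("b", sum(tab$significant_in == "a")))
})

test_that("Welch p-values match the t.test oracle to 1e-12", {
  set.seed(23)
  for (rep in 1:50) {
    na <- sample(2:6, 1); nb <- sample(2:6, 1)
    a <- matrix(rlnorm(5 * na), 5, na,
                dimnames = list(paste0("P", 1:5), NULL))
    b <- matrix(rlnorm(5 * nb), 5, nb,
                dimnames = list(paste0("P", 1:5), NULL))
    tab <- differential_enrichment(a, b)
    for (i in 1:5) {
      expect_equal(tab$p_value[i], oracle_welch_p(a[i, ], b[i, ]),
                   tolerance = 1e-12)
    }
  }
})

test_that("BH adjustment equals the brute-force step-up", {
  set.seed(29)
  for (m in c(1, 10, 500, 5000)) {
    p <- runif(m)^2
    expect_equal(stats::p.adjust(p, "BH"), oracle_bh(p), tolerance = 1e-12)
  }
  # and through the enrichment table itself
  sim <- small_sim(seed = 37, n_proteins = 200)
  tab <- run_comparison(sim)
  expect_equal(tab$fdr, oracle_bh(tab$p_value), tolerance = 1e-12)
  expect_true(all(tab$fdr >= tab$p_value - 1e-15))
})

test_that("significance respects thresholds and is monotone in fc_min", {
  sim <- small_sim(seed = 41, n_proteins = 300)
  prev <- c(a = Inf, b = Inf)
  for (fc_min in c(1.1, 1.2, 1.5, 2.0)) {
    tab <- run_comparison(sim, thresholds = ip_thresholds(
      comparison_fc_min = fc_min))
    cnt <- significant_counts(tab, bait = "BRG1")
    expect_lte(cnt["a"], prev["a"])
    expect_lte(cnt["b"], prev["b"])
    prev <- cnt
    # calls consistent with the rule
    sig_a <- tab$significant_in == "a"
    expect_true(all(tab$fold_change[sig_a] > fc_min))
    expect_true(all(tab$p_value[sig_a] < 0.05))
  }
  # empty table edge: no significant proteins
  null_tab <- differential_enrichment(
    matrix(1 + rnorm(6, sd = 1e-4), 2, 3, dimnames = list(c("A", "B"), NULL)),
    matrix(1 + rnorm(6, sd = 1e-4), 2, 3, dimnames = list(c("A", "B"), NULL)),
    thresholds = ip_thresholds(comparison_fc_min = 10))
  expect_equal(unname(significant_counts(null_tab)), c(0L, 0L))
})

test_that("chain is never anticonservative under the between-IP null", {
  # all classes at equal capture in both IPs: true fold change 1 everywhere
  rates <- vapply(1:10, function(s) {
    sim <- simulate_ip_experiment(ip_sim_config(
      n_proteins = 400, baits = list(c("BRG1", "MLS"), c("DDIT3", "MLS")),
      fraction_interactor = 1, fraction_igg_only = 0, seed = 100 + s))
    tab <- run_comparison(sim)
    null_prot <- sim$truth$protein[sim$truth$class == "interactor"]
    p <- tab$p_value[tab$protein %in% null_prot]
    mean(p < 0.05)
  }, numeric(1))
  n_total <- 10 * 370  # approximate pooled test count
  expect_lt(mean(rates), 0.05 + 2 * sqrt(0.05 * 0.95 / n_total))
  expect_gt(mean(rates), 0.01)  # test is live, not degenerate
})

test_that("planted class enrichment is recovered by mean fold change", {
  fcs <- vapply(1:5, function(s) {
    sim <- simulate_ip_experiment(ip_sim_config(
      n_proteins = 800, seed = 200 + s,
      planted_enrichment = list(
        list(class = "gbaf_specific", ip = "DDIT3:MLS", factor = 2.0))))
    tab <- run_comparison(sim)
    gbaf <- sim$truth$protein[sim$truth$class == "gbaf_specific"]
    mean(tab$fold_change[tab$protein %in% gbaf])
  }, numeric(1))
  expect_lt(abs(mean(fcs) - 2.0) / 2.0, 0.15)
})
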