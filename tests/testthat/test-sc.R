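sc_fixture <- function() {
  # 4 genes x 6 cells; ACTB everywhere, BRD9 in half, core gene BAF155 in 5
  m <- rbind(ACTB = c(5L, 2L, 1L, 3L, 1L, 4L),
             SMARCC1 = c(1L, 1L, 0L, 2L, 1L, 1L),
             BRD9 = c(1L, 0L, 1L, 0L, 1L, 0L),
             PBRM1 = c(0L, 0L, 0L, 0L, 0L, 1L))
  colnames(m) <- paste0("c", 1:6)
  m
}

test_that("positive_fraction counts detection and reports absent genes", {
  m <- sc_fixture()
  res <- positive_fraction(m, c("ACTB", "BRD9", "NOSUCH"))
  expect_equal(unname(res$fractions["ACTB"]), 1.0)
  expect_equal(unname(res$fractions["BRD9"]), 0.5)
  expect_equal(res$not_found, "NOSUCH")
  expect_error(positive_fraction(m[, 0]), "zero cells")
  # simulated marginal converges to the detection probability
  sim <- simulate_sc_counts(10000, c(g = 0.4), seed = 2)
  f <- positive_fraction(sim, "g")$fractions[["g"]]
  expect_lt(abs(f - 0.4), 4 * sqrt(0.4 * 0.6 / 10000))
})

test_that("subtype calls follow the >=1 specific component rule", {
  m <- sc_fixture()
  res <- call_subtypes(m, load_catalog(), require_core = TRUE)
  calls <- res$calls
  # cell c3 has BRD9 but no core component: excluded when core required
  expect_false(calls$evaluated[calls$cell == "c3"])
  expect_true(all(calls$evaluated[calls$core_positive]))
  # gbaf from BRD9, pbaf from PBRM1, no cbaf genes present
  c1 <- calls[calls$cell == "c1", ]
  expect_true(c1$gbaf); expect_false(c1$pbaf); expect_false(c1$cbaf)
  c2 <- calls[calls$cell == "c2", ]
  expect_equal(c2$n_subtypes, 0L)  # the "no detected subtype" bucket
  expect_equal(sum(res$summary$n_subtype_distribution), 1.0)
  # monotone: requiring core never increases evaluated subtype fractions' n
  res_all <- call_subtypes(m, load_catalog(), require_core = FALSE)
  expect_gte(res_all$summary$n_cells_evaluated,
             res$summary$n_cells_evaluated)
  expect_error(call_subtypes(m[c("ACTB", "SMARCC1"), ], load_catalog()),
               "no subtype-specific")
})

test_that("subtype fractions recover planted detection probabilities", {
  probs <- c(SMARCC1 = 0.6, BRD9 = 0.3, PBRM1 = 0.5, ARID1A = 0.25)
  m <- simulate_sc_counts(8000, probs, seed = 21)
  res <- call_subtypes(m, load_catalog(), require_core = FALSE)
  se <- function(p) 4 * sqrt(p * (1 - p) / 8000)
  expect_lt(abs(res$summary$subtype_fractions[["gbaf"]] - 0.3), se(0.3))
  expect_lt(abs(res$summary$subtype_fractions[["pbaf"]] - 0.5), se(0.5))
  expect_lt(abs(res$summary$subtype_fractions[["cbaf"]] - 0.25), se(0.25))
})

test_that("binarization idempotence: counts and flags give identical results", {
  m <- simulate_sc_counts(500, c(a = 0.4, b = 0.3, BRD9 = 0.5,
                                 SMARCC1 = 0.6), seed = 31)
  bin <- (m >= 1) + 0L
  dimnames(bin) <- dimnames(m)
  expect_equal(positive_fraction(m)$fractions,
               positive_fraction(bin)$fractions)
  expect_equal(call_subtypes(m, load_catalog(), require_core = FALSE)$summary,
               call_subtypes(bin, load_catalog(),
                             require_core = FALSE)$summary)
  r1 <- coexpression_independence(m, "a", "b")
  r2 <- coexpression_independence(bin, "a", "b")
  expect_equal(r1$p_value, r2$p_value)
  expect_equal(r1$ratio, r2$ratio)
})

test_that("coexpression: saturated gene forces ratio 1; errors on absent gene", {
  m <- sc_fixture()
  res <- coexpression_independence(m, "ACTB", "BRD9")
  expect_equal(res$ratio, 1.0)
  expect_equal(res$observed, res$expected)
  expect_error(coexpression_independence(m, "ACTB", "NOSUCH"), "absent")
})

test_that("Fisher p-values match the hypergeometric oracle on small tables", {
  # enumerate 2x2 tables over modest totals; realize each as binary vectors
  for (n in c(4, 9, 16, 25)) {
    for (a in 0:min(n, 6)) for (b in 0:min(n - a, 6)) {
      for (cc in 0:min(n - a - b, 6)) {
        d <- n - a - b - cc
        xi <- rep(c(1L, 1L, 0L, 0L), c(a, b, cc, d))
        xj <- rep(c(1L, 0L, 1L, 0L), c(a, b, cc, d))
        m <- rbind(gi = xi, gj = xj)
        colnames(m) <- paste0("c", seq_len(n))
        got <- coexpression_independence(m, "gi", "gj")$p_value
        want <- oracle_fisher_2x2(a, b, cc, d)
        expect_equal(got, want, tolerance = 1e-9)
      }
    }
  }
})

test_that("independent genes give calibrated dependency ratios", {
  ratios <- vapply(1:20, function(s) {
    m <- simulate_sc_counts(4000, c(a = 0.5, b = 0.5), seed = 400 + s)
    coexpression_independence(m, "a", "b")$ratio
  }, numeric(1))
  expect_lt(abs(mean(ratios) - 1), 0.02)
})

test_that("planted dependency is detected by both test routes", {
  dep <- list(gene_i = "a", gene_j = "b", odds_multiplier = 4)
  m <- simulate_sc_counts(3000, c(a = 0.3, b = 0.3), dependency = dep,
                          seed = 55)
  fish <- coexpression_independence(m, "a", "b")
  perm <- coexpression_independence(m, "a", "b", method = "permutation",
                                    n_perm = 500, seed = 1)
  expect_lt(fish$p_value, 0.01)
  expect_lt(perm$p_value, 0.01)
  expect_gt(fish$ratio, 1.5)
})

test_that("permutation p-values are uniform under independence", {
  pvals <- vapply(1:150, function(s) {
    m <- simulate_sc_counts(300, c(a = 0.4, b = 0.4), seed = 500 + s)
    coexpression_independence(m, "a", "b", method = "permutation",
                              n_perm = 199, seed = s)$p_value
  }, numeric(1))
  ks <- suppressWarnings(stats::ks.test(pvals, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("components per cell and Poisson-binomial band fractions agree", {
  m <- sc_fixture()
  res <- components_per_cell(m, load_catalog())
  # ACTB, SMARCC1, BRD9, PBRM1 are all catalog genes (via aliases)
  expect_equal(unname(res$counts["c1"]), 3)
  expect_equal(unname(res$counts["c6"]), 3)
  all_pos <- matrix(1L, 2, 3, dimnames = list(c("BRD9", "PBRM1"),
                                              paste0("c", 1:3)))
  expect_equal(unname(components_per_cell(all_pos, load_catalog())$counts),
               rep(2, 3))
  # planted probabilities: band fraction matches the exact Poisson-binomial
  probs <- c(SMARCC1 = 0.5, SMARCC2 = 0.4, BRD9 = 0.3, PBRM1 = 0.6,
             ARID1A = 0.35, SMARCA4 = 0.55)
  sim <- simulate_sc_counts(6000, probs, seed = 61)
  got <- components_per_cell(sim, load_catalog(), band = c(2, 4))
  pmf <- oracle_poisson_binomial(unname(probs))
  want <- sum(pmf[3:5])  # P(2 <= X <= 4), pmf index 1 is X = 0
  expect_lt(abs(got$band_fraction - want), 4 * sqrt(want * (1 - want) / 6000))
})

test_that("single-cell matrices round-trip through MatrixMarket and TSV", {
  m <- simulate_sc_counts(40, c(BRD9 = 0.5, SMARCC1 = 0.8, ACTB = 1.0),
                          seed = 71)
  dir <- withr::local_tempdir()
  write_sc_matrix(m, dir)
  re <- read_sc_matrix(file.path(dir, "matrix.mtx"),
                       file.path(dir, "genes.txt"),
                       file.path(dir, "cells.txt"))
  expect_equal(unname(re), unname(m))
  expect_identical(dimnames(re), dimnames(m))
  f <- withr::local_tempfile(fileext = ".tsv")
  df <- data.frame(gene = rownames(m), m, check.names = FALSE)
  write.table(df, f, sep = "\t", quote = FALSE, row.names = FALSE)
  re2 <- read_sc_matrix(f)
  expect_equal(unname(re2), unname(m))
})
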