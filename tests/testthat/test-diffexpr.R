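test_that("NB exact test agrees with the conditional split oracle", {
  set.seed(21)
  for (phi in c(0, 0.1, 0.5)) {
    for (rep in 1:30) {
      total <- sample(0:30, 1)
      sum_a <- sample(0:total, 1)
      n_a <- sample(1:3, 1); n_b <- sample(1:3, 1)
      expect_equal(
        nb_exact_test(sum_a, n_a, total - sum_a, n_b, phi),
        nb_exact_oracle(sum_a, n_a, total - sum_a, n_b, phi),
        tolerance = 1e-10,
        info = sprintf("phi=%g sum_a=%d total=%d n=(%d,%d)",
                       phi, sum_a, total, n_a, n_b)
      )
    }
  }
})

test_that("NB exact test reduces to the binomial test in the Poisson limit", {
  # phi = 0, one replicate each, total 4, observed (4, 0):
  # two-sided binomial(4, 1/2) tail = 2 * (1/16) = 0.125
  expect_equal(nb_exact_test(4, 1, 0, 1, 0), 0.125)
  # general binomial-tail agreement at phi = 0
  for (total in c(6, 11, 20)) {
    for (sum_a in c(0, 2, total)) {
      pk <- dbinom(0:total, total, 0.5)
      p_bin <- sum(pk[pk <= pk[sum_a + 1] * (1 + 1e-12)])
      expect_equal(nb_exact_test(sum_a, 1, total - sum_a, 1, 0), min(1, p_bin))
    }
  }
})

test_that("NB exact test: symmetric null gives p = 1 and group swap leaves p unchanged", {
  expect_equal(nb_exact_test(10, 2, 10, 2, 0.2), 1)
  expect_equal(nb_exact_test(0, 1, 0, 1, 0.5), 1)
  set.seed(5)
  for (i in 1:20) {
    sa <- sample(0:50, 1); sb <- sample(0:50, 1)
    na <- sample(1:3, 1); nb <- sample(1:3, 1)
    phi <- runif(1, 0, 0.5)
    expect_equal(nb_exact_test(sa, na, sb, nb, phi),
                 nb_exact_test(sb, nb, sa, na, phi), tolerance = 1e-12)
  }
})

test_that("p decreases monotonically as the split moves away from balance", {
  total <- 40
  p_seq <- vapply(20:40, function(sa)
    nb_exact_test(sa, 2, total - sa, 2, 0.1), numeric(1))
  expect_true(all(diff(p_seq) <= 1e-12))
})

test_that("NB exact test matches edgeR's small-p exact test", {
  skip_if_not_installed("edgeR")
  set.seed(31)
  n <- 40; mu <- runif(n, 5, 80)
  y1 <- matrix(rnbinom(2 * n, size = 5, mu = rep(mu, 2)), n, 2)
  y2 <- matrix(rnbinom(2 * n, size = 5, mu = rep(mu, 2)), n, 2)
  pe <- edgeR::exactTestBySmallP(y1, y2, dispersion = 0.2)
  po <- vapply(seq_len(n), function(i)
    nb_exact_test(sum(y1[i, ]), 2, sum(y2[i, ]), 2, 0.2), numeric(1))
  expect_equal(po, as.numeric(pe), tolerance = 1e-10)
})

test_that("null p-values are approximately uniform", {
  set.seed(99)
  n <- 2000
  mu <- exp(rnorm(n, log(200), 1))
  ya <- matrix(rnbinom(2 * n, size = 10, mu = rep(mu, 2)), n, 2)
  yb <- matrix(rnbinom(2 * n, size = 10, mu = rep(mu, 2)), n, 2)
  p <- vapply(seq_len(n), function(i)
    nb_exact_test(sum(ya[i, ]), 2, sum(yb[i, ]), 2, 0.1), numeric(1))
  ks <- suppressWarnings(stats::ks.test(p, "punif"))
  expect_lt(unname(ks$statistic), 0.05)
})

test_that("common dispersion recovers the simulation truth and floors at zero", {
  set.seed(11)
  n <- 2000
  mu <- exp(rnorm(n, log(150), 0.8))
  # NB truth phi = 0.2, 3 reps per group
  ya <- matrix(rnbinom(3 * n, size = 5, mu = rep(mu, 3)), n, 3)
  yb <- matrix(rnbinom(3 * n, size = 5, mu = rep(mu, 3)), n, 3)
  est <- estimate_common_dispersion(ya, yb)
  expect_gt(est$phi, 0.1); expect_lt(est$phi, 0.3)
  expect_identical(est$method, "qCML-common")
  # Poisson truth -> small phi
  ya0 <- matrix(rpois(3 * n, rep(mu, 3)), n, 3)
  yb0 <- matrix(rpois(3 * n, rep(mu, 3)), n, 3)
  expect_lt(estimate_common_dispersion(ya0, yb0)$phi, 0.05)
  # identical replicates within each gene -> floored at 0
  yc <- matrix(rep(c(5, 17, 40), each = 3), 3, 3, byrow = TRUE)
  expect_equal(estimate_common_dispersion(yc, yc)$phi, 0)
  expect_error(estimate_common_dispersion(yc * 0, yc * 0), "all-zero")
})

test_that("common dispersion is close to edgeR's qCML estimate", {
  skip_if_not_installed("edgeR")
  set.seed(13)
  n <- 500; mu <- runif(n, 20, 200)
  y1 <- matrix(rnbinom(2 * n, size = 5, mu = rep(mu, 2)), n, 2)
  y2 <- matrix(rnbinom(2 * n, size = 5, mu = rep(mu, 2)), n, 2)
  d <- edgeR::DGEList(counts = cbind(y1, y2), group = rep(1:2, each = 2))
  d <- edgeR::estimateCommonDisp(d)
  ours <- estimate_common_dispersion(y1, y2)$phi
  expect_equal(ours, d$common.dispersion, tolerance = 0.05)
})

test_that("BH adjustment matches the hand-applied step-up rule", {
  expect_equal(bh_adjust(0.03), 0.03)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  set.seed(3)
  for (i in 1:10) {
    p <- runif(sample(1:50, 1))
    adj <- bh_adjust(p)
    expect_equal(adj, bh_oracle(p), tolerance = 1e-12)
    expect_true(all(adj >= p))
    expect_true(all(adj <= 1))
  }
  expect_error(bh_adjust(c(0.5, 0)), "0, 1")
  expect_error(bh_adjust(c(0.5, 1.2)), "0, 1")
})

test_that("log2 fold change follows the pseudocount formula", {
  expect_equal(log2_fold_change(10, 40, pseudocount = 1e-12), 2,
               tolerance = 1e-9)
  expect_equal(log2_fold_change(7, 7), 0)
  expect_equal(log2_fold_change(0, 8, pseudocount = 1), log2(9))
  expect_error(log2_fold_change(1, 2, pseudocount = 0), "positive")
})

test_that("DEG calls apply strict thresholds", {
  rec <- data.frame(
    gene_id = c("a", "b", "c", "d"),
    log2fc = c(1.6, 1.5, -2.0, 3.0),
    p_adj = c(0.04, 0.001, 0.05, 0.01)
  )
  # a: passes both; b: |lfc| not strictly > 1.5; c: p not strictly < 0.05
  expect_identical(call_degs(rec), c("a", "d"))
  # independent filter oracle on random records
  set.seed(17)
  rr <- data.frame(gene_id = paste0("g", 1:200),
                   log2fc = rnorm(200, 0, 2),
                   p_adj = runif(200))
  oracle <- rr$gene_id[abs(rr$log2fc) > 1.5 & rr$p_adj < 0.05]
  expect_identical(call_degs(rr), oracle)
})

test_that("pairwise DE pipeline returns a coherent record table", {
  set.seed(23)
  sim <- generate_counts(sim_config(
    n_genes_per_mode = c(null = 300, additive = 100),
    dispersion = 0.05, seed = 23
  ))
  tab <- de_pairwise(sim$cm, "PC", "PB", library_sizes = sim$library_sizes)
  expect_true(all(tab$p_adj >= tab$p_raw))
  expect_true(all(tab$p_raw > 0 & tab$p_raw <= 1))
  expect_identical(tab$is_deg,
                   abs(tab$log2fc) > 1.5 & tab$p_adj < 0.05)
  # the planted parental fold (2x) is sub-threshold (log2 2 = 1 < 1.5),
  # so additive genes should rarely be DEGs while p-values still skew low
  expect_lt(mean(tab$is_deg), 0.05)
})

test_that("FDR is controlled near the nominal level under an all-null simulation", {
  # pooled over 20 seeds: fraction of genes with adjusted p < 0.05 stays
  # within a sanity band of the nominal rate
  called <- 0L; tested <- 0L
  for (seed in 1:20) {
    sim <- generate_counts(sim_config(n_genes_per_mode = c(null = 400),
                                      dispersion = 0.1, seed = seed))
    tab <- de_pairwise(sim$cm, "PC", "PB", library_sizes = sim$library_sizes)
    called <- called + sum(tab$p_adj < 0.05)
    tested <- tested + nrow(tab)
  }
  expect_lte(called / tested, 0.075)
})
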