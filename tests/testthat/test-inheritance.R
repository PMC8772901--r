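test_that("per-hybrid calls respect the inclusive 20% envelope boundary", {
  # exactly 1.2 x the larger parent is transgressive-up ("at least 20%")
  expect_identical(call_transgressive_per_hybrid(10, 20, 24), "up")
  # exactly 0.8 x the smaller parent is transgressive-down
  expect_identical(call_transgressive_per_hybrid(10, 20, 8), "down")
  # inside the envelope
  expect_identical(call_transgressive_per_hybrid(10, 20, 15), "none")
  # just inside the margins
  expect_identical(call_transgressive_per_hybrid(10, 20, 23.999), "none")
  expect_identical(call_transgressive_per_hybrid(10, 20, 8.001), "none")
  expect_error(call_transgressive_per_hybrid(1, 1, 1, margin = 1), "margin")
  expect_error(call_transgressive_per_hybrid(-1, 1, 1), "non-negative")
})

test_that("degenerate zero parents cannot be called down and need f1 > 0 for up", {
  expect_identical(call_transgressive_per_hybrid(0, 0, 0), "none")
  expect_identical(call_transgressive_per_hybrid(0, 0, 5), "up")
  # one zero parent: down would need f1 below 0, impossible
  expect_identical(call_transgressive_per_hybrid(0, 10, 0), "none")
  expect_identical(call_transgressive_per_hybrid(0, 10, 12), "up")
})

test_that("classification truth table is exact over the full 3 x 3 grid", {
  grid <- expand.grid(bc = c("up", "down", "none"),
                      cb = c("up", "down", "none"),
                      stringsAsFactors = FALSE)
  expected <- c(
    "up|up" = "concordant_up",
    "down|down" = "concordant_down",
    "up|down" = "discordant_II",
    "down|up" = "discordant_II",
    "up|none" = "discordant_I",
    "down|none" = "discordant_I",
    "none|up" = "discordant_I",
    "none|down" = "discordant_I",
    "none|none" = "non_transgressive"
  )
  got <- classify_gene(grid$bc, grid$cb)
  expect_identical(got, unname(expected[paste(grid$bc, grid$cb, sep = "|")]))
  expect_error(classify_gene("sideways", "up"), "up")
})

test_that("classify_all partitions the expressed universe and is order-invariant", {
  set.seed(41)
  tm <- matrix(runif(400, 0, 50), 100, 4,
               dimnames = list(paste0("g", 1:100), GENETIC_TYPES))
  genes <- rownames(tm)
  calls <- classify_all(tm, genes)
  expect_identical(calls$gene_id, genes)
  expect_true(all(calls$klass %in% c("concordant_up", "concordant_down",
                                     "discordant_I", "discordant_II",
                                     "non_transgressive")))
  # permuting gene order leaves per-gene calls unchanged
  perm <- sample(genes)
  calls2 <- classify_all(tm[perm, ], perm)
  m <- merge(calls, calls2, by = "gene_id")
  expect_identical(m$klass.x, m$klass.y)
  # equal means in all four types -> everything non-transgressive
  flat <- matrix(5, 10, 4, dimnames = list(paste0("f", 1:10), GENETIC_TYPES))
  expect_true(all(classify_all(flat, rownames(flat))$klass ==
                    "non_transgressive"))
  expect_error(classify_all(tm, character(0)), "empty")
  expect_error(classify_all(tm, "nope"), "absent")
})

test_that("calls are scale-invariant and symmetric in the parents", {
  set.seed(43)
  tm <- matrix(runif(200, 0, 30), 50, 4,
               dimnames = list(paste0("g", 1:50), GENETIC_TYPES))
  base <- classify_all(tm, rownames(tm))
  # common positive rescaling per gene
  sc <- tm * runif(50, 0.1, 10)
  expect_identical(classify_all(sc, rownames(sc))$klass, base$klass)
  # swapping PC and PB labels
  sw <- tm[, c("PB", "PC", "F1BC", "F1CB")]
  colnames(sw) <- GENETIC_TYPES
  expect_identical(classify_all(sw, rownames(sw))$klass, base$klass)
})

test_that("raising the margin only shrinks the transgressive set", {
  set.seed(47)
  tm <- matrix(runif(400, 0, 40), 100, 4,
               dimnames = list(paste0("g", 1:100), GENETIC_TYPES))
  prev <- classify_all(tm, rownames(tm), margin = 0)
  for (m in c(0.1, 0.2, 0.4, 0.8)) {
    cur <- classify_all(tm, rownames(tm), margin = m)
    was_none <- prev$klass == "non_transgressive"
    expect_true(all(cur$klass[was_none] == "non_transgressive"))
    prev <- cur
  }
})

test_that("class summary reproduces count-derived percentages", {
  s <- summarize_classes(list(concordant_up = 60, concordant_down = 925,
                              discordant_I = 106, discordant_II = 49),
                         universe_size = 13420)
  expect_equal(s$n_transgressive, 1140)
  expect_equal(s$pct_transgressive, 8.5)
  expect_equal(s$pct_concordant_down, 94)
  expect_equal(s$pct_discordant_II, 4.3)
  expect_lt(s$pct_discordant_I, 10)
  # empty calls: all zero
  empty <- summarize_classes(data.frame(klass = character(0)), 10)
  expect_equal(unname(empty$counts), rep(0, 5))
  expect_equal(empty$pct_transgressive, 0)
  expect_error(summarize_classes(list(concordant_up = 5), 0), "positive")
  expect_error(summarize_classes(list(concordant_up = 11), 10), "universe")
  # counts from a call table sum to the universe
  set.seed(53)
  tm <- matrix(runif(400, 0, 40), 100, 4,
               dimnames = list(paste0("g", 1:100), GENETIC_TYPES))
  calls <- classify_all(tm, rownames(tm))
  s2 <- summarize_classes(calls, 100)
  expect_equal(sum(s2$counts), 100)
})

test_that("hybrid overlap matches the Venn arithmetic", {
  conc <- data.frame(call_BC = rep("up", 4), call_CB = rep("up", 4))
  expect_equal(hybrid_overlap(conc)$shared_fraction, 1)
  d1 <- data.frame(call_BC = c("up", "none"), call_CB = c("none", "down"))
  expect_equal(hybrid_overlap(d1)$shared_fraction, 0)
  # printed-count composition: (985 + 49) / 1140
  calls <- data.frame(
    call_BC = c(rep("up", 60), rep("down", 925), rep("up", 106), rep("up", 49)),
    call_CB = c(rep("up", 60), rep("down", 925), rep("none", 106), rep("down", 49))
  )
  ov <- hybrid_overlap(calls)
  expect_equal(ov$shared_fraction, (985 + 49) / 1140)
  expect_gt(ov$shared_fraction, 0.9)
  expect_equal(ov$BC_only, 106)
  none <- data.frame(call_BC = "none", call_CB = "none")
  expect_error(hybrid_overlap(none), "undefined")
})
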