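test_that("spike-in factors follow the minimum-count rule and its invariances", {
  expect_equal(spike_in_factors(c(a = 100, b = 100))$factor, c(1, 1))
  f <- spike_in_factors(c(a = 100, b = 200))
  expect_equal(f$factor[f$sample == "b"], 0.5)
  expect_error(spike_in_factors(c(a = 0, b = 200)), "a",
               class = "chromakit_error")
  # scale invariance and exact equalization
  counts <- c(x = 123456, y = 77777, z = 990011)
  f1 <- spike_in_factors(counts)
  f2 <- spike_in_factors(counts * 7)
  expect_equal(f1$factor, f2$factor)
  expect_true(all(abs(f1$count * f1$factor - min(counts)) < 1e-9))
})

test_that("differential classification applies the 20 and 30 percent thresholds", {
  expect_equal(as.character(classify_differential(10, 13, "histone")), "up")
  expect_equal(as.character(classify_differential(10, 11, "histone")), "stable")
  expect_equal(as.character(classify_differential(10, 12.5, "tf")), "stable")
  expect_equal(as.character(classify_differential(10, 14, "tf")), "up")
  expect_error(classify_differential(10, 12, "atac"), class = "chromakit_error")
  expect_error(classify_differential(-1, 2, "histone"), class = "chromakit_error")
  # antisymmetry with a zero pseudocount: an up call never stays up after
  # swapping, and exact swaps hold whenever both directions clear the
  # threshold (the control-denominator convention makes the boundary zone
  # one-sided)
  withr::with_seed(5, {
    ctrl <- runif(200, 1, 100)
    treat <- runif(200, 1, 100)
    fwd <- classify_differential(ctrl, treat, "histone", pseudocount = 0)
    bwd <- classify_differential(treat, ctrl, "histone", pseudocount = 0)
    expect_false(any(fwd == "up" & bwd == "up"))
    expect_false(any(fwd == "down" & bwd == "down"))
    both <- abs(treat - ctrl) / pmax(ctrl, treat) >= 0.2
    swapped <- c(down = "up", stable = "stable", up = "down")[as.character(fwd)]
    expect_equal(as.character(bwd[both]), unname(swapped[both]))
  })
})

test_that("H2A.Z level classes hit the documented sizes and are rank-based", {
  withr::with_seed(8, scores <- sample(seq(0.5, 600, length.out = 100)))
  cls <- classify_h2az_levels(scores)
  expect_equal(as.integer(table(cls)), c(3L, 22L, 50L, 25L))
  # invariance under any monotone transform
  expect_equal(classify_h2az_levels(log(scores)), cls)
  expect_equal(classify_h2az_levels(rank(scores)), cls)
  # ties broken by stable input order
  tied <- classify_h2az_levels(rep(1, 40))
  expect_equal(as.character(tied[1]), "No")
  expect_equal(as.character(tied[40]), "High")
  expect_error(classify_h2az_levels(numeric(0)), class = "chromakit_error")
  expect_error(classify_h2az_levels(1:10), class = "chromakit_error")
})

test_that("fragility is the MNase-low over MNase-high ratio with a pseudocount escape", {
  expect_equal(fragility(2, 1), 2)
  expect_equal(fragility(3, 3), 1)
  expect_equal(fragility(3, 0, pseudocount = 0.1), 30)
  expect_warning(out <- fragility(c(1, 2), c(1, 0)))
  expect_true(is.na(out[2]))
})

test_that("rescued peaks require a margin-exceeding loss difference", {
  expect_true(rescued_peaks(10, 9, 10, 8.8))    # cd loss 1.2 > 1.1 * 1.0
  expect_false(rescued_peaks(10, 9, 10, 8.95))  # 1.05 < 1.1
  expect_false(rescued_peaks(10, 9, 10, 10.5))  # cd gains: nothing to rescue
  expect_error(rescued_peaks(c(1, 2), 1, 1, 1), class = "chromakit_error")
  # alternative formulation: wt signal stays within 10% of its control
  expect_true(rescued_peaks(10, 9.5, 10, 5, rule = "results"))
  expect_false(rescued_peaks(10, 8, 10, 5, rule = "results"))
})

test_that("turnover groups pick the earliest timepoint losing half the signal", {
  m <- rbind(c(10, 4, 3, 2, 1), c(10, 9, 8, 7, 4), c(10, 9, 9, 9, 9),
             c(10, 6, 4, 4, 4))
  expect_equal(as.character(turnover_groups(m)), c("2h", "8h", "stable", "4h"))
  expect_error(turnover_groups(c(0, 1, 1, 1, 1)), class = "chromakit_error")
  expect_error(turnover_groups(c(10, 1, 1)), class = "chromakit_error")
})

test_that("methylation classes use an inclusive five-point margin", {
  expect_equal(as.character(classify_methylation(40, 46)), "hyper")
  expect_equal(as.character(classify_methylation(40, 36)), "stable")
  expect_equal(as.character(classify_methylation(40, 35)), "hypo")
  expect_equal(as.character(classify_methylation(40, 45)), "hyper")
  expect_error(classify_methylation(101, 40), class = "chromakit_error")
})

test_that("z-score k-means recovers well-separated planted patterns up to relabeling", {
  withr::with_seed(21, {
    centers <- matrix(rnorm(6 * 8, sd = 4), 6, 8)
    truth <- rep(1:6, each = 30)
    mat <- centers[truth, ] + matrix(rnorm(180 * 8, sd = 0.2), 180, 8)
  })
  rownames(mat) <- sprintf("g%03d", 1:180)
  res <- zscore_cluster(mat, k = 6, seed = 33)
  expect_true(same_partition(res$cluster, truth))
  res2 <- zscore_cluster(mat, k = 6, seed = 33)
  expect_identical(res$cluster, res2$cluster)
})

test_that("constant rows are dropped with a warning and get NA labels", {
  withr::with_seed(22, mat <- matrix(rnorm(60), 10, 6))
  mat[3, ] <- 5
  expect_warning(res <- zscore_cluster(mat, k = 2, seed = 1), "constant")
  expect_true(is.na(res$cluster[3]))
  expect_equal(sum(is.na(res$cluster)), 1)
  small <- matrix(rnorm(12), 2, 6)
  expect_error(zscore_cluster(small, k = 6, seed = 1),
               class = "chromakit_error")
})
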