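# toy with two exact duplicate pairs far apart in expression space
duplicate_pair_toy <- function() {
  set.seed(8)
  a <- rnorm(20, 0, 1); b <- rnorm(20, 10, 1)
  x <- cbind(A1 = a, A2 = a, B1 = b, B2 = b)
  rownames(x) <- paste0("G", 1:20)
  x
}

test_that("panel restriction keeps panel order and prunes degenerate rows", {
  ch <- generate_cohort(small_config(seed = 2))
  xp <- subset_to_panel(ch$expression, ch$panel)
  expect_equal(rownames(xp), ch$panel$symbol)

  sub_panel <- ch$panel[1:20, ]
  class(sub_panel) <- class(ch$panel)
  xp2 <- subset_to_panel(ch$expression, sub_panel)
  expect_equal(nrow(xp2), 20)

  # absent panel genes reported; constant rows dropped
  x3 <- ch$expression
  x3["DRV0001", ] <- 5
  panel3 <- rbind(ch$panel, data.frame(symbol = "GHOST", category = "marker"))
  class(panel3) <- class(ch$panel)
  expect_warning(expect_warning(xp3 <- subset_to_panel(x3, panel3),
                                "GHOST"), "zero-variance.*DRV0001")
  expect_false("DRV0001" %in% rownames(xp3))

  empty_panel <- data.frame(symbol = "NOPE", category = "marker")
  expect_error(subset_to_panel(ch$expression, empty_panel), "no overlap")
})

test_that("duplicate-pair toy yields all-or-nothing consensus and PAC 0", {
  x <- duplicate_pair_toy()
  res <- consensus_cluster(x, k_range = 2, n_resamples = 50, seed = 4)
  cm <- res$consensus[["2"]]
  expect_equal(cm["A1", "A2"], 1)
  expect_equal(cm["B1", "B2"], 1)
  expect_equal(cm["A1", "B1"], 0)
  expect_equal(unname(res$pac["2"]), 0)
  expect_equal(res$labels[["A1"]], res$labels[["A2"]])
  expect_false(res$labels[["A1"]] == res$labels[["B1"]])
})

test_that("consensus matrices match the straight-loop tally oracle", {
  set.seed(15)
  x <- matrix(rnorm(8 * 9), 8, 9,
              dimnames = list(paste0("G", 1:8), paste0("S", 1:9)))
  res <- consensus_cluster(x, k_range = 2:4, n_resamples = 50,
                           subsample_fraction = 0.7, seed = 15)
  for (k in 2:4) {
    cm_oracle <- oracle_consensus(x, res$resamples, k)
    expect_lt(max(abs(res$consensus[[as.character(k)]] - cm_oracle)), 1e-10)
  }
})

test_that("no subsampling variability collapses consensus to {0, 1}", {
  set.seed(22)
  x <- matrix(rnorm(10 * 8), 10, 8,
              dimnames = list(paste0("G", 1:10), paste0("S", 1:8)))
  res <- consensus_cluster(x, k_range = 2:3, n_resamples = 10,
                           subsample_fraction = 1, seed = 9)
  for (k in c("2", "3")) {
    expect_true(all(res$consensus[[k]] %in% c(0, 1)))
  }
})

test_that("consensus invariants hold across random seeds", {
  for (s in 1:20) {
    set.seed(100 + s)
    n <- sample(8:14, 1)
    x <- matrix(rnorm(12 * n), 12, n,
                dimnames = list(paste0("G", 1:12), paste0("S", seq_len(n))))
    res <- consensus_cluster(x, k_range = 2:4, n_resamples = 30,
                             seed = 100 + s)
    for (k in names(res$consensus)) {
      cm <- res$consensus[[k]]
      expect_true(isSymmetric(cm))
      expect_true(all(diag(cm) == 1))
      expect_true(all(cm >= 0 & cm <= 1))
      # consensus * cosample == cooccurrence where co-sampled
      co <- res$cooccurrence_counts[[k]]
      cs <- res$cosample_counts
      idx <- cs > 0 & !diag(TRUE, nrow(cm))
      expect_lt(max(abs((cm * cs - co)[idx])), 1e-10)
    }
    expect_true(all(res$pac >= 0 & res$pac <= 1))
    expect_equal(length(unique(res$labels)), res$chosen_k)
  }
})

test_that("k selection recovers planted structure and breaks ties low", {
  # three well-separated equidistant blobs -> k = 3
  set.seed(33)
  centers <- matrix(0, 15, 3)
  centers[cbind(1:3, 1:3)] <- 8
  x <- centers[, rep(1:3, each = 8)] + matrix(rnorm(15 * 24, sd = 1), 15, 24)
  dimnames(x) <- list(paste0("G", 1:15), paste0("S", 1:24))
  res <- consensus_cluster(x, k_range = 2:6, n_resamples = 100, seed = 33,
                           distance = "euclidean")
  expect_equal(res$chosen_k, 3)

  # identical consensus across k -> smallest k by tie-break (both methods)
  fake <- res
  fake$consensus <- lapply(fake$consensus, function(cm) {
    cm[] <- 0; diag(cm) <- 1; cm
  })
  fake$delta_area <- setNames(rep(0, 5), names(fake$consensus))
  expect_equal(select_k(fake, "pac"), 2)
  expect_equal(select_k(fake, "delta_area"), 2)
})

test_that("final labels are invariant to sample permutation (up to renaming)", {
  ch <- generate_cohort(small_config(seed = 6))
  xp <- subset_to_panel(ch$expression, ch$panel)
  res1 <- consensus_cluster(xp, k_range = 2:3, n_resamples = 60, seed = 10)
  set.seed(44)
  perm <- sample(ncol(xp))
  res2 <- consensus_cluster(xp[, perm], k_range = 2:3, n_resamples = 60,
                            seed = 10)
  l1 <- final_labels(res1, 2)
  l2 <- final_labels(res2, 2)[names(l1)]
  expect_gt(oracle_ari(l1, l2), 0.999)
})

test_that("two-group cohort labels agree with planted phenotypes", {
  ch <- generate_cohort(small_config(seed = 12))
  xp <- subset_to_panel(ch$expression, ch$panel)
  res <- consensus_cluster(xp, seed = 12)
  expect_equal(res$chosen_k, 2)
  truth <- ch$phenotypes$diagnosis[match(names(res$labels),
                                         ch$phenotypes$sample_id)]
  expect_gte(oracle_ari(res$labels, truth), 0.9)
})

test_that("resampling preconditions are enforced", {
  x <- duplicate_pair_toy()
  expect_error(consensus_cluster(x, k_range = 2, n_resamples = 1), ">= 2")
  expect_error(consensus_cluster(x, k_range = 2:5, n_resamples = 10),
               "samples")
  expect_error(consensus_cluster(x, k_range = 2, n_resamples = 10,
                                 subsample_fraction = 0), "fraction")
  # only 2 distinct profiles: k = 3 cannot be clustered in any resample
  expect_error(consensus_cluster(x, k_range = 3, n_resamples = 5, seed = 1),
               "distinct")
})
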