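# small eigengene-like matrix used across these tests
egs_fixture <- function(n_mod = 100L, n_cond = 40L, seed = 14L) {
  set.seed(seed)
  matrix(rnorm(n_mod * n_cond), n_mod, n_cond,
         dimnames = list(as.character(seq_len(n_mod)),
                         sprintf("c%03d", seq_len(n_cond))))
}

test_that("condition similarity is a correlation with the expected invariances", {
  egs <- egs_fixture()
  expect_equal(condition_similarity(egs, "c001", "c001"), 1)
  # monotone transform: spearman 1, pearson <= 1
  egs2 <- cbind(egs, mono = egs[, "c002"]^3)
  colnames(egs2)[ncol(egs2)] <- "mono"
  expect_equal(condition_similarity(egs2, "c002", "mono",
                                    method = "spearman"), 1)
  expect_lte(condition_similarity(egs2, "c002", "mono"), 1)
  # symmetry and bounds
  ab <- condition_similarity(egs, "c003", "c004")
  expect_equal(ab, condition_similarity(egs, "c004", "c003"))
  expect_true(abs(ab) <= 1)
  expect_error(condition_similarity(egs[1:2, ], "c001", "c002"), ">= 3 modules")
})

test_that("a noisy analog of a condition is recognized, an unrelated one is not", {
  set.seed(33)
  egs <- egs_fixture(100L, 10L, seed = 33L)
  analog <- egs[, "c001"] + rnorm(100, sd = 0.3)
  indep <- rnorm(100)
  egs2 <- cbind(egs, analog = analog, indep = indep)
  expect_gt(condition_similarity(egs2, "c001", "analog"), 0.9)
  expect_lt(abs(condition_similarity(egs2, "c001", "indep")), 0.3)
})

test_that("SVD imputation recovers a low-rank matrix and is a projection", {
  set.seed(8)
  u <- matrix(rnorm(100 * 3), 100, 3)
  v <- matrix(rnorm(60 * 3), 60, 3)
  full <- u %*% t(v)
  dimnames(full) <- list(as.character(1:100), sprintf("c%02d", 1:60))
  holed <- full
  holes <- sample(length(full), round(0.1 * length(full)))
  holed[holes] <- NA
  imp <- impute_conditions(holed, rank = 3L)
  rmse <- sqrt(mean((imp[holes] - full[holes])^2))
  expect_lt(rmse, 0.1 * sd(full))
  # observed entries untouched
  expect_identical(imp[-holes][1:50], full[-holes][1:50])
  # projection property: running it again changes nothing
  imp2 <- impute_conditions(imp, rank = 3L)
  expect_equal(imp2, imp, tolerance = 1e-12, ignore_attr = TRUE)

  # complete matrix is a fixed point
  expect_equal(impute_conditions(full), full, ignore_attr = TRUE)
  # fully-missing condition errors
  bad <- holed; bad[, 5] <- NA
  expect_error(impute_conditions(bad, rank = 3L), "c05")
})

test_that("dropping a time point uses the condition filter before imputing", {
  egs <- egs_fixture(20L, 12L)
  colnames(egs) <- c(sprintf("CPD%02d_2 hr_LO", 1:6),
                     sprintf("CPD%02d_24 hr_LO", 1:6))
  egs[3, 8] <- NA
  meta <- coexmod:::parse_condition_meta(colnames(egs),
                                         default_condition_pattern())
  out <- impute_conditions(egs,
                           drop_conditions =
                             meta$condition_id[meta$time == "2 hr"],
                           rank = 2L)
  expect_identical(ncol(out), 6L)
  expect_false(anyNA(out))
})

test_that("seed expansion applies the r >= 0.7 rule and always keeps seeds", {
  set.seed(4)
  base <- rnorm(30)
  egs <- rbind(`1` = base,
               `2` = 0.8 * base + sqrt(1 - 0.8^2) * rnorm(30),
               `3` = rnorm(30),
               `4` = 0.72 * base + sqrt(1 - 0.72^2) * rnorm(30))
  colnames(egs) <- sprintf("c%02d", 1:30)
  res <- expand_seed_modules(egs, seeds = "1", r_min = 0.7)
  r2 <- cor(egs["1", ], egs["2", ]); r4 <- cor(egs["1", ], egs["4", ])
  expect_identical("2" %in% res$addin_ids, r2 >= 0.7)
  expect_identical("4" %in% res$addin_ids, r4 >= 0.7)
  expect_false("3" %in% res$addin_ids)
  expect_true("1" %in% res$member_ids)
  # a seed whose correlations are all low is still a member
  res2 <- expand_seed_modules(egs, seeds = "3", r_min = 0.7)
  expect_true("3" %in% res2$member_ids)
  expect_error(expand_seed_modules(egs, seeds = "99"), "99")
})

test_that("Ward D2 clustering recovers planted anti-correlated groups", {
  set.seed(10)
  n <- 60L
  a <- rnorm(n)
  grp1 <- t(sapply(1:5, function(i) 0.95 * a + 0.3 * rnorm(n)))
  grp2 <- t(sapply(1:5, function(i) -0.85 * a + 0.45 * rnorm(n)))
  egs <- rbind(grp1, grp2)
  dimnames(egs) <- list(as.character(1:10), sprintf("c%02d", 1:n))
  res <- cluster_modules(egs, k = 2L)
  expect_length(unique(res$cluster_labels[as.character(1:5)]), 1L)
  expect_length(unique(res$cluster_labels[as.character(6:10)]), 1L)
  expect_identical(sort(unique(unname(res$cluster_labels))), c(1L, 2L))
  # merge heights are non-decreasing (Ward monotonicity)
  expect_true(all(diff(res$linkage$height) >= -1e-12))
  # invariance to member ordering
  res_rev <- cluster_modules(egs, members = rev(rownames(egs)), k = 2L)
  expect_identical(res$cluster_labels[names(res$cluster_labels)],
                   res_rev$cluster_labels[names(res$cluster_labels)])
  # perfectly correlated modules merge first at distance ~0
  egs2 <- rbind(egs, `11` = egs["1", ])
  res3 <- cluster_modules(egs2, k = 3L)
  expect_identical(res3$cluster_labels[["11"]], res3$cluster_labels[["1"]])
  expect_lt(min(res3$linkage$height), 1e-6)
  expect_error(cluster_modules(egs, k = 2L, height = 1), "exactly one")
  egs_bad <- egs; egs_bad["3", ] <- 5
  expect_error(cluster_modules(egs_bad, k = 2L), "module 3")
})

test_that("eight planted module groups are recovered at k = 8 (property)", {
  set.seed(18)
  n <- 80L
  k_grp <- 8L
  per <- 6L
  acts <- matrix(rnorm(k_grp * n), k_grp, n)
  egs <- do.call(rbind, lapply(seq_len(k_grp), function(g)
    t(sapply(seq_len(per), function(i) 0.92 * acts[g, ] + 0.35 * rnorm(n)))))
  dimnames(egs) <- list(as.character(seq_len(k_grp * per)),
                        sprintf("c%03d", seq_len(n)))
  truth <- rep(seq_len(k_grp), each = per)
  res <- cluster_modules(egs, k = 8L)
  labels <- res$cluster_labels[rownames(egs)]
  ari <- coexmod:::adjusted_rand_index(truth, unname(labels))
  expect_gte(ari, 0.9)
})
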