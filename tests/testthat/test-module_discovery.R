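test_that("gene filter keeps any-condition hits with a strict boundary", {
  vals <- matrix(0, 3, 3, dimnames = list(paste0("c", 1:3), c("gA", "gB", "gC")))
  ap <- matrix(0.9, 3, 3, dimnames = dimnames(vals))
  ap[1, "gA"] <- 0.0005      # one significant condition -> kept
  ap[2, "gB"] <- 0.001       # exactly at the cut -> excluded (strict <)
  ap[3, "gC"] <- 0.01
  fc <- fold_change_matrix(vals, adj_p = ap)
  expect_identical(filter_genes(fc, 0.001), "gA")
  expect_identical(filter_genes(fc, 0.1), c("gA", "gB", "gC"))
  ap[] <- 0.01
  expect_identical(filter_genes(fold_change_matrix(vals, adj_p = ap), 0.001),
                   character(0))
  expect_error(filter_genes(fold_change_matrix(vals)), "adjusted-p")
})

test_that("soft-power selection returns single candidates and honors the R2 target", {
  fc <- two_block_fc()
  expect_identical(as.integer(suppressWarnings(
    select_soft_power(fc, candidates = 5L))), 5L)
  # independent oracle: recompute the binned regression R2 for the chosen beta
  # a two-block network is not scale-free: the max-R2 fallback warns
  expect_warning(beta <- select_soft_power(fc, candidates = 1:10,
                                           r2_target = 0.5), "R\\^2")
  fit <- attr(beta, "fit")
  k <- colSums(abs(cor(fc$values))^as.integer(beta)) - 1
  brks <- seq(min(k), max(k), length.out = 11L)
  bin <- cut(k, brks, include.lowest = TRUE)
  freq <- tabulate(bin, 10L); mid <- tapply(k, bin, mean)
  keep <- freq > 0 & !is.na(mid)
  lmfit <- lm(log10(freq[keep]) ~ log10(mid[keep]))
  r2 <- summary(lmfit)$r.squared * ifelse(coef(lmfit)[2] < 0, 1, -1)
  expect_equal(fit$r_squared[fit$beta == as.integer(beta)], unname(r2),
               tolerance = 1e-10)
})

test_that("degenerate connectivity falls back to the max-R2 candidate with a warning", {
  vals <- outer(rnorm(12), rep(1, 12)) + 0  # identical columns -> all cor 1
  dimnames(vals) <- list(paste0("c", 1:12), paste0("g", 1:12))
  vals <- vals + matrix(rnorm(144, sd = 1e-9), 12, 12)
  fc <- fold_change_matrix(vals)
  expect_warning(beta <- select_soft_power(fc, candidates = 1:3), "R\\^2")
  expect_true(as.integer(beta) %in% 1:3)
})

test_that("adjacency follows |cor|^beta and TOM matches a brute-force oracle", {
  fc <- tiny_fc(n_cond = 30L, n_genes = 4L, seed = 9L)
  net <- build_network(fc, beta = 5L)
  cc <- cor(fc$values)
  expect_equal(net$adjacency["g1", "g2"], abs(cc["g1", "g2"])^5,
               tolerance = 1e-12)
  expect_equal(unname(diag(net$adjacency)), rep(1, 4))
  # element-wise brute force over the TOM formula
  a <- abs(cc)^5; diag(a) <- 1
  k <- sapply(1:4, function(i) sum(a[i, -i]))
  tom <- matrix(1, 4, 4)
  for (i in 1:4) for (j in 1:4) if (i != j) {
    l <- sum(a[i, -c(i, j)] * a[-c(i, j), j])
    tom[i, j] <- (l + a[i, j]) / (min(k[i], k[j]) + 1 - a[i, j])
  }
  expect_equal(unname(net$tom_dissimilarity), 1 - tom, tolerance = 1e-10)
  # symmetry and range invariants
  expect_lt(max(abs(net$adjacency - t(net$adjacency))), 1e-10)
  expect_lt(max(abs(net$tom_dissimilarity - t(net$tom_dissimilarity))), 1e-10)
  expect_true(all(net$tom_dissimilarity >= -1e-12 & net$tom_dissimilarity <= 1))
  # arithmetic check of the stated formula on a fabricated correlation
  expect_equal(0.6^5, 0.07776)
})

test_that("zero-variance genes are rejected by name", {
  fc <- tiny_fc()
  fc$values[, "g2"] <- 3
  expect_error(build_network(fc, beta = 5L), "g2")
})

test_that("planted blocks are recovered exactly and small clusters dissolve", {
  fc <- two_block_fc()
  net <- build_network(fc, beta = 5L)
  assign <- detect_modules(net, min_size = 5L)
  lab <- assign$labels
  expect_identical(sort(unique(unname(lab))), c(1L, 2L))
  expect_length(unique(lab[paste0("g", sprintf("%02d", 1:10))]), 1L)
  expect_length(unique(lab[paste0("g", sprintf("%02d", 11:20))]), 1L)

  # 3 correlated genes under min_size 5 -> all gray
  set.seed(1)
  a <- rnorm(40)
  vals <- sapply(1:3, function(i) a + 0.2 * rnorm(40))
  dimnames(vals) <- list(paste0("c", 1:40), paste0("g", 1:3))
  netg <- build_network(fold_change_matrix(vals), beta = 5L)
  expect_true(all(detect_modules(netg, min_size = 5L)$labels == 0L))
})

test_that("pure-noise matrices leave >= 90% of genes gray", {
  set.seed(123)
  vals <- matrix(rnorm(60 * 150), 60, 150,
                 dimnames = list(paste0("c", 1:60), paste0("g", 1:150)))
  net <- build_network(fold_change_matrix(vals), beta = 5L)
  assign <- detect_modules(net, min_size = 5L)
  expect_gte(mean(assign$labels == 0L), 0.9)
})

test_that("modules merge at eigengene correlation >= 0.8 and not below", {
  set.seed(5)
  n <- 80L
  a <- rnorm(n)
  b <- 0.97 * a + sqrt(1 - 0.97^2) * rnorm(n)   # eigengene cor ~ 0.95
  c_ <- rnorm(n)                                # independent
  mk <- function(act, k, off) sapply(seq_len(k), function(i)
    0.95 * act + 0.3 * rnorm(n))
  vals <- cbind(mk(a, 8), mk(b, 6), mk(c_, 5))
  dimnames(vals) <- list(paste0("cn", seq_len(n)), paste0("g", 1:19))
  fc <- fold_change_matrix(vals)
  labels <- setNames(rep(1:3, c(8, 6, 5)), colnames(vals))
  assign <- structure(list(gene_ids = colnames(vals), labels = labels),
                      class = "module_assignment")
  ms <- merge_and_label(assign, fc, merge_cor = 0.8)
  sizes <- unname(module_sizes <- sapply(ms$modules, function(m) length(m$gene_ids)))
  expect_identical(length(ms$modules), 2L)       # 1+2 merged, 3 untouched
  expect_identical(sizes, c(14L, 5L))            # bigger module gets label 1
  expect_identical(ms$modules[[1]]$id, 1L)

  ms2 <- merge_and_label(assign, fc, merge_cor = 0.99)
  expect_identical(length(ms2$modules), 3L)      # below threshold: unchanged
})

test_that("labels decrease with module size after relabeling", {
  sb <- small_build()
  sizes <- sapply(sb$build$modules$modules, function(m) length(m$gene_ids))
  expect_true(all(diff(sizes) <= 0))
  ids <- sapply(sb$build$modules$modules, `[[`, "id")
  expect_identical(ids, seq_along(ids))
})

test_that("planted-module recovery holds across fixture scales (property)", {
  for (seed in c(2L, 3L)) {
    sim <- generate_reference(n_genes = 500L, n_modules = 10L,
                              module_size_range = c(8L, 40L),
                              n_conditions = 120L, seed = seed)
    res <- build_modules(sim$fc, beta = 5)
    truth <- sim$truth$module_partition
    det <- setNames(integer(length(truth)), names(truth))
    for (m in res$modules$modules) det[m$gene_ids] <- m$id
    keep <- truth > 0 & det > 0
    expect_gte(coexmod:::adjusted_rand_index(truth[keep], det[keep]), 0.9)
  }
})

test_that("merging is order-independent when pair correlations are distinct", {
  sb <- small_build()
  fc <- coexmod:::subset_genes(sb$sim$fc, sb$build$assignment$gene_ids)
  lab <- sb$build$assignment$labels
  partition_of <- function(ms) {
    out <- lapply(ms$modules, function(m) sort(m$gene_ids))
    out[order(vapply(out, `[[`, character(1L), 1L))]
  }
  ms_a <- merge_and_label(sb$build$assignment, fc, merge_cor = 0.5)
  # relabel the input modules in reverse order and re-merge
  relab <- max(lab) + 1L - lab
  relab[lab == 0L] <- 0L
  assign_b <- structure(list(gene_ids = sb$build$assignment$gene_ids,
                             labels = relab), class = "module_assignment")
  ms_b <- merge_and_label(assign_b, fc, merge_cor = 0.5)
  expect_identical(partition_of(ms_a), partition_of(ms_b))
})
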