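test_that("hypergeometric ORA matches exact enumeration (incl. the worked case)", {
  universe <- sprintf("u%02d", 1:20)
  gene_set <- universe[1:5]
  module <- universe[c(1, 2, 3, 10)]          # k = 3, K = 5, n = 4, N = 20
  row <- ora_module(module, gene_set, universe)
  expect_equal(row$p, 155 / 4845, tolerance = 1e-12)
  expect_identical(c(row$k, row$K, row$n, row$N), c(3L, 5L, 4L, 20L))

  # k = 0 -> upper tail includes X = 0 -> p = 1
  expect_equal(ora_module(universe[10:13], universe[1:5], universe)$p, 1)
  # degenerate certainty
  expect_equal(ora_module(universe, universe, universe)$p, 1)
  expect_error(ora_module(character(0), gene_set, universe), "empty module")
  expect_error(ora_module(module, gene_set, character(0)), "empty universe")
})

test_that("ORA equals the binomial-coefficient oracle over all N <= 30 instances", {
  # exact tail by explicit enumeration: p = sum_{j >= k} C(K,j) C(N-K,n-j) / C(N,n)
  for (N in c(5L, 12L, 20L, 30L)) {
    universe <- sprintf("x%03d", seq_len(N))
    for (K in seq(0L, N, by = 4L)) {
      gene_set <- utils::head(universe, K)
      for (n in seq(1L, N, by = 5L)) {
        for (k in max(0L, n + K - N):min(n, K)) {
          module <- c(utils::head(gene_set, k),
                      utils::head(setdiff(universe, gene_set), n - k))
          got <- ora_module(module, gene_set, universe)$p
          js <- k:min(n, K)
          want <- sum(choose(K, js) * choose(N - K, n - js)) / choose(N, n)
          expect_equal(got, want, tolerance = 1e-12)
        }
      }
    }
  }
})

test_that("module annotation keeps top-10 by p at FDR < 0.05 and BH is monotone", {
  sb <- small_build()
  ms <- sb$build$modules
  # gene sets derived from the planted partition: strong signal sets plus noise
  set.seed(12)
  sets <- list()
  for (m in ms$modules) {
    for (j in 1:12) {
      nm <- sprintf("SIG_m%d_%d", m$id, j)
      extra <- sample(setdiff(ms$universe, m$gene_ids), 3)
      sets[[nm]] <- c(sample(m$gene_ids, min(8, length(m$gene_ids))), extra)
    }
  }
  for (j in 1:20) sets[[sprintf("RND_%d", j)]] <- sample(ms$universe, 10)
  coll <- structure(list(sets = sets, source = "fixture"),
                    class = "gene_set_collection")
  res <- enrich_modules(ms, coll, p_cut = 0.01, top_n = 10L, fdr_cut = 0.05)
  expect_true(all(res$table$p < 0.01))
  expect_true(all(res$table$fdr >= res$table$p))
  # BH never inverts the p ordering
  ord <- order(res$table$p)
  expect_true(all(diff(res$table$fdr[ord]) >= -1e-12))
  counts <- table(res$annotation$module_id[!is.na(res$annotation$set_name)])
  expect_true(all(counts <= 10))
  big <- ms$modules[[1]]$id
  expect_equal(unname(counts[as.character(big)]), 10L)  # >10 qualify -> capped
  # a module with nothing qualifying is retained with a null annotation
  ann_ids <- unique(res$annotation$module_id)
  expect_setequal(ann_ids, sapply(ms$modules, `[[`, "id"))
})

test_that("TF enrichment respects confidence tiers", {
  ms <- toy_module_set()
  reg <- structure(list(regulons = list(
    TFX = data.frame(target = c("g1", "g2", "g3", "g4", "g5"),
                     mode = c(1, 1, -1, 1, 1),
                     confidence = c("A", "B", "C", "D", "D"),
                     stringsAsFactors = FALSE),
    TFZ = data.frame(target = "nope", mode = 1, confidence = "A",
                     stringsAsFactors = FALSE))),
    class = "regulon_collection")
  hc <- expect_message(
    tf_enrichment(ms, reg, "high_confidence", p_cut = 1.01), "TFZ")
  expect_true(all(hc$K[hc$tf == "TFX"] == 3L))       # classes A-C
  hv <- suppressMessages(tf_enrichment(ms, reg, "high_coverage", p_cut = 1.01))
  expect_true(all(hv$K[hv$tf == "TFX"] == 5L))       # classes A-D
  expect_error(tf_enrichment(ms, reg, "everything"))
})

test_that("surrogate TF activity follows the signed sqrt-m normalization", {
  reg <- structure(list(regulons = list(
    UP = data.frame(target = paste0("t", 1:4), mode = 1,
                    confidence = "A", stringsAsFactors = FALSE),
    DN = data.frame(target = paste0("t", 1:4), mode = -1,
                    confidence = "A", stringsAsFactors = FALSE),
    TINY = data.frame(target = c("t1", "t2"), mode = 1,
                      confidence = "A", stringsAsFactors = FALSE))),
    class = "regulon_collection")
  vals <- matrix(1, 2, 4, dimnames = list(c("c1", "c2"), paste0("t", 1:4)))
  vals[2, ] <- c(1, -1, 1, -1)
  fc <- fold_change_matrix(vals)
  sds <- setNames(rep(1, 4), paste0("t", 1:4))
  nes <- tf_activity(reg, fc, ref_sd = sds)
  expect_equal(unname(nes["UP", "c1"]), 2)           # 4 / sqrt(4)
  expect_equal(unname(nes["DN", "c1"]), -2)          # antisymmetric in mode
  expect_equal(unname(nes["UP", "c2"]), 0)
  expect_true(is.na(nes["TINY", "c1"]))              # < 3 measured targets
  # linearity in log2FC
  fc3 <- fold_change_matrix(vals * 3)
  expect_equal(tf_activity(reg, fc3, ref_sd = sds)["UP", ],
               3 * nes["UP", ], tolerance = 1e-12)
})

test_that("surrogate activity is calibrated under the null (mean 0, SD 1)", {
  set.seed(123)
  n_cond <- 500L; n_genes <- 20L
  vals <- matrix(rnorm(n_cond * n_genes), n_cond, n_genes,
                 dimnames = list(sprintf("c%03d", 1:n_cond),
                                 sprintf("t%02d", 1:n_genes)))
  fc <- fold_change_matrix(vals)
  reg <- structure(list(regulons = lapply(
    setNames(1:20, sprintf("TF%02d", 1:20)), function(i) {
      set.seed(i)
      data.frame(target = sample(colnames(vals), 8),
                 mode = sample(c(-1, 1), 8, replace = TRUE),
                 confidence = "A", stringsAsFactors = FALSE)
    })), class = "regulon_collection")
  nes <- tf_activity(reg, fc, ref_sd = setNames(rep(1, n_genes),
                                                colnames(vals)))
  draws <- as.vector(nes)                            # 10,000 TF x condition draws
  expect_lt(abs(mean(draws)), 0.05)
  expect_lt(abs(sd(draws) - 1), 0.1)
})
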