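#' Filter genes by adjusted-p significance
#'
#' Keeps genes whose BH-adjusted p-value is below `alpha` in at least one
#' condition (strict inequality), the inclusion rule applied before network
#' construction. Input gene order is preserved.
#'
#' @param fc an [fold_change_matrix()] with an `adj_p` grid.
#' @param alpha significance cut, default `0.001`.
#' @return character vector of retained gene ids.
#' @export
filter_genes <- function(fc, alpha = 0.001) {
  if (is.null(fc$adj_p))
    stop2("`fc` has no adjusted-p grid; supply one via `adjp_path` ",
          "or skip filtering explicitly by passing all genes downstream")
  if (!(alpha > 0 && alpha < 1)) stop2("`alpha` must lie in (0, 1)")
  min_p <- apply(fc$adj_p, 2L, min, na.rm = TRUE)
  colnames(fc$values)[min_p < alpha]
}

#' Select the soft-power exponent by scale-free fit
#'
#' For each candidate exponent beta, the adjacency `|cor|^beta` is formed
#' and the connectivity distribution is tested for approximate scale-free
#' topology: frequencies of binned connectivity are regressed as
#' log10(freq) ~ log10(mean k) and the fit R-squared is signed by the
#' slope (only the negative-slope branch counts). Returns the smallest
#' candidate reaching `r2_target`; if none does, the candidate with the
#' best fit is returned with a warning.
#'
#' @param fc complete [fold_change_matrix()].
#' @param candidates integer vector of candidate exponents, default `1:20`.
#' @param r2_target required scale-free fit, default `0.8`.
#' @param n_bins connectivity histogram bins, default `10`.
#' @param cor_method `"pearson"` (default) or `"spearman"`.
#' @return chosen exponent (integer) with attribute `"fit"`: a data.frame
#'   of candidate betas and their signed R-squared.
#' @export
select_soft_power <- function(fc, candidates = 1:20, r2_target = 0.8,
                              n_bins = 10L,
                              cor_method = c("pearson", "spearman")) {
  cor_method <- match.arg(cor_method)
  assert_complete(fc, "soft-power selection")
  if (!length(candidates)) stop2("`candidates` must be non-empty")
  if (!(r2_target > 0 && r2_target < 1)) stop2("`r2_target` must lie in (0, 1)")
  if (ncol(fc$values) < 10L) stop2("scale-free fit undefined for < 10 genes")
  cc <- abs(stats::cor(fc$values, method = cor_method))
  r2 <- vapply(candidates, function(beta) {
    a <- cc^beta
    k <- colSums(a) - 1
    scale_free_r2(k, n_bins)
  }, numeric(1L))
  ok <- which(r2 >= r2_target)
  if (length(ok)) {
    beta <- candidates[min(ok)]
  } else {
    beta <- candidates[which.max(r2)]
    warn2(sprintf(paste0("no candidate reached scale-free R^2 >= %.2f; ",
                         "returning beta = %d (R^2 = %.3f)"),
                  r2_target, beta, max(r2)))
  }
  structure(as.integer(beta),
            fit = data.frame(beta = candidates, r_squared = r2))
}

## signed scale-free model fit: R^2 of log10(freq) ~ log10(k) over
## equal-width connectivity bins, negated when the slope is positive
scale_free_r2 <- function(k, n_bins) {
  if (diff(range(k)) < .Machine$double.eps^0.5) return(0)  # degenerate
  cut_points <- seq(min(k), max(k), length.out = n_bins + 1L)
  bin <- cut(k, cut_points, include.lowest = TRUE)
  freq <- tabulate(bin, nbins = n_bins)
  mid <- tapply(k, bin, mean)
  keep <- freq > 0 & !is.na(mid) & mid > 0
  if (sum(keep) < 3L) return(0)
  x <- log10(mid[keep]); y <- log10(freq[keep])
  fit <- stats::lm.fit(cbind(1, x), y)
  ssr <- sum(fit$residuals^2); sst <- sum((y - mean(y))^2)
  if (sst == 0) return(0)
  r2 <- 1 - ssr / sst
  slope <- fit$coefficients[2L]
  if (is.na(slope) || slope >= 0) -r2 else r2
}

#' Build the unsigned co-expression network
#'
#' Adjacency `a_ij = |cor(i, j)|^beta` and topological-overlap
#' dissimilarity `1 - TOM`, with
#' `TOM_ij = (l_ij + a_ij) / (min(k_i, k_j) + 1 - a_ij)`,
#' `l_ij = sum_{u != i,j} a_iu a_uj` and `k_i = sum_{u != i} a_iu`.
#'
#' @param fc complete [fold_change_matrix()].
#' @param genes genes to include (default all).
#' @param beta soft-power exponent (positive integer).
#' @param cor_method `"pearson"` (default) or `"spearman"`.
#' @return list of class `coexpression_network` with `gene_ids`, `beta`,
#'   `adjacency`, `tom_dissimilarity`.
#' @export
build_network <- function(fc, genes = colnames(fc$values), beta,
                          cor_method = c("pearson", "spearman")) {
  cor_method <- match.arg(cor_method)
  fc <- subset_genes(fc, genes)
  assert_complete(fc, "network construction")
  if (nrow(fc$values) < 3L) stop2("need >= 3 conditions to build a network")
  sds <- col_sds(fc$values)
  if (any(sds == 0))
    stop2("zero-variance gene: ", genes[which(sds == 0)[1L]])
  a <- abs(stats::cor(fc$values, method = cor_method))^beta
  diag(a) <- 1
  a <- (a + t(a)) / 2
  m <- a; diag(m) <- 0
  l <- m %*% m                       # l_ij = sum_{u != i,j} a_iu a_uj
  k <- colSums(m)
  min_k <- outer(k, k, pmin)
  tom <- (l + m) / (min_k + 1 - m)
  diag(tom) <- 1
  tom <- (tom + t(tom)) / 2
  diss <- 1 - tom
  diag(diss) <- 0
  structure(list(gene_ids = genes, beta = as.integer(beta),
                 adjacency = a, tom_dissimilarity = diss),
            class = "coexpression_network")
}

#' Detect modules by hierarchical tree cut
#'
#' Average-linkage hierarchical clustering of the TOM dissimilarity,
#' cut at the `cut_q` quantile of merge heights; clusters smaller than
#' `min_size`, or lacking internal coherence, are dissolved into the gray
#' pool (label 0). Coherence is judged on the soft-power-independent
#' correlation scale: a cluster is kept only when its mean internal
#' `1 - |cor|` is at most `coherence` times the network's 75th-percentile
#' `1 - |cor|`. Chance clusters of independent genes sit at ratios >= 0.8,
#' genuinely co-expressed modules well below 0.5, so the default 0.6
#' separates them with margin on both sides. Deterministic given its
#' input.
#'
#' @param net a `coexpression_network` from [build_network()].
#' @param min_size minimum module size, default `5`.
#' @param cut_q quantile of merge heights at which the tree is cut,
#'   default `0.95`.
#' @param coherence dissolve clusters whose mean internal `1 - |cor|`
#'   exceeds this fraction of the network-wide 75th percentile, default
#'   `0.6`.
#' @return list of class `module_assignment` with `gene_ids` and integer
#'   `labels` (0 = gray), plus the `tree` used.
#' @export
detect_modules <- function(net, min_size = 5L, cut_q = 0.95,
                           coherence = 0.6) {
  if (min_size < 2L) stop2("`min_size` must be >= 2")
  d <- net$tom_dissimilarity
  tree <- stats::hclust(stats::as.dist(d), method = "average")
  h <- stats::quantile(tree$height, cut_q, names = FALSE)
  labels <- stats::cutree(tree, h = h)
  tab <- table(labels)
  if (length(tab) == 1L) {
    warn2("tree cut produced a single indivisible cluster")
  }
  keep <- as.integer(names(tab)[tab >= min_size])
  dc <- 1 - net$adjacency^(1 / net$beta)   # back to the |cor| scale
  base <- stats::quantile(dc[upper.tri(dc)], 0.75, names = FALSE)
  keep <- keep[vapply(keep, function(cl) {
    idx <- which(labels == cl)
    sub <- dc[idx, idx]
    mean(sub[upper.tri(sub)]) <= coherence * base
  }, logical(1L))]
  labels[!(labels %in% keep)] <- 0L
  ## relabel surviving clusters 1..K by decreasing size (final labels are
  ## reassigned again after merging; this keeps intermediate output tidy)
  if (any(labels > 0L)) {
    sizes <- sort(table(labels[labels > 0L]), decreasing = TRUE)
    remap <- stats::setNames(seq_along(sizes), names(sizes))
    labels[labels > 0L] <- remap[as.character(labels[labels > 0L])]
  }
  structure(list(gene_ids = net$gene_ids,
                 labels = stats::setNames(as.integer(labels), net$gene_ids),
                 tree = tree),
            class = "module_assignment")
}

#' Merge correlated modules and freeze the module set
#'
#' Iteratively merges the module pair with the highest eigengene
#' correlation while that correlation is `>= merge_cor`, recomputing
#' eigengenes after every merge. Ties are broken toward the pair
#' containing the smallest module id. Final modules are relabeled
#' `1..K` by decreasing size (larger module, smaller label) and per-gene
#' corEG, hub genes, and the reference normalization constants are
#' populated.
#'
#' @param assign a `module_assignment` from [detect_modules()].
#' @param fc the reference [fold_change_matrix()] (complete over the
#'   assigned genes).
#' @param merge_cor eigengene-correlation merge threshold, default `0.8`.
#' @param reference_label stored on the result.
#' @param hub `"signed"` (default: highest corEG) or `"abs"` (highest
#'   absolute corEG).
#' @return a frozen [module_set()].
#' @export
merge_and_label <- function(assign, fc, merge_cor = 0.8,
                            reference_label = "", hub = c("signed", "abs")) {
  hub <- match.arg(hub)
  if (!(merge_cor > 0 && merge_cor <= 1)) stop2("`merge_cor` must lie in (0, 1]")
  fc_sub <- subset_genes(fc, assign$gene_ids)
  assert_complete(fc_sub, "module merging")
  zfc <- standardize_reference(fc_sub)
  labels <- assign$labels
  groups <- split(names(labels)[labels > 0L], labels[labels > 0L])
  names(groups) <- as.character(seq_along(groups))
  if (length(groups) >= 2L) {
    egs <- vapply(groups, function(g) module_eigengene(zfc$values[, g, drop = FALSE]),
                  numeric(nrow(zfc$values)))
    repeat {
      cc <- suppressWarnings(stats::cor(egs))
      diag(cc) <- -Inf
      cc[is.na(cc)] <- -Inf
      best <- max(cc)
      if (best < merge_cor) break
      idx <- which(cc == best, arr.ind = TRUE)
      idx <- idx[idx[, 1L] < idx[, 2L], , drop = FALSE]
      ## tie-break: pair containing the smallest module id, then smallest
      ## partner id
      ids <- cbind(as.integer(colnames(egs)[idx[, 1L]]),
                   as.integer(colnames(egs)[idx[, 2L]]))
      ord <- order(pmin(ids[, 1L], ids[, 2L]), pmax(ids[, 1L], ids[, 2L]))
      i <- idx[ord[1L], 1L]; j <- idx[ord[1L], 2L]
      keep_id <- colnames(egs)[min(i, j)]
      drop_id <- colnames(egs)[max(i, j)]
      groups[[keep_id]] <- c(groups[[keep_id]], groups[[drop_id]])
      groups[[drop_id]] <- NULL
      egs <- egs[, colnames(egs) != drop_id, drop = FALSE]
      egs[, keep_id] <- module_eigengene(
        zfc$values[, groups[[keep_id]], drop = FALSE])
      if (ncol(egs) < 2L) break
    }
  }
  ## relabel by decreasing size; ties keep the previous relative order
  sizes <- vapply(groups, length, integer(1L))
  groups <- groups[order(-sizes, as.integer(names(groups)))]
  labels[] <- 0L
  for (i in seq_along(groups)) labels[groups[[i]]] <- i
  freeze_module_set(labels, fc_sub, zfc = zfc,
                    reference_label = reference_label, hub = hub)
}

#' One-call module build pipeline
#'
#' Convenience wrapper chaining [filter_genes()], [select_soft_power()],
#' [build_network()], [detect_modules()] and [merge_and_label()].
#'
#' @param fc reference [fold_change_matrix()].
#' @param alpha gene-filter cut (`NULL` skips filtering), default `0.001`.
#' @param beta `"auto"` (scale-free selection) or an integer override.
#' @param min_size minimum module size, default `5`.
#' @param merge_cor eigengene merge threshold, default `0.8`.
#' @param cut_q tree-cut height quantile, default `0.95`.
#' @param reference_label stored on the result.
#' @return list with `modules` (the frozen [module_set()]), `assignment`,
#'   `beta`, and a `report` list (genes filtered, beta, module count, gray
#'   fraction).
#' @export
build_modules <- function(fc, alpha = 0.001, beta = "auto", min_size = 5L,
                          merge_cor = 0.8, cut_q = 0.95,
                          reference_label = "") {
  genes <- if (is.null(alpha)) colnames(fc$values) else filter_genes(fc, alpha)
  if (length(genes) < 10L)
    stop2("fewer than 10 genes pass the filter; nothing to build")
  fc_f <- subset_genes(fc, genes)
  if (identical(beta, "auto")) beta <- select_soft_power(fc_f)
  net <- build_network(fc_f, beta = as.integer(beta))
  assign <- detect_modules(net, min_size = min_size, cut_q = cut_q)
  ms <- merge_and_label(assign, fc_f, merge_cor = merge_cor,
                        reference_label = reference_label)
  gray_frac <- 1 - sum(module_sizes(ms)) / length(genes)
  list(modules = ms, assignment = assign, beta = as.integer(beta),
       report = list(n_genes_input = ncol(fc$values),
                     n_genes_filtered = length(genes),
                     beta = as.integer(beta),
                     n_modules = length(ms$modules),
                     gray_fraction = gray_frac))
}
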