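#' Correlation of two conditions in module-score space
#'
#' @param egs modules x conditions score matrix (eigengene or projected).
#' @param a,b condition ids.
#' @param method `"pearson"` (default) or `"spearman"`.
#' @return the correlation of the two module-score vectors.
#' @export
condition_similarity <- function(egs, a, b,
                                 method = c("pearson", "spearman")) {
  method <- match.arg(method)
  if (nrow(egs) < 3L) stop2("need >= 3 modules for a condition correlation")
  for (id in c(a, b)) if (!id %in% colnames(egs))
    stop2("condition not found: ", id)
  stats::cor(egs[, a], egs[, b], method = method)
}

#' Iterative SVD imputation of missing module scores
#'
#' Drops the conditions named in `drop_conditions` (typically an
#' undersampled early time point, e.g. all 2-h experiments), then fills
#' the remaining missing entries by iterative low-rank SVD reconstruction:
#' initialize missing cells with per-module (row) means, truncate the SVD
#' to `rank` components, refill only the missing cells from the
#' reconstruction, and repeat until the relative change of the imputed
#' values falls below `tol`. Observed entries are never altered.
#'
#' @param egs modules x conditions matrix, `NA` for missing.
#' @param drop_conditions condition ids to remove before imputation
#'   (default none).
#' @param rank SVD truncation rank; default `NULL` picks the smallest rank
#'   explaining at least 90% of the variance of the complete-column
#'   submatrix.
#' @param tol relative-change convergence threshold, default `0.01`.
#' @param max_iter iteration cap, default `100`.
#' @return the completed matrix (attribute `"rank"` records the rank
#'   used).
#' @export
impute_conditions <- function(egs, drop_conditions = NULL, rank = NULL,
                              tol = 0.01, max_iter = 100L) {
  x <- as.matrix(egs)
  if (!is.null(drop_conditions))
    x <- x[, !(colnames(x) %in% drop_conditions), drop = FALSE]
  miss <- is.na(x)
  if (any(rowSums(!miss) == 0L))
    stop2("module with all values missing: ",
          rownames(x)[which(rowSums(!miss) == 0L)[1L]])
  if (any(colSums(!miss) == 0L))
    stop2("condition with all values missing: ",
          colnames(x)[which(colSums(!miss) == 0L)[1L]])
  if (mean(miss) >= 0.5)
    stop2("more than 50% of entries missing after dropping conditions")
  if (!any(miss)) {
    attr(x, "rank") <- 0L
    return(x)
  }
  if (is.null(rank)) rank <- default_impute_rank(x, miss)
  rank <- max(1L, min(as.integer(rank), nrow(x) - 1L, ncol(x) - 1L))
  row_means <- rowMeans(x, na.rm = TRUE)
  filled <- x
  filled[miss] <- row_means[row(x)[miss]]
  for (iter in seq_len(max_iter)) {
    sv <- svd(filled, nu = rank, nv = rank)
    recon <- sv$u %*% (sv$d[seq_len(rank)] * t(sv$v))
    old <- filled[miss]
    filled[miss] <- recon[miss]
    denom <- sqrt(sum(old^2))
    delta <- if (denom > 0) sqrt(sum((filled[miss] - old)^2)) / denom
             else sqrt(sum(filled[miss]^2))
    if (delta < tol) break
  }
  attr(filled, "rank") <- rank
  filled
}

## smallest rank explaining >= 90% variance of the complete-column
## submatrix (falls back to the row-mean-filled matrix when no column is
## complete)
default_impute_rank <- function(x, miss) {
  complete_cols <- colSums(miss) == 0L
  base <- if (sum(complete_cols) >= 2L) x[, complete_cols, drop = FALSE]
          else {
            filled <- x
            filled[miss] <- rowMeans(x, na.rm = TRUE)[row(x)[miss]]
            filled
          }
  d2 <- svd(base, nu = 0L, nv = 0L)$d^2
  cum <- cumsum(d2) / sum(d2)
  as.integer(which(cum >= 0.9)[1L])
}

#' Expand seed modules by eigengene correlation
#'
#' Builds the expanded module set around a list of well-annotated seed
#' modules: a candidate is added in when its best Pearson correlation with
#' any seed eigengene reaches `r_min`. Seeds are always members of the
#' expanded set.
#'
#' @param egs modules x conditions score matrix.
#' @param seeds module ids (must be rows of `egs`).
#' @param r_min add-in threshold, default `0.7`.
#' @param candidates candidate module ids, default all rows (restrict to
#'   preserved modules to follow the reference workflow).
#' @return list of class `seed_expansion`: `seed_ids`, `addin_ids`,
#'   `member_ids`, and the per-candidate `best_seed_cor`.
#' @export
expand_seed_modules <- function(egs, seeds, r_min = 0.7,
                                candidates = rownames(egs)) {
  seeds <- as.character(seeds); candidates <- as.character(candidates)
  if (!(r_min > 0 && r_min <= 1)) stop2("`r_min` must lie in (0, 1]")
  absent <- setdiff(seeds, rownames(egs))
  if (length(absent)) stop2("seed module not found: ", absent[1L])
  cand <- setdiff(intersect(candidates, rownames(egs)), seeds)
  best <- if (length(cand)) {
    cc <- stats::cor(t(egs[cand, , drop = FALSE]),
                     t(egs[seeds, , drop = FALSE]))
    stats::setNames(apply(cc, 1L, max), cand)
  } else stats::setNames(numeric(0), character(0))
  addin <- names(best)[best >= r_min]
  structure(list(seed_ids = seeds, addin_ids = addin,
                 member_ids = c(seeds, addin), best_seed_cor = best),
            class = "seed_expansion")
}

#' Ward D2 clustering of modules on 1 - correlation
#'
#' Hierarchical clustering of module score profiles with the full Ward
#' criterion (`ward.D2`) on the distance `1 - cor`; exactly one of `k`
#' (number of clusters) or `height` (cut height) selects the partition.
#' Cluster ids are assigned by decreasing cluster size, ties broken by the
#' smallest member module id.
#'
#' @param egs modules x conditions score matrix.
#' @param members module ids to cluster, default all rows.
#' @param k number of clusters.
#' @param height cut height.
#' @param method correlation flavor, `"pearson"` (default) or
#'   `"spearman"`.
#' @return list of class `module_clustering`: `cluster_labels` (named
#'   integer), `linkage` (the `hclust` tree), `members`.
#' @export
cluster_modules <- function(egs, members = rownames(egs), k = NULL,
                            height = NULL,
                            method = c("pearson", "spearman")) {
  method <- match.arg(method)
  members <- as.character(members)
  if (length(members) < 2L) stop2("need >= 2 modules to cluster")
  if (is.null(k) == is.null(height))
    stop2("supply exactly one of `k` or `height`")
  x <- egs[members, , drop = FALSE]
  sds <- apply(x, 1L, stats::sd)
  if (any(sds == 0))
    stop2("constant score vector for module ", members[which(sds == 0)[1L]])
  ## sort members for an input-order-invariant tree
  ord <- order(members)
  x <- x[ord, , drop = FALSE]
  d <- stats::as.dist(1 - stats::cor(t(x), method = method))
  tree <- stats::hclust(d, method = "ward.D2")
  raw <- if (!is.null(k)) stats::cutree(tree, k = k)
         else stats::cutree(tree, h = height)
  labels <- relabel_clusters(raw)
  structure(list(cluster_labels = labels, linkage = tree,
                 members = names(labels)),
            class = "module_clustering")
}

## relabel clusters 1..K by decreasing size; ties by smallest member id
relabel_clusters <- function(raw) {
  sizes <- table(raw)
  key <- suppressWarnings(as.numeric(names(raw)))
  if (anyNA(key)) key <- match(names(raw), sort(names(raw)))
  first_member <- tapply(key, raw, min)
  ord <- order(-as.integer(sizes),
               first_member[names(sizes)])
  remap <- stats::setNames(seq_along(ord), names(sizes)[ord])
  stats::setNames(as.integer(remap[as.character(raw)]), names(raw))
}

#' Seed expansion followed by clustering
#'
#' The full interaction-map recipe: drop undersampled conditions + impute
#' (optional, see [impute_conditions()]), expand seeds at `r_min`, then
#' Ward-cluster the expanded set.
#'
#' @inheritParams expand_seed_modules
#' @inheritParams cluster_modules
#' @return list of class `seed_cluster_result`: `seed_ids`, `addin_ids`,
#'   `cluster_labels`, `linkage`.
#' @export
seed_cluster_modules <- function(egs, seeds, r_min = 0.7,
                                 candidates = rownames(egs), k = NULL,
                                 height = NULL) {
  exp <- expand_seed_modules(egs, seeds, r_min, candidates)
  cl <- cluster_modules(egs, exp$member_ids, k = k, height = height)
  structure(list(seed_ids = exp$seed_ids, addin_ids = exp$addin_ids,
                 cluster_labels = cl$cluster_labels, linkage = cl$linkage),
            class = "seed_cluster_result")
}
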