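#' Translate gene ids through a one-to-one ortholog map
#'
#' Keeps only map entries that are one-to-one after filtering (any source
#' mapped to several targets, or target hit by several sources, is dropped
#' entirely) and renames the matrix genes into the reference namespace;
#' unmapped genes are dropped with a message.
#'
#' @param fc a [fold_change_matrix()] in the source namespace.
#' @param ortholog_map data.frame with columns `source_id`, `target_id`
#'   (see [read_ortholog_map()]).
#' @return an `fc_matrix` in the target namespace.
#' @export
map_orthologs <- function(fc, ortholog_map) {
  src <- ortholog_map$source_id; tgt <- ortholog_map$target_id
  multi_src <- unique(src[duplicated(src)])
  multi_tgt <- unique(tgt[duplicated(tgt)])
  drop <- src %in% multi_src | tgt %in% multi_tgt
  if (any(drop))
    warn2(sum(drop), " ortholog pair(s) dropped to enforce a one-to-one map")
  src <- src[!drop]; tgt <- tgt[!drop]
  keep <- colnames(fc$values) %in% src
  if (!any(keep)) stop2("no matrix gene has a usable ortholog mapping")
  n_unmapped <- sum(!keep)
  if (n_unmapped) message(n_unmapped, " gene(s) without an ortholog dropped")
  vals <- fc$values[, keep, drop = FALSE]
  lut <- stats::setNames(tgt, src)
  colnames(vals) <- unname(lut[colnames(vals)])
  fold_change_matrix(vals,
                     adj_p = if (!is.null(fc$adj_p)) {
                       ap <- fc$adj_p[, keep, drop = FALSE]
                       colnames(ap) <- colnames(vals); ap
                     },
                     meta = fc$meta)
}

#' Permutation module-preservation statistics
#'
#' Quantifies whether modules defined on the reference corpus retain their
#' density and connectivity in a test dataset. For each module (restricted
#' to genes present in both datasets) four observed statistics are
#' computed on the test data's correlation structure (adjacency uses the
#' reference build's soft power): mean within-module adjacency and mean
#' |kME| (density class); correlation of intramodular connectivity
#' vectors, reference vs test, and correlation of the vectorized
#' within-module correlation matrices (connectivity class). A permutation
#' null reassigns module membership to random same-size gene sets from the
#' shared universe; `Z = (obs - mean_perm) / sd_perm`. `z_density` and
#' `z_connectivity` are the class medians and `z_summary` their mean;
#' `Z >= 2` is conventionally read as moderate and `>= 10` as high
#' preservation. `median_rank` (lower = better preserved, less
#' size-dependent) ranks modules by each observed statistic and takes the
#' per-module median, re-ranked into `1..M` with ties.
#'
#' Only this four-statistic subset of the published catalogue is
#' implemented; Z values are comparable within this tool only.
#'
#' @param ref_fc reference [fold_change_matrix()] (complete).
#' @param test_fc test [fold_change_matrix()] (complete; same gene
#'   namespace -- run [map_orthologs()] first if needed).
#' @param modules a [module_set()] built on the reference.
#' @param n_perm permutations, default `200` (minimum 50).
#' @param seed RNG seed (mandatory for reproducibility).
#' @param beta adjacency soft power, default `5`.
#' @return data.frame with one row per module: observed statistics, the
#'   four Z's, `z_density`, `z_connectivity`, `z_summary`, `median_rank`,
#'   `n_shared_genes`. Modules with fewer than 3 shared genes get NA
#'   statistics and are excluded from ranking.
#' @export
compute_preservation <- function(ref_fc, test_fc, modules, n_perm = 200L,
                                 seed = 1L, beta = 5L) {
  if (n_perm < 50L) stop2("`n_perm` must be >= 50")
  assert_complete(ref_fc, "preservation"); assert_complete(test_fc, "preservation")
  shared <- intersect(colnames(ref_fc$values), colnames(test_fc$values))
  if (length(shared) < 10L) stop2("fewer than 10 shared genes")
  zr <- scale(ref_fc$values[, shared, drop = FALSE])
  zt <- scale(test_fc$values[, shared, drop = FALSE])
  if (anyNA(zr) || anyNA(zt))
    stop2("zero-variance gene in the shared universe")
  groups <- lapply(modules$modules, function(m) {
    intersect(m$gene_ids, shared)
  })
  ids <- vapply(modules$modules, `[[`, integer(1L), "id")
  scored <- vapply(groups, length, integer(1L)) >= 3L
  if (sum(scored) < 2L) stop2("need >= 2 modules with >= 3 shared genes")
  if (any(!scored))
    message(sum(!scored), " module(s) with < 3 shared genes excluded")
  rng <- local_rng(seed)
  on.exit(rng$restore())
  obs <- matrix(NA_real_, length(groups), 4L,
                dimnames = list(ids, c("mean_adj", "mean_abs_kme",
                                       "cor_kim", "cor_cor")))
  zmat <- obs
  for (i in which(scored)) {
    s <- groups[[i]]
    obs[i, ] <- preservation_stats(zr, zt, match(s, shared), beta)
    perm <- matrix(NA_real_, n_perm, 4L)
    for (p in seq_len(n_perm)) {
      idx <- sample.int(length(shared), length(s))
      perm[p, ] <- preservation_stats(zr, zt, idx, beta)
    }
    mu <- colMeans(perm); sdv <- apply(perm, 2L, stats::sd)
    sdv[sdv < 1e-10] <- NA_real_   # degenerate null (e.g. test == ref)
    zmat[i, ] <- (obs[i, ] - mu) / sdv
  }
  ## a permutation null with zero spread (e.g. cor.kIM when test == ref:
  ## perfect for any gene set) carries no evidence; such statistics are NA
  ## and the class medians / summary are composed from informative ones
  z_density <- apply(zmat[, c("mean_adj", "mean_abs_kme"), drop = FALSE],
                     1L, stats::median, na.rm = TRUE)
  z_connectivity <- apply(zmat[, c("cor_kim", "cor_cor"), drop = FALSE],
                          1L, stats::median, na.rm = TRUE)
  z_density[is.nan(z_density)] <- NA_real_
  z_connectivity[is.nan(z_connectivity)] <- NA_real_
  z_summary <- rowMeans(cbind(z_density, z_connectivity), na.rm = TRUE)
  z_summary[scored & is.nan(z_summary)] <- NA_real_
  z_summary[!scored] <- NA_real_
  ## median rank of the observed statistics (rank 1 = strongest), re-ranked
  ## into 1..M with ties so ranks are directly comparable across runs
  rk <- apply(obs[scored, , drop = FALSE], 2L,
              function(v) rank(-v, ties.method = "average"))
  mr0 <- apply(rk, 1L, stats::median)
  median_rank <- rep(NA_real_, length(groups))
  median_rank[scored] <- rank(mr0, ties.method = "min")
  obs_df <- as.data.frame(obs); names(obs_df) <- paste0("obs_", names(obs_df))
  z_df <- as.data.frame(zmat); names(z_df) <- paste0("z_", names(z_df))
  out <- data.frame(module_id = ids,
                    n_shared_genes = vapply(groups, length, integer(1L)),
                    obs_df, z_df,
                    z_density = z_density,
                    z_connectivity = z_connectivity,
                    z_summary = z_summary,
                    median_rank = median_rank)
  rownames(out) <- NULL
  out
}

## the four statistics for gene indices `idx` into the shared universe;
## zr/zt are scaled reference/test matrices over the shared universe
preservation_stats <- function(zr, zt, idx, beta) {
  n_r <- nrow(zr); n_t <- nrow(zt)
  cr <- crossprod(zr[, idx, drop = FALSE]) / (n_r - 1)
  ct <- crossprod(zt[, idx, drop = FALSE]) / (n_t - 1)
  ar <- abs(cr)^beta; at <- abs(ct)^beta
  k <- length(idx)
  off <- upper.tri(ar)
  mean_adj <- mean(at[off])
  ## kME in test data: correlation of each member with the test eigengene
  eg <- module_eigengene(zt[, idx, drop = FALSE])
  kme <- drop(stats::cor(zt[, idx, drop = FALSE], eg))
  mean_abs_kme <- mean(abs(kme))
  kim_r <- rowSums(ar) - 1
  kim_t <- rowSums(at) - 1
  cor_kim <- if (stats::sd(kim_r) > 0 && stats::sd(kim_t) > 0)
    stats::cor(kim_r, kim_t) else 0
  vr <- cr[off]; vt <- ct[off]
  cor_cor <- if (stats::sd(vr) > 0 && stats::sd(vt) > 0)
    stats::cor(vr, vt) else 0
  c(mean_adj, mean_abs_kme, cor_kim, cor_cor)
}

#' Classify modules as preserved across two test systems
#'
#' A module is preserved when its Z-summary exceeds `z_min` in BOTH test
#' systems, or its median rank is within the top `rank_top` in BOTH.
#'
#' @param stats_a,stats_b data.frames from [compute_preservation()] against
#'   two test datasets, same module ids.
#' @param z_min Z-summary threshold, default `2`.
#' @param rank_top median-rank cutoff; default `NULL` uses
#'   `ceiling(rank_top_frac * M)`.
#' @param rank_top_frac fraction of modules for the rank rule when
#'   `rank_top` is not given, default `0.25`.
#' @return data.frame `module_id`, `preserved` (logical), plus the inputs'
#'   z_summary and median_rank columns.
#' @export
classify_preservation <- function(stats_a, stats_b, z_min = 2,
                                  rank_top = NULL, rank_top_frac = 0.25) {
  if (!identical(sort(stats_a$module_id), sort(stats_b$module_id)))
    stop2("the two preservation tables cover different module ids")
  b <- stats_b[match(stats_a$module_id, stats_b$module_id), ]
  m <- sum(!is.na(stats_a$z_summary))
  if (is.null(rank_top)) rank_top <- ceiling(rank_top_frac * m)
  z_rule <- stats_a$z_summary > z_min & b$z_summary > z_min
  r_rule <- stats_a$median_rank <= rank_top & b$median_rank <= rank_top
  preserved <- (z_rule | r_rule) %in% TRUE
  data.frame(module_id = stats_a$module_id,
             z_summary_a = stats_a$z_summary, z_summary_b = b$z_summary,
             median_rank_a = stats_a$median_rank, median_rank_b = b$median_rank,
             preserved = preserved)
}
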