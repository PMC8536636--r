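#' Project external data onto frozen modules
#'
#' Scores a new dataset against a frozen [module_set()] with the upload
#' formula: per member gene present in the external data,
#' `Z = log2FC / ref_gene_sd * corEG` (no mean centering); genes absent
#' from the upload, or NA in a given condition, contribute `Z = 0`
#' (which can attenuate scores at low coverage); the module score is
#' `sum(Z) / ref_sumz_sd`. Per-module coverage (fraction of member genes
#' measured) is reported alongside.
#'
#' @param modules a frozen [module_set()].
#' @param ext external [fold_change_matrix()] in the same gene-id
#'   namespace (map orthologs first, see [map_orthologs()]).
#' @param denominator `"sumz"` (default; SD of the corEG-weighted Z sum) or
#'   `"rawscore"` (SD of the raw PC1 score) as the normalization constant.
#' @return list of class `projected_scores`: `scores` (modules x external
#'   conditions), `coverage` (named per-module fraction), `denominator`.
#' @export
project_external <- function(modules, ext,
                             denominator = c("sumz", "rawscore")) {
  denominator <- match.arg(denominator)
  ext_genes <- colnames(ext$values)
  member_genes <- unlist(lapply(modules$modules, `[[`, "gene_ids"),
                         use.names = FALSE)
  if (!length(intersect(ext_genes, member_genes)))
    stop2("no external gene overlaps any module member")
  n_cond <- nrow(ext$values)
  ids <- vapply(modules$modules, function(m) as.character(m$id), character(1L))
  scores <- matrix(0, length(ids), n_cond,
                   dimnames = list(ids, rownames(ext$values)))
  coverage <- stats::setNames(numeric(length(ids)), ids)
  for (i in seq_along(modules$modules)) {
    m <- modules$modules[[i]]
    present <- intersect(m$gene_ids, ext_genes)
    coverage[i] <- length(present) / length(m$gene_ids)
    if (!length(present)) next                    # coverage 0 -> score 0
    x <- ext$values[, present, drop = FALSE]
    x[is.na(x)] <- 0                              # NA cells behave as absent
    w <- m$corEG[present] / m$ref_gene_sd[present]
    denom <- if (denominator == "sumz") m$ref_sumz_sd else m$ref_rawscore_sd
    scores[i, ] <- drop(x %*% w) / denom
  }
  structure(list(scores = scores, coverage = coverage,
                 denominator = denominator),
            class = "projected_scores")
}

#' @export
print.projected_scores <- function(x, ...) {
  cat(sprintf("<projected_scores> %d modules x %d conditions; mean coverage %.2f\n",
              nrow(x$scores), ncol(x$scores), mean(x$coverage)))
  invisible(x)
}

#' Coverage and gene-quality report for a measured gene panel
#'
#' For every module: its size, members present in the panel, coverage
#' fraction, and whether the hub gene is on the panel. The mean |corEG| of
#' the covered members is compared against an empirical null of `n_draws`
#' random same-size draws from the pooled member-gene |corEG| distribution
#' of the whole module set (one-sided, greater), with Bonferroni adjustment
#' across modules -- the gene-quality check for targeted panels.
#'
#' @param modules a frozen [module_set()].
#' @param panel character vector of measured gene ids.
#' @param n_draws random draws for the empirical null, default `1000`.
#' @param seed RNG seed for the draws, default `1`.
#' @return data.frame with one row per module: `module_id`, `size`,
#'   `n_in_panel`, `coverage`, `hub_in_panel`, `mean_abs_coreg`,
#'   `null_mean`, `p_empirical`, `p_bonferroni`. Attributes
#'   `"panel_mean_abs_coreg"` and `"panel_p"` carry the panel-level
#'   gene-quality comparison (all covered members vs equal-size random
#'   draws).
#' @export
coverage_report <- function(modules, panel, n_draws = 1000L, seed = 1L) {
  pool <- abs(unlist(lapply(modules$modules, `[[`, "corEG"),
                     use.names = FALSE))
  rows <- lapply(modules$modules, function(m) {
    present <- intersect(m$gene_ids, panel)
    data.frame(module_id = m$id,
               size = length(m$gene_ids),
               n_in_panel = length(present),
               coverage = length(present) / length(m$gene_ids),
               hub_in_panel = m$hub_gene %in% panel,
               mean_abs_coreg = if (length(present))
                 mean(abs(m$corEG[present])) else NA_real_)
  })
  out <- do.call(rbind, rows)
  out$null_mean <- NA_real_
  out$p_empirical <- NA_real_
  rng <- local_rng(seed)
  for (i in seq_len(nrow(out))) {
    k <- out$n_in_panel[i]
    if (k == 0L) next
    null_means <- vapply(seq_len(n_draws), function(j)
      mean(sample(pool, k)), numeric(1L))
    out$null_mean[i] <- mean(null_means)
    out$p_empirical[i] <- (1 + sum(null_means >= out$mean_abs_coreg[i])) /
      (n_draws + 1)
  }
  ## panel-level gene-quality test: mean |corEG| of every covered member
  ## vs random draws of the same total size from the member pool
  covered_vals <- unlist(lapply(modules$modules, function(m)
    abs(m$corEG[intersect(m$gene_ids, panel)])), use.names = FALSE)
  if (length(covered_vals)) {
    obs <- mean(covered_vals)
    null_means <- vapply(seq_len(n_draws), function(j)
      mean(sample(pool, length(covered_vals))), numeric(1L))
    attr(out, "panel_mean_abs_coreg") <- obs
    attr(out, "panel_p") <- (1 + sum(null_means >= obs)) / (n_draws + 1)
  }
  rng$restore()
  out$p_bonferroni <- pmin(1, out$p_empirical * sum(!is.na(out$p_empirical)))
  out
}

## scoped RNG: seed without clobbering the caller's RNG state
local_rng <- function(seed) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv())
  set.seed(seed)
  list(restore = function() {
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
}
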