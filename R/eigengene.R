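#' Standardize the reference corpus gene-wise
#'
#' Per-gene Z-score conversion `(x - mean) / sd` with the sample (n-1)
#' standard deviation, applied across conditions. The eigengene of each
#' module is the first principal component of this standardized matrix.
#'
#' @param fc complete [fold_change_matrix()].
#' @return an `fc_matrix` with per-gene mean 0 and sample SD 1.
#' @export
standardize_reference <- function(fc) {
  assert_complete(fc, "standardization")
  sds <- col_sds(fc$values)
  if (any(sds == 0))
    stop2("zero-SD gene cannot be standardized: ",
          colnames(fc$values)[which(sds == 0)[1L]])
  z <- sweep(sweep(fc$values, 2L, colMeans(fc$values)), 2L, sds, "/")
  fold_change_matrix(z, adj_p = fc$adj_p, meta = fc$meta)
}

## raw eigengene of a standardized conditions x genes submatrix: the unit
## left singular vector of X, computed through the (genes x genes) cross
## product, oriented positively with the member-mean profile
module_eigengene <- function(x) {
  x <- as.matrix(x)
  if (ncol(x) == 1L) {
    raw <- x[, 1L] / sqrt(sum(x[, 1L]^2))
  } else {
    cp <- crossprod(x)
    eg <- eigen(cp, symmetric = TRUE)
    v1 <- eg$vectors[, 1L]
    lambda1 <- eg$values[1L]
    if (lambda1 <= 0) stop2("degenerate module submatrix (all zeros)")
    raw <- drop(x %*% v1) / sqrt(lambda1)
  }
  orient_eigengene(raw, x)
}

orient_eigengene <- function(raw, x) {
  m <- rowMeans(x)
  s <- if (stats::sd(m) > 0 && stats::sd(raw) > 0) {
    sign(stats::cor(raw, m))
  } else 0
  if (s == 0) s <- sign(sum(crossprod(x, raw)))   # sum of loadings
  if (s == 0) s <- 1
  raw * s
}

#' Compute normalized module eigengene scores
#'
#' For each module, the raw score is the first principal component of the
#' conditions x member-genes submatrix of the standardized reference,
#' oriented so that it correlates non-negatively with the per-condition
#' mean of member Z-values, then scaled to unit sample SD across the
#' reference conditions.
#'
#' @param modules a [module_set()], a `module_assignment`, or a named list
#'   of gene-id vectors (names = module ids).
#' @param zfc standardized reference matrix from [standardize_reference()].
#' @return an `eigengene_matrix`: a modules x conditions numeric matrix
#'   (rownames are module ids) with attribute `"rawscore_sd"`, the per-
#'   module sample SD of the raw score.
#' @export
compute_module_scores <- function(modules, zfc) {
  groups <- module_gene_groups(modules)
  if (nrow(zfc$values) < 2L) stop2("need >= 2 conditions for eigengenes")
  missing <- setdiff(unlist(groups, use.names = FALSE), colnames(zfc$values))
  if (length(missing))
    stop2("module gene absent from the matrix: ", missing[1L])
  n_cond <- nrow(zfc$values)
  scores <- matrix(NA_real_, length(groups), n_cond,
                   dimnames = list(names(groups), rownames(zfc$values)))
  raw_sd <- stats::setNames(numeric(length(groups)), names(groups))
  for (i in seq_along(groups)) {
    raw <- module_eigengene(zfc$values[, groups[[i]], drop = FALSE])
    raw_sd[i] <- sample_sd(raw)
    if (raw_sd[i] == 0) stop2("module ", names(groups)[i],
                              ": raw eigengene score is constant")
    scores[i, ] <- raw / raw_sd[i]
  }
  structure(scores, rawscore_sd = raw_sd, class = c("eigengene_matrix", "matrix"))
}

module_gene_groups <- function(modules) {
  if (inherits(modules, "module_set")) {
    groups <- lapply(modules$modules, `[[`, "gene_ids")
    names(groups) <- vapply(modules$modules, function(m) as.character(m$id),
                            character(1L))
  } else if (inherits(modules, "module_assignment")) {
    lab <- modules$labels
    groups <- split(names(lab)[lab > 0L], lab[lab > 0L])
  } else if (is.list(modules)) {
    groups <- modules
    if (is.null(names(groups))) names(groups) <- as.character(seq_along(groups))
  } else stop2("unsupported module specification")
  empty <- vapply(groups, length, integer(1L)) == 0L
  if (any(empty)) stop2("module ", names(groups)[empty][1L], " has no genes")
  groups[order(as.integer(names(groups)))]
}

#' Per-gene module statistics and reference constants
#'
#' For every member gene: `corEG`, the Pearson correlation between its raw
#' log2FC profile and the parent module eigengene across the reference
#' conditions (negative values indicate inverse members); `ref_gene_sd`,
#' the sample SD of its raw log2FC. The hub gene is the member with the
#' highest corEG (`hub = "signed"`, ties broken lexicographically), or the
#' highest |corEG| with `hub = "abs"`. The projection denominator
#' `ref_sumz_sd` is precomputed as the sample SD across reference
#' conditions of the corEG-weighted Z sum.
#'
#' @param modules module specification as in [compute_module_scores()].
#' @param fc raw (unstandardized) reference [fold_change_matrix()].
#' @param egs `eigengene_matrix` from [compute_module_scores()] on the same
#'   conditions.
#' @param hub `"signed"` (default) or `"abs"`.
#' @param universe gene universe stored on the result; defaults to all
#'   genes in `fc`.
#' @param reference_label stored on the result.
#' @return a frozen [module_set()].
#' @export
compute_gene_stats <- function(modules, fc, egs, hub = c("signed", "abs"),
                               universe = colnames(fc$values),
                               reference_label = "") {
  hub <- match.arg(hub)
  groups <- module_gene_groups(modules)
  if (!identical(colnames(egs), rownames(fc$values)))
    stop2("eigengene conditions do not match the fold-change matrix")
  out <- vector("list", length(groups))
  for (i in seq_along(groups)) {
    id <- names(groups)[i]
    genes <- groups[[i]]
    x <- fc$values[, genes, drop = FALSE]
    sds <- col_sds(x)
    if (any(sds == 0))
      stop2("constant gene '", genes[which(sds == 0)[1L]],
            "': corEG undefined")
    e <- egs[id, ]
    coreg <- drop(stats::cor(x, e))
    names(coreg) <- genes
    hub_gene <- if (hub == "signed") {
      genes[order(-coreg, genes)][1L]
    } else {
      genes[order(-abs(coreg), genes)][1L]
    }
    sumz <- drop(sweep(x, 2L, sds, "/") %*% coreg)
    out[[i]] <- list(id = as.integer(id),
                     gene_ids = genes,
                     corEG = coreg,
                     hub_gene = hub_gene,
                     ref_gene_sd = stats::setNames(sds, genes),
                     ref_sumz_sd = sample_sd(sumz),
                     ref_rawscore_sd = unname(attr(egs, "rawscore_sd")[id]))
  }
  module_set(out, universe = universe, reference_label = reference_label)
}

## standardize + score + gene stats in one pass over a labeled assignment
freeze_module_set <- function(labels, fc, zfc = NULL, reference_label = "",
                              hub = "signed") {
  if (is.null(zfc)) zfc <- standardize_reference(fc)
  groups <- split(names(labels)[labels > 0L], labels[labels > 0L])
  egs <- compute_module_scores(groups, zfc)
  compute_gene_stats(groups, fc, egs, hub = hub,
                     universe = names(labels),
                     reference_label = reference_label)
}

#' Flag large module perturbations
#'
#' A normalized eigengene score greater than `+threshold` or smaller than
#' `-threshold` (strict inequalities) marks a large, biologically relevant
#' perturbation in the context of the reference corpus.
#'
#' @param egs an `eigengene_matrix` (or any numeric matrix of scores).
#' @param threshold positive cut, default `2`.
#' @return logical matrix of the same shape.
#' @export
flag_perturbations <- function(egs, threshold = 2) {
  if (!is_scalar_number(threshold) || threshold <= 0)
    stop2("`threshold` must be a positive number")
  m <- unclass(egs)
  attr(m, "rawscore_sd") <- NULL
  m > threshold | m < -threshold
}

#' Percent dimensionality reduction of the module representation
#'
#' Going from `n_genes` gene-level features to `n_modules` module scores.
#'
#' @param n_genes number of gene features.
#' @param n_modules number of module scores.
#' @param digits decimals to round the percentage to, default 1.
#' @return percentage reduction, e.g. `97.7`.
#' @export
dimensionality_reduction <- function(n_genes, n_modules, digits = 1L) {
  round(100 * (1 - n_modules / n_genes), digits)
}
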