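#' Hypergeometric over-representation of one gene set in one module
#'
#' Exact upper-tail probability `P(X >= k)` for the overlap `k` between a
#' module of size `n` and a gene set of size `K` inside a universe of size
#' `N` (the set is intersected with the universe before testing).
#'
#' @param module_genes member genes of the module (must lie in `universe`).
#' @param gene_set annotated gene set.
#' @param universe background gene ids.
#' @return one-row data.frame: `k`, `K`, `n`, `N`, `p`.
#' @export
ora_module <- function(module_genes, gene_set, universe) {
  if (!length(universe)) stop2("empty universe")
  if (!length(module_genes)) stop2("empty module")
  if (length(setdiff(module_genes, universe)))
    stop2("module gene outside the universe: ",
          setdiff(module_genes, universe)[1L])
  set <- intersect(gene_set, universe)
  k <- length(intersect(module_genes, set))
  K <- length(set); n <- length(module_genes); N <- length(universe)
  p <- stats::phyper(k - 1L, K, N - K, n, lower.tail = FALSE)
  data.frame(k = k, K = K, n = n, N = N, p = p)
}

#' Enrich all modules against a gene-set collection
#'
#' Hypergeometric tests for every module x set pair with BH adjustment
#' across all pairs in the collection (one joint family). The full table
#' keeps rows with `p < p_cut`; the per-module annotation keeps at most
#' `top_n` rows by ascending p with `fdr < fdr_cut`.
#'
#' @param modules a [module_set()]; its `universe` is the ORA background.
#' @param collection a `gene_set_collection` from [read_gene_sets()].
#' @param p_cut nominal p cut for the full table, default `0.01`.
#' @param top_n annotation rows per module, default `10`.
#' @param fdr_cut BH cut for annotation rows, default `0.05`.
#' @return list with `table` (rows `module_id`, `set_name`, `k`, `K`, `n`,
#'   `N`, `p`, `fdr`, filtered at `p < p_cut`) and `annotation` (top rows
#'   per module; modules with no qualifying set appear with NA set_name).
#' @export
enrich_modules <- function(modules, collection, p_cut = 0.01, top_n = 10L,
                           fdr_cut = 0.05) {
  universe <- modules$universe
  sets <- lapply(collection$sets, intersect, universe)
  keep <- vapply(sets, length, integer(1L)) > 0L
  sets <- sets[keep]
  rows <- list()
  for (m in modules$modules) {
    for (s in names(sets)) {
      r <- ora_module(m$gene_ids, sets[[s]], universe)
      r$module_id <- m$id; r$set_name <- s
      rows[[length(rows) + 1L]] <- r
    }
  }
  tab <- do.call(rbind, rows)
  tab$fdr <- stats::p.adjust(tab$p, method = "BH")
  tab <- tab[, c("module_id", "set_name", "k", "K", "n", "N", "p", "fdr")]
  full <- tab[tab$p < p_cut, , drop = FALSE]
  full <- full[order(full$module_id, full$p), , drop = FALSE]
  rownames(full) <- NULL
  ann <- lapply(modules$modules, function(m) {
    sub <- full[full$module_id == m$id & full$fdr < fdr_cut, , drop = FALSE]
    if (!nrow(sub))
      return(data.frame(module_id = m$id, set_name = NA_character_,
                        k = NA_integer_, K = NA_integer_, n = NA_integer_,
                        N = NA_integer_, p = NA_real_, fdr = NA_real_))
    utils::head(sub[order(sub$p), , drop = FALSE], top_n)
  })
  annotation <- do.call(rbind, ann)
  rownames(annotation) <- NULL
  list(table = full, annotation = annotation)
}

#' Transcription-factor regulon enrichment per module
#'
#' Filters regulon targets to a confidence tier -- `"high_confidence"`
#' keeps classes A-C, `"high_coverage"` classes A-D -- and runs the same
#' hypergeometric ORA per (module, TF), ignoring the sign of regulation.
#'
#' @param modules a [module_set()].
#' @param regulons a `regulon_collection` from [read_regulons()].
#' @param confidence `"high_confidence"` (default) or `"high_coverage"`.
#' @param p_cut nominal p cut, default `0.01`.
#' @return data.frame of rows with `p < p_cut`: `module_id`, `tf`, `k`,
#'   `K`, `n`, `N`, `p`, `fdr` (BH across all module x TF tests).
#' @export
tf_enrichment <- function(modules, regulons,
                          confidence = c("high_confidence", "high_coverage"),
                          p_cut = 0.01) {
  confidence <- match.arg(confidence)
  classes <- if (confidence == "high_confidence") c("A", "B", "C")
             else c("A", "B", "C", "D")
  universe <- modules$universe
  rows <- list()
  for (tf in names(regulons$regulons)) {
    reg <- regulons$regulons[[tf]]
    targets <- intersect(reg$target[reg$confidence %in% classes], universe)
    if (!length(targets)) {
      message("TF '", tf, "' has no targets in the universe; skipped")
      next
    }
    for (m in modules$modules) {
      r <- ora_module(m$gene_ids, targets, universe)
      r$module_id <- m$id; r$tf <- tf
      rows[[length(rows) + 1L]] <- r
    }
  }
  if (!length(rows)) return(data.frame())
  tab <- do.call(rbind, rows)
  tab$fdr <- stats::p.adjust(tab$p, method = "BH")
  tab <- tab[, c("module_id", "tf", "k", "K", "n", "N", "p", "fdr")]
  out <- tab[tab$p < p_cut, , drop = FALSE]
  out <- out[order(out$module_id, out$p), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Surrogate TF activity scores per condition
#'
#' A simple signed, variance-normalized surrogate for regulon-based
#' normalized enrichment scores (the published NES algorithm is not
#' reproduced; these values are labeled surrogate-NES and are comparable
#' only within this tool): for each TF with `m >= 3` measured targets in a
#' condition, `nes = sum(mode_t * log2FC_t / sd_t) / sqrt(m)`. Under
#' independent standard-normal target scores the surrogate is mean 0,
#' SD 1.
#'
#' @param regulons a `regulon_collection`.
#' @param fc external or reference [fold_change_matrix()].
#' @param ref_sd optional named per-gene SD vector (typically
#'   `ref_gene_sd` pooled from a frozen [module_set()], see
#'   [reference_gene_sds()]); genes without an entry fall back to their own
#'   SD across `fc`.
#' @return TFs x conditions matrix of surrogate-NES values; TFs with fewer
#'   than 3 measured targets in the data are NA.
#' @export
tf_activity <- function(regulons, fc, ref_sd = NULL) {
  genes <- colnames(fc$values)
  own_sd <- col_sds(fc$values)
  sds <- own_sd
  if (!is.null(ref_sd)) {
    hit <- intersect(names(ref_sd), genes)
    sds[hit] <- ref_sd[hit]
  }
  tfs <- names(regulons$regulons)
  out <- matrix(NA_real_, length(tfs), nrow(fc$values),
                dimnames = list(tfs, rownames(fc$values)))
  for (tf in tfs) {
    reg <- regulons$regulons[[tf]]
    hit <- reg$target %in% genes & sds[reg$target] > 0
    reg <- reg[hit, , drop = FALSE]
    x <- fc$values[, reg$target, drop = FALSE]
    z <- sweep(x, 2L, sds[reg$target], "/")
    z_signed <- sweep(z, 2L, reg$mode, "*")
    m_cond <- rowSums(!is.na(z_signed))
    s <- rowSums(z_signed, na.rm = TRUE)
    nes <- ifelse(m_cond >= 3L, s / sqrt(m_cond), NA_real_)
    out[tf, ] <- nes
  }
  out
}

#' Pool per-gene reference SDs from a frozen module set
#'
#' @param modules a [module_set()].
#' @return named numeric vector over all member genes.
#' @export
reference_gene_sds <- function(modules) {
  unlist(lapply(modules$modules, `[[`, "ref_gene_sd"))
}
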