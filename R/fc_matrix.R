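#' Treatment x gene log2 fold-change matrix
#'
#' The central data container: a conditions x genes numeric matrix of log2
#' fold-changes, an optional matching grid of BH-adjusted p-values, and
#' per-condition metadata (compound, time point, dose) parsed from the
#' condition identifiers.
#'
#' Missing values (`NA`) are permitted in `values`; operations that require
#' a complete matrix (network construction, eigengene scoring) reject them,
#' so impute first (see [impute_conditions()]) or subset.
#'
#' @param values numeric matrix, conditions in rows, genes in columns, with
#'   unique dimnames on both axes.
#' @param adj_p optional numeric matrix of BH-adjusted p-values in `[0, 1]`,
#'   identical dimnames to `values`.
#' @param meta optional data.frame of per-condition metadata with columns
#'   `condition_id`, `compound`, `time`, `dose`. When `NULL` it is parsed
#'   from the condition ids with `id_pattern`.
#' @param id_pattern PCRE with named groups `compound`, `time`, `dose`
#'   applied to condition ids; conditions that do not match get `NA`
#'   metadata rather than failing.
#' @return An object of class `fc_matrix`: a list with elements `values`,
#'   `adj_p`, `meta`.
#' @examples
#' m <- matrix(rnorm(6), 2, 3,
#'             dimnames = list(c("CPDA_24 hr_LO", "CPDA_24 hr_HI"),
#'                             c("g1", "g2", "g3")))
#' fc <- fold_change_matrix(m)
#' fc$meta$dose
#' @export
fold_change_matrix <- function(values, adj_p = NULL, meta = NULL,
                               id_pattern = default_condition_pattern()) {
  if (!is.matrix(values) || !is.numeric(values))
    stop2("`values` must be a numeric matrix (conditions x genes)")
  cid <- rownames(values); gid <- colnames(values)
  if (is.null(cid) || is.null(gid))
    stop2("`values` must carry condition rownames and gene colnames")
  dup <- cid[duplicated(cid)]
  if (length(dup)) stop2("duplicate condition id: ", dup[1L])
  dup <- gid[duplicated(gid)]
  if (length(dup)) stop2("duplicate gene id: ", dup[1L])
  bad <- which(!is.na(values) & !is.finite(values))
  if (length(bad)) stop2("non-finite fold-change value at position ", bad[1L])
  if (!is.null(adj_p)) {
    if (!is.matrix(adj_p) || !identical(dim(adj_p), dim(values)))
      stop2("`adj_p` must be a matrix with the same shape as `values`")
    if (!identical(rownames(adj_p), cid) || !identical(colnames(adj_p), gid))
      stop2("`adj_p` dimnames must match `values`")
    rng <- range(adj_p, na.rm = TRUE)
    if (any(is.finite(rng)) && (rng[1] < 0 || rng[2] > 1))
      stop2("`adj_p` values must lie in [0, 1]")
  }
  if (is.null(meta)) meta <- parse_condition_meta(cid, id_pattern)
  structure(list(values = values, adj_p = adj_p, meta = meta),
            class = "fc_matrix")
}

#' @export
print.fc_matrix <- function(x, ...) {
  cat(sprintf("<fc_matrix> %d conditions x %d genes; adj_p: %s; NA values: %d\n",
              nrow(x$values), ncol(x$values),
              if (is.null(x$adj_p)) "absent" else "present",
              sum(is.na(x$values))))
  invisible(x)
}

#' @export
dim.fc_matrix <- function(x) dim(x$values)

#' Default condition-id metadata pattern
#'
#' Condition ids of the form `compound_time_dose`
#' (e.g. `"CSA_24 hr_HI"`) are split into metadata fields.
#' @return a PCRE string with named capture groups.
#' @export
default_condition_pattern <- function() {
  "^(?<compound>[^_]+)_(?<time>[^_]+)_(?<dose>[^_]+)$"
}

parse_condition_meta <- function(condition_ids, pattern) {
  out <- data.frame(condition_id = condition_ids,
                    compound = NA_character_,
                    time = NA_character_,
                    dose = NA_character_,
                    stringsAsFactors = FALSE)
  m <- regexpr(pattern, condition_ids, perl = TRUE)
  ok <- m > 0L
  if (any(ok)) {
    st <- attr(m, "capture.start")[ok, , drop = FALSE]
    len <- attr(m, "capture.length")[ok, , drop = FALSE]
    for (f in c("compound", "time", "dose")) {
      if (!f %in% colnames(st)) next
      out[[f]][ok] <- substr(condition_ids[ok], st[, f], st[, f] + len[, f] - 1L)
    }
  }
  out
}

## subset an fc_matrix to a gene set (order preserved as given)
subset_genes <- function(fc, genes) {
  missing <- setdiff(genes, colnames(fc$values))
  if (length(missing))
    stop2("gene not present in matrix: ", missing[1L])
  fold_change_matrix(fc$values[, genes, drop = FALSE],
                     adj_p = if (!is.null(fc$adj_p)) fc$adj_p[, genes, drop = FALSE],
                     meta = fc$meta)
}

assert_complete <- function(fc, what = "this operation") {
  if (anyNA(fc$values))
    stop2(what, " requires a complete matrix; impute or drop missing values first")
}
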