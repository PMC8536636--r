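#' Read a delimited fold-change table
#'
#' Reads a TSV/CSV table of log2 fold-changes with a header of gene ids (or
#' condition ids, depending on `orientation`) plus an optional companion
#' table of BH-adjusted p-values with identical axes.
#'
#' @param path path to the delimited table. The first column holds the row
#'   identifiers.
#' @param orientation `"conditions-as-rows"` (default) or `"genes-as-rows"`;
#'   the result is always normalized to conditions x genes.
#' @param adjp_path optional path to the matching adjusted-p table.
#' @param sep field separator; `"\t"` for TSV (default), `","` for CSV.
#' @param missing_token string treated as missing (default `"NA"`).
#' @param duplicate_genes `"error"` (default) rejects duplicated gene ids;
#'   `"resolve"` keeps, per gene, the row/column with the smallest
#'   adjusted p-value (when `adjp_path` is given) or else the largest
#'   absolute log2FC, as is customary when multiple probes map to a gene.
#' @param id_pattern condition-id metadata pattern, see
#'   [default_condition_pattern()].
#' @return an [fold_change_matrix()] object.
#' @export
read_foldchange_table <- function(path,
                                  orientation = c("conditions-as-rows",
                                                  "genes-as-rows"),
                                  adjp_path = NULL,
                                  sep = "\t",
                                  missing_token = "NA",
                                  duplicate_genes = c("error", "resolve"),
                                  id_pattern = default_condition_pattern()) {
  orientation <- match.arg(orientation)
  duplicate_genes <- match.arg(duplicate_genes)
  vals <- read_numeric_grid(path, sep, missing_token)
  if (orientation == "genes-as-rows") vals <- t(vals)
  adj_p <- NULL
  if (!is.null(adjp_path)) {
    adj_p <- read_numeric_grid(adjp_path, sep, missing_token)
    if (orientation == "genes-as-rows") adj_p <- t(adj_p)
    if (!identical(dim(adj_p), dim(vals)) ||
        !identical(rownames(adj_p), rownames(vals)) ||
        !identical(colnames(adj_p), colnames(vals)))
      stop2("adjusted-p table axes do not match the fold-change table")
  }
  gid <- colnames(vals)
  if (anyDuplicated(gid)) {
    if (duplicate_genes == "error")
      stop2("duplicate gene id: ", gid[duplicated(gid)][1L])
    res <- resolve_duplicate_genes(vals, adj_p)
    vals <- res$values; adj_p <- res$adj_p
  }
  fold_change_matrix(vals, adj_p = adj_p, id_pattern = id_pattern)
}

read_numeric_grid <- function(path, sep, missing_token) {
  df <- utils::read.delim(path, sep = sep, header = TRUE,
                          check.names = FALSE, stringsAsFactors = FALSE,
                          na.strings = missing_token, colClasses = "character")
  if (ncol(df) < 2L) stop2("table has no data columns: ", path)
  rn <- df[[1L]]
  if (anyDuplicated(rn))
    stop2("duplicate row id: ", rn[duplicated(rn)][1L])
  body <- df[, -1L, drop = FALSE]
  num <- suppressWarnings(vapply(body, as.numeric, numeric(nrow(body))))
  if (nrow(body) == 1L) num <- matrix(num, nrow = 1L)
  ## both `[.data.frame` and vapply() make.unique duplicated column names;
  ## restore the originals so duplicate gene ids are detected downstream
  colnames(num) <- colnames(df)[-1L]
  bad <- which(is.na(num) & !is.na(as.matrix(body)), arr.ind = TRUE)
  if (nrow(bad) > 0L)
    stop2("non-numeric cell '", as.matrix(body)[bad[1L, 1L], bad[1L, 2L]],
          "' at row '", rn[bad[1L, 1L]], "', column '",
          colnames(body)[bad[1L, 2L]], "'")
  rownames(num) <- rn
  num
}

#' Collapse duplicate gene measurements
#'
#' When a platform measures a gene more than once (multiple probes), keep a
#' single column per gene: the one with the smallest minimum adjusted
#' p-value when an adjusted-p grid is available, otherwise the one with the
#' largest maximum absolute log2FC.
#'
#' @param values conditions x genes matrix, possibly with duplicated
#'   colnames.
#' @param adj_p optional matching adjusted-p matrix.
#' @return list with de-duplicated `values` and `adj_p`.
#' @export
resolve_duplicate_genes <- function(values, adj_p = NULL) {
  gid <- colnames(values)
  if (!anyDuplicated(gid)) return(list(values = values, adj_p = adj_p))
  crit <- if (!is.null(adj_p)) {
    -apply(adj_p, 2L, min, na.rm = TRUE)  # larger = more significant
  } else {
    apply(abs(values), 2L, max, na.rm = TRUE)
  }
  keep <- vapply(split(seq_along(gid), gid), function(idx) {
    idx[which.max(crit[idx])]
  }, integer(1L))
  keep <- sort(unname(keep))
  n_drop <- length(gid) - length(keep)
  message(sprintf("resolved %d duplicate gene measurement(s) by %s", n_drop,
                  if (!is.null(adj_p)) "smallest adjusted p" else "largest |log2FC|"))
  list(values = values[, keep, drop = FALSE],
       adj_p = if (!is.null(adj_p)) adj_p[, keep, drop = FALSE])
}

#' Read a GMT gene-set collection
#'
#' Standard GMT dialect: one set per line, tab-separated
#' `name <TAB> description <TAB> member...`. Empty sets are dropped with a
#' warning; duplicated set names are an error.
#'
#' @param path path to a GMT file.
#' @return a list of class `gene_set_collection` with elements `sets`
#'   (named list of character vectors) and `source`.
#' @export
read_gene_sets <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  sets <- list()
  for (i in seq_along(lines)) {
    f <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1L]]
    if (length(f) < 2L)
      stop2("malformed GMT line ", i, ": fewer than 2 fields")
    nm <- f[1L]
    if (nm %in% names(sets)) stop2("duplicate gene-set name: ", nm)
    members <- unique(f[-c(1L, 2L)])
    members <- members[nzchar(members)]
    if (!length(members)) {
      warn2("gene set '", nm, "' has no members and was dropped")
      next
    }
    sets[[nm]] <- members
  }
  structure(list(sets = sets, source = path), class = "gene_set_collection")
}

#' Read a transcription-factor regulon table
#'
#' Four tab-separated columns with header: `tf`, `target`,
#' `mode` (`+1`/`-1`, or `A` for activation / `I` for inhibition) and
#' `confidence` (one of `A`-`E`).
#'
#' @param path path to the regulon TSV.
#' @return list of class `regulon_collection`; `regulons` maps each TF name
#'   to a data.frame with columns `target`, `mode` (+1/-1), `confidence`.
#' @export
read_regulons <- function(path) {
  df <- utils::read.delim(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE, colClasses = "character")
  need <- c("tf", "target", "mode", "confidence")
  if (!all(need %in% names(df)))
    stop2("regulon table must have columns: ", paste(need, collapse = ", "))
  mode <- ifelse(df$mode %in% c("+1", "1", "A"), 1,
                 ifelse(df$mode %in% c("-1", "I"), -1, NA))
  if (anyNA(mode))
    stop2("unrecognized regulation mode '", df$mode[which(is.na(mode))[1L]], "'")
  if (!all(df$confidence %in% LETTERS[1:5]))
    stop2("confidence class must be one of A-E; got '",
          setdiff(df$confidence, LETTERS[1:5])[1L], "'")
  key <- paste(df$tf, df$target, sep = "\r")
  if (anyDuplicated(key)) {
    d <- df[duplicated(key), , drop = FALSE]
    stop2("duplicate (tf, target) pair: ", d$tf[1L], " / ", d$target[1L])
  }
  df$mode <- as.numeric(mode)
  structure(list(regulons = split(df[c("target", "mode", "confidence")], df$tf),
                 source = path),
            class = "regulon_collection")
}

#' Read a two-column ortholog map
#'
#' @param path TSV with header and two columns: source id, target id.
#' @return data.frame with columns `source_id`, `target_id`.
#' @export
read_ortholog_map <- function(path) {
  df <- utils::read.delim(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE, colClasses = "character")
  if (ncol(df) < 2L) stop2("ortholog map needs two columns")
  out <- data.frame(source_id = df[[1L]], target_id = df[[2L]],
                    stringsAsFactors = FALSE)
  out
}

#' Read a donor x trait table
#'
#' TSV of binary trait indicators: first column donor id, remaining columns
#' traits, cells in `{0, 1, NA}`.
#'
#' @param path path to the trait TSV.
#' @return list of class `trait_matrix` with `values` (donors x traits 0/1
#'   matrix, NA allowed), `donor_ids`, `trait_names`.
#' @export
read_traits <- function(path) {
  m <- read_numeric_grid(path, "\t", "NA")
  trait_matrix(m)
}

#' Construct a donor x trait matrix
#'
#' @param values donors x traits matrix of 0/1 (NA allowed), with dimnames.
#' @return a `trait_matrix` object.
#' @export
trait_matrix <- function(values) {
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop2("trait matrix needs donor rownames and trait colnames")
  if (anyDuplicated(rownames(values)))
    stop2("duplicate donor id: ", rownames(values)[duplicated(rownames(values))][1L])
  ok <- is.na(values) | values %in% c(0, 1)
  if (!all(ok)) stop2("trait values must be 0, 1 or NA")
  structure(list(values = values,
                 donor_ids = rownames(values),
                 trait_names = colnames(values)),
            class = "trait_matrix")
}

#' Write a matrix as a TSV with a leading id column
#'
#' @param m matrix with dimnames.
#' @param path output path.
#' @param id_name header for the id column.
#' @export
write_matrix_tsv <- function(m, path, id_name = "id") {
  df <- data.frame(rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  colnames(df)[1L] <- id_name
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
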