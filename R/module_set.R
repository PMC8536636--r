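MODULE_SCHEMA_VERSION <- "1.0"

#' Frozen module definitions
#'
#' A `module_set` is a hard partition of (a subset of) the build-time gene
#' universe into numbered modules. Each module carries the per-gene
#' eigengene correlations (`corEG`), the hub gene, and the reference
#' normalization constants needed to project external data:
#' `ref_gene_sd` (per-gene SD of log2FC across the reference corpus),
#' `ref_sumz_sd` (SD of the corEG-weighted Z sum) and `ref_rawscore_sd`
#' (SD of the raw first-principal-component score). Genes in `universe`
#' that belong to no module form the implicit "gray" pool.
#'
#' @param modules list of module records; each a list with elements `id`
#'   (positive integer), `gene_ids`, `corEG` (named numeric), `hub_gene`,
#'   `ref_gene_sd` (named numeric, > 0), `ref_sumz_sd` (> 0),
#'   `ref_rawscore_sd` (> 0).
#' @param universe character vector of all gene ids used at build time.
#' @param reference_label free-text label of the reference corpus.
#' @return object of class `module_set`.
#' @export
module_set <- function(modules, universe, reference_label = "") {
  ids <- vapply(modules, function(m) as.integer(m$id), integer(1L))
  if (any(ids < 1L)) stop2("module ids must be positive integers")
  if (anyDuplicated(ids)) stop2("duplicate module id: ", ids[duplicated(ids)][1L])
  all_genes <- unlist(lapply(modules, `[[`, "gene_ids"), use.names = FALSE)
  if (anyDuplicated(all_genes))
    stop2("gene assigned to more than one module: ",
          all_genes[duplicated(all_genes)][1L])
  if (length(setdiff(all_genes, universe)))
    stop2("module gene missing from universe: ",
          setdiff(all_genes, universe)[1L])
  modules <- lapply(modules, validate_module)
  modules <- modules[order(ids)]
  structure(list(modules = modules, universe = universe,
                 reference_label = reference_label),
            class = "module_set")
}

validate_module <- function(m) {
  m$id <- as.integer(m$id)
  if (!is.character(m$gene_ids) || !length(m$gene_ids))
    stop2("module ", m$id, ": empty gene list")
  if (!m$hub_gene %in% m$gene_ids)
    stop2("module ", m$id, ": hub gene '", m$hub_gene,
          "' is not a member gene")
  for (f in c("corEG", "ref_gene_sd")) {
    v <- m[[f]]
    if (is.null(v) || !identical(sort(names(v)), sort(m$gene_ids)))
      stop2("module ", m$id, ": `", f, "` must be named over the member genes")
    m[[f]] <- v[m$gene_ids]
  }
  if (any(abs(m$corEG) > 1 + 1e-8))
    stop2("module ", m$id, ": |corEG| exceeds 1")
  if (any(m$ref_gene_sd <= 0))
    stop2("module ", m$id, ": ref_gene_sd must be positive")
  for (f in c("ref_sumz_sd", "ref_rawscore_sd")) {
    if (!is_scalar_number(m[[f]]) || m[[f]] <= 0)
      stop2("module ", m$id, ": `", f, "` must be a positive number")
  }
  m
}

#' @export
print.module_set <- function(x, ...) {
  sizes <- vapply(x$modules, function(m) length(m$gene_ids), integer(1L))
  cat(sprintf(paste0("<module_set> %d modules, %d member genes, ",
                     "%d-gene universe (%.0f%% gray)\n"),
              length(x$modules), sum(sizes), length(x$universe),
              100 * (1 - sum(sizes) / length(x$universe))))
  invisible(x)
}

module_sizes <- function(ms) {
  stats::setNames(vapply(ms$modules, function(m) length(m$gene_ids), integer(1L)),
                  vapply(ms$modules, function(m) as.character(m$id), character(1L)))
}

module_by_id <- function(ms, id) {
  for (m in ms$modules) if (m$id == id) return(m)
  stop2("no module with id ", id)
}

#' Write a module set to JSON
#'
#' The JSON carries a schema-version string; [read_modules()] rejects
#' unknown major versions. Numeric constants are stored at full precision
#' so that write-then-read is the identity.
#'
#' @param ms a [module_set()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_modules <- function(ms, path) {
  payload <- list(
    schema_version = MODULE_SCHEMA_VERSION,
    reference_label = ms$reference_label,
    universe = ms$universe,
    modules = lapply(ms$modules, function(m) {
      list(id = m$id,
           gene_ids = m$gene_ids,
           corEG = unname(m$corEG),
           hub_gene = m$hub_gene,
           ref_gene_sd = unname(m$ref_gene_sd),
           ref_sumz_sd = m$ref_sumz_sd,
           ref_rawscore_sd = m$ref_rawscore_sd)
    }))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = FALSE)
  invisible(path)
}

#' Read a module set from JSON
#'
#' @param path path to JSON written by [write_modules()].
#' @return a [module_set()].
#' @export
read_modules <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = TRUE,
                                 simplifyDataFrame = FALSE,
                                 simplifyMatrix = FALSE)
  ver <- payload$schema_version %||% ""
  major <- sub("\\..*$", "", ver)
  if (!identical(major, sub("\\..*$", "", MODULE_SCHEMA_VERSION)))
    stop2("unsupported module schema version '", ver, "'")
  modules <- lapply(payload$modules, function(m) {
    list(id = as.integer(m$id),
         gene_ids = as.character(m$gene_ids),
         corEG = stats::setNames(as.numeric(m$corEG), m$gene_ids),
         hub_gene = as.character(m$hub_gene),
         ref_gene_sd = stats::setNames(as.numeric(m$ref_gene_sd), m$gene_ids),
         ref_sumz_sd = as.numeric(m$ref_sumz_sd),
         ref_rawscore_sd = as.numeric(m$ref_rawscore_sd))
  })
  module_set(modules, universe = as.character(payload$universe),
             reference_label = payload$reference_label %||% "")
}
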