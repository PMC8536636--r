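#' Simulate a reference corpus with planted co-expression modules
#'
#' Factor-model generator: gene `g` planted in module `m` has
#' `log2FC(c, g) = loading_g * activity_m(c) + eps`,
#' `eps ~ N(0, noise_sd^2)`; background genes are pure standard-normal
#' noise. Module activities are standard normal per condition; with
#' `dose_structure = TRUE` each compound draws one latent response per
#' module which is scaled monotonically by dose and time (so dose-response
#' filters on the condition metadata are exercised). A companion
#' BH-adjusted-p grid is generated such that planted genes pass the
#' 0.001 inclusion filter and ~98% of background genes do not.
#'
#' Everything is a pure function of `(parameters, seed)`.
#'
#' @param n_genes total genes, default `2000`.
#' @param n_modules planted modules, default `20`.
#' @param module_size_range inclusive size bounds, default `c(5, 100)`.
#' @param n_conditions treatment conditions, default `200`.
#' @param loading_range per-gene loading bounds, default `c(0.6, 0.95)`.
#' @param noise_sd residual SD, default `0.5`.
#' @param background_frac fraction of unassigned (gray) genes, default
#'   `0.3`.
#' @param dose_structure encode compound/dose/time structure in the
#'   activities and condition ids, default `TRUE`.
#' @param times,doses labels used when `dose_structure = TRUE`.
#' @param seed RNG seed.
#' @return list with `fc` (an [fold_change_matrix()] with `adj_p`) and
#'   `truth` (class `fixture_truth`): `module_partition` (named integer,
#'   0 = background), `latent_activity` (modules x conditions),
#'   `loadings`, `noise_sd`, `seed`.
#' @export
generate_reference <- function(n_genes = 2000L, n_modules = 20L,
                               module_size_range = c(5L, 100L),
                               n_conditions = 200L,
                               loading_range = c(0.6, 0.95),
                               noise_sd = 0.5, background_frac = 0.3,
                               dose_structure = TRUE,
                               times = c("8 hr", "24 hr"),
                               doses = c("LO", "MED", "HI"),
                               seed = 1L) {
  stopifnot(n_genes >= 1L, n_modules >= 1L, n_conditions >= 2L)
  if (loading_range[1] <= 0 || loading_range[2] > 1)
    stop2("`loading_range` must lie within (0, 1]")
  n_assigned <- round((1 - background_frac) * n_genes)
  if (n_modules * module_size_range[1] > n_assigned)
    stop2("module sizes exceed the number of assignable genes")
  rng <- local_rng(seed)
  on.exit(rng$restore())
  sizes <- draw_module_sizes(n_modules, module_size_range, n_assigned)
  gene_ids <- sprintf("G%05d", seq_len(n_genes))
  partition <- stats::setNames(integer(n_genes), gene_ids)
  assigned <- sample(gene_ids, sum(sizes))
  partition[assigned] <- rep(seq_len(n_modules), sizes)
  ## condition grid and latent activities
  if (dose_structure) {
    per_cpd <- length(times) * length(doses)
    n_cpd <- ceiling(n_conditions / per_cpd)
    grid <- expand.grid(dose = doses, time = times,
                        compound = sprintf("CPD%03d", seq_len(n_cpd)),
                        stringsAsFactors = FALSE)[seq_len(n_conditions), ]
    cond_ids <- paste(grid$compound, grid$time, grid$dose, sep = "_")
    dose_f <- stats::setNames(seq(0.5, 1.5, length.out = length(doses)), doses)
    time_f <- stats::setNames(seq(0.6, 1.2, length.out = length(times)), times)
    base <- matrix(stats::rnorm(n_modules * n_cpd), n_modules, n_cpd,
                   dimnames = list(NULL, unique(grid$compound)))
    scale_c <- dose_f[grid$dose] * time_f[grid$time]
    activity <- base[, grid$compound, drop = FALSE] *
      rep(scale_c, each = n_modules) +
      matrix(stats::rnorm(n_modules * n_conditions, sd = 0.3),
             n_modules, n_conditions)
  } else {
    cond_ids <- sprintf("COND%04d", seq_len(n_conditions))
    activity <- matrix(stats::rnorm(n_modules * n_conditions),
                       n_modules, n_conditions)
  }
  dimnames(activity) <- list(as.character(seq_len(n_modules)), cond_ids)
  loadings <- stats::setNames(
    stats::runif(n_genes, loading_range[1], loading_range[2]), gene_ids)
  loadings[partition == 0L] <- 0
  vals <- matrix(stats::rnorm(n_conditions * n_genes), n_conditions, n_genes,
                 dimnames = list(cond_ids, gene_ids))
  planted <- partition > 0L
  vals[, planted] <- t(activity[partition[planted], , drop = FALSE]) *
    rep(loadings[planted], each = n_conditions) +
    vals[, planted] * noise_sd
  adj_p <- matrix(stats::runif(n_conditions * n_genes, 0.001, 1),
                  n_conditions, n_genes,
                  dimnames = list(cond_ids, gene_ids))
  sig_gene <- planted | stats::runif(n_genes) < 0.02
  hit_row <- sample.int(n_conditions, sum(sig_gene), replace = TRUE)
  adj_p[cbind(hit_row, which(sig_gene))] <-
    stats::runif(sum(sig_gene), 0, 0.0009)
  truth <- structure(list(module_partition = partition,
                          latent_activity = activity,
                          loadings = loadings,
                          noise_sd = noise_sd,
                          seed = seed),
                     class = "fixture_truth")
  list(fc = fold_change_matrix(vals, adj_p = adj_p), truth = truth)
}

## sizes within bounds summing (up to bound saturation) to `total`
draw_module_sizes <- function(n, bounds, total) {
  raw <- stats::runif(n, bounds[1], bounds[2])
  sizes <- pmin(pmax(round(raw * total / sum(raw)), bounds[1]), bounds[2])
  for (i in seq_len(10 * n)) {
    diff <- total - sum(sizes)
    if (diff == 0) break
    j <- if (diff > 0) which(sizes < bounds[2]) else which(sizes > bounds[1])
    if (!length(j)) break
    j <- j[(i - 1L) %% length(j) + 1L]
    sizes[j] <- sizes[j] + sign(diff)
  }
  sizes
}

#' Simulate a targeted-panel study from a reference fixture
#'
#' Draws new conditions from the planted factor model of `ref_truth` and
#' restricts the measured genes to a panel of `panel_frac` of the genome,
#' optionally biased toward high-loading (high-corEG) genes, emulating a
#' curated targeted sequencing panel.
#'
#' @param ref_truth `fixture_truth` from [generate_reference()].
#' @param panel_frac fraction of genes on the panel, in (0, 1].
#' @param bias_high_coreg sample genes with probability increasing in
#'   their planted loading, default `FALSE`.
#' @param n_conditions new conditions to simulate, default `50`.
#' @param seed RNG seed.
#' @return list with `fc` (panel-restricted [fold_change_matrix()]),
#'   `panel` (gene ids) and `activity` (planted modules x conditions).
#' @export
generate_panel_study <- function(ref_truth, panel_frac,
                                 bias_high_coreg = FALSE,
                                 n_conditions = 50L, seed = 1L) {
  if (!(panel_frac > 0 && panel_frac <= 1))
    stop2("`panel_frac` must lie in (0, 1]")
  rng <- local_rng(seed)
  on.exit(rng$restore())
  part <- ref_truth$module_partition
  gene_ids <- names(part)
  n_panel <- max(1L, round(panel_frac * length(gene_ids)))
  prob <- if (bias_high_coreg) exp(8 * ref_truth$loadings) - 0.999 else NULL
  panel <- sort(sample(gene_ids, n_panel, prob = prob))
  n_modules <- nrow(ref_truth$latent_activity)
  activity <- matrix(stats::rnorm(n_modules * n_conditions),
                     n_modules, n_conditions,
                     dimnames = list(rownames(ref_truth$latent_activity),
                                     sprintf("EXT%03d_24 hr_HI",
                                             seq_len(n_conditions))))
  vals <- matrix(stats::rnorm(n_conditions * n_panel), n_conditions, n_panel,
                 dimnames = list(colnames(activity), panel))
  planted <- part[panel] > 0L
  vals[, planted] <- t(activity[part[panel][planted], , drop = FALSE]) *
    rep(ref_truth$loadings[panel][planted], each = n_conditions) +
    vals[, planted] * ref_truth$noise_sd
  list(fc = fold_change_matrix(vals), panel = panel, activity = activity)
}

#' Simulate a multi-donor cohort with planted trait effects
#'
#' Emulates a donor-panel exposure study: `n_donors` donors, each exposed
#' at every concentration (one 24-h condition per donor x concentration).
#' Donors carry a persistent module-response random effect
#' (`donor_sd`, the stable donor phenotype component), and trait-positive
#' donors receive a planted mean shift of `d` within-group SDs on the
#' specified module's activity at the specified concentration.
#'
#' @param ref either a `fixture_truth` from [generate_reference()] or a
#'   frozen [module_set()] (loadings are then reconstructed as
#'   `corEG * ref_gene_sd`).
#' @param n_donors donors (>= 6), default `50`.
#' @param traits_spec data.frame of planted effects with columns `module`,
#'   `trait`, `concentration`, `d`; `NULL` plants no effect on a single
#'   trait `"trait1"`.
#' @param concentrations dose labels, default `c("LO", "MED", "HI")`.
#' @param prevalence trait prevalence, default `0.4`.
#' @param donor_sd SD share of the persistent donor random effect, in
#'   [0, 1), default `0.7`.
#' @param time_label time point label, default `"24 hr"`.
#' @param noise_sd gene-level residual SD; default taken from `ref` when
#'   it is a `fixture_truth`, else `0.5`.
#' @param seed RNG seed.
#' @return list with `fc` (donor x concentration conditions), `traits`
#'   (a `trait_matrix`), `meta` (condition_id, donor, dose, time) and
#'   `truth` (planted activities and effects).
#' @export
generate_donor_cohort <- function(ref, n_donors = 50L, traits_spec = NULL,
                                  concentrations = c("LO", "MED", "HI"),
                                  prevalence = 0.4, donor_sd = 0.7,
                                  time_label = "24 hr", noise_sd = NULL,
                                  seed = 1L) {
  if (n_donors < 6L) stop2("`n_donors` must be >= 6")
  if (inherits(ref, "fixture_truth")) {
    part <- ref$module_partition
    loadings <- ref$loadings
    if (is.null(noise_sd)) noise_sd <- ref$noise_sd
  } else if (inherits(ref, "module_set")) {
    part <- stats::setNames(integer(length(ref$universe)), ref$universe)
    loadings <- stats::setNames(numeric(length(ref$universe)), ref$universe)
    for (m in ref$modules) {
      part[m$gene_ids] <- m$id
      loadings[m$gene_ids] <- m$corEG * m$ref_gene_sd
    }
    if (is.null(noise_sd)) noise_sd <- 0.5
  } else stop2("`ref` must be a fixture_truth or a module_set")
  if (is.null(traits_spec))
    traits_spec <- data.frame(module = integer(0), trait = character(0),
                              concentration = character(0), d = numeric(0))
  trait_names <- unique(c(traits_spec$trait, "trait1"))
  module_ids <- sort(unique(part[part > 0L]))
  rng <- local_rng(seed)
  on.exit(rng$restore())
  donors <- sprintf("D%03d", seq_len(n_donors))
  labels <- matrix(stats::rbinom(n_donors * length(trait_names), 1L,
                                 prevalence),
                   n_donors, length(trait_names),
                   dimnames = list(donors, trait_names))
  if (any(colSums(labels) < 3L) || any(colSums(1 - labels) < 3L))
    stop2("trait prevalence yielded a donor group smaller than 3; ",
          "change `prevalence` or `seed`")
  grid <- expand.grid(dose = concentrations, donor = donors,
                      stringsAsFactors = FALSE)
  cond_ids <- paste(grid$donor, time_label, grid$dose, sep = "_")
  n_cond <- nrow(grid)
  n_mod <- length(module_ids)
  donor_re <- matrix(stats::rnorm(n_mod * n_donors), n_mod, n_donors,
                     dimnames = list(as.character(module_ids), donors))
  activity <- donor_sd * donor_re[, grid$donor, drop = FALSE] +
    sqrt(1 - donor_sd^2) *
    matrix(stats::rnorm(n_mod * n_cond), n_mod, n_cond)
  colnames(activity) <- cond_ids
  if (nrow(traits_spec)) {
    for (i in seq_len(nrow(traits_spec))) {
      m <- as.character(traits_spec$module[i])
      hit <- grid$dose == traits_spec$concentration[i] &
        labels[grid$donor, traits_spec$trait[i]] == 1L
      activity[m, hit] <- activity[m, hit] + traits_spec$d[i]
    }
  }
  gene_ids <- names(part)
  vals <- matrix(stats::rnorm(n_cond * length(gene_ids)), n_cond,
                 length(gene_ids), dimnames = list(cond_ids, gene_ids))
  planted <- part > 0L
  vals[, planted] <- t(activity[as.character(part[planted]), ,
                                drop = FALSE]) *
    rep(loadings[planted], each = n_cond) + vals[, planted] * noise_sd
  meta <- data.frame(condition_id = cond_ids, donor = grid$donor,
                     dose = grid$dose, time = time_label,
                     stringsAsFactors = FALSE)
  truth <- structure(list(activity = activity, traits_spec = traits_spec,
                          donor_sd = donor_sd, seed = seed),
                     class = "fixture_truth")
  list(fc = fold_change_matrix(vals, meta = meta),
       traits = trait_matrix(labels), meta = meta, truth = truth)
}
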