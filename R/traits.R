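#' Cluster summary scores and overall transcriptional activity
#'
#' Cluster behavior per condition is the arithmetic mean of the member
#' module scores; `avgAbsEG` -- the covariate used in trait regressions --
#' is the mean of |score| over ALL modules per condition.
#'
#' @param scores modules x conditions score matrix (eigengene or
#'   projected).
#' @param cluster_labels named integer vector (names = module ids), e.g.
#'   from [cluster_modules()].
#' @return list with `cluster_scores` (clusters x conditions) and
#'   `avg_abs_eg` (named per-condition numeric).
#' @export
compute_summary_scores <- function(scores, cluster_labels) {
  absent <- setdiff(names(cluster_labels), rownames(scores))
  if (length(absent)) stop2("cluster member has no score row: ", absent[1L])
  ids <- sort(unique(cluster_labels))
  cs <- t(vapply(ids, function(cl) {
    members <- names(cluster_labels)[cluster_labels == cl]
    if (!length(members)) stop2("empty cluster ", cl)
    colMeans(scores[members, , drop = FALSE])
  }, numeric(ncol(scores))))
  rownames(cs) <- as.character(ids)
  list(cluster_scores = cs,
       avg_abs_eg = colMeans(abs(scores)))
}

#' Cohen's d (pooled SD)
#'
#' Standardized mean difference between the trait-positive and
#' trait-negative groups:
#' `d = (mean_pos - mean_neg) / s_pooled`.
#'
#' @param pos,neg numeric score vectors for the two groups.
#' @return Cohen's d.
#' @export
cohen_d <- function(pos, neg) {
  n1 <- length(pos); n2 <- length(neg)
  if (n1 < 2L || n2 < 2L) return(NA_real_)
  sp <- sqrt(((n1 - 1) * stats::var(pos) + (n2 - 1) * stats::var(neg)) /
               (n1 + n2 - 2))
  if (sp == 0) return(0)
  (mean(pos) - mean(neg)) / sp
}

#' Associate unit scores with binary donor traits
#'
#' Analyses run per (trait, concentration) slice at one time point
#' (default the 24-h exposures, where transcriptomic changes are
#' generally largest). Per unit (module or cluster): Cohen's d between
#' trait-positive and trait-negative donors, and a logistic regression of
#' the trait on the unit score plus avgAbsEG -- so a unit is significant
#' only if it explains residual odds beyond overall transcriptional
#' activity. Wald p-values of the unit coefficient are BH-adjusted across
#' units within each slice. Slices where either group has fewer than 3
#' donors are skipped with a message. Perfect separation (non-convergence
#' or |coefficient| > 20) triggers a ridge-penalized refit
#' (lambda = 1e-4) and flags the row.
#'
#' @param unit_scores units x conditions score matrix.
#' @param traits a `trait_matrix` (donor x trait, 0/1/NA).
#' @param meta data.frame over the score conditions with columns
#'   `condition_id`, `donor`, `dose`, `time` (a donor contributes one
#'   condition per dose at the analyzed time).
#' @param avg_abs_eg named per-condition covariate; default computes it
#'   from `unit_scores` (supply module-level avgAbsEG when `unit_scores`
#'   is cluster-level).
#' @param time_label analyzed time point, default `"24 hr"`.
#' @return data.frame with one row per (unit, trait, concentration):
#'   `unit_id`, `trait_name`, `concentration_label`, `n_pos`, `n_neg`,
#'   `cohen_d`, `coef`, `p`, `p_adj`, `signed_log10_p_adj`, `ridged`.
#' @export
associate_traits <- function(unit_scores, traits, meta, avg_abs_eg = NULL,
                             time_label = "24 hr") {
  need <- c("condition_id", "donor", "dose", "time")
  if (!all(need %in% names(meta)))
    stop2("`meta` must have columns: ", paste(need, collapse = ", "))
  if (is.null(avg_abs_eg)) {
    message("avgAbsEG computed from `unit_scores` (pass module-level ",
            "avgAbsEG when scoring clusters)")
    avg_abs_eg <- colMeans(abs(unit_scores))
  }
  meta <- meta[meta$time == time_label & meta$condition_id %in%
                 colnames(unit_scores), , drop = FALSE]
  if (!nrow(meta)) stop2("no conditions at time point '", time_label, "'")
  rows <- list()
  for (conc in unique(meta$dose)) {
    slice <- meta[meta$dose == conc, , drop = FALSE]
    if (anyDuplicated(slice$donor))
      stop2("donor measured more than once at dose '", conc, "'")
    for (tr in traits$trait_names) {
      lab <- traits$values[slice$donor, tr]
      ok <- !is.na(lab)
      if (sum(lab[ok] == 1) < 3L || sum(lab[ok] == 0) < 3L) {
        message("trait '", tr, "' at dose '", conc,
                "': fewer than 3 donors in a group; slice skipped")
        next
      }
      cond <- slice$condition_id[ok]
      y <- lab[ok]
      covar <- avg_abs_eg[cond]
      slice_rows <- lapply(rownames(unit_scores), function(u) {
        s <- unit_scores[u, cond]
        d <- cohen_d(s[y == 1], s[y == 0])
        fit <- logistic_unit_fit(y, s, covar)
        data.frame(unit_id = u, trait_name = tr,
                   concentration_label = conc,
                   n_pos = sum(y == 1), n_neg = sum(y == 0),
                   cohen_d = d, coef = fit$coef, p = fit$p,
                   ridged = fit$ridged,
                   stringsAsFactors = FALSE)
      })
      sl <- do.call(rbind, slice_rows)
      sl$p_adj <- stats::p.adjust(sl$p, method = "BH")
      sl$signed_log10_p_adj <- -log10(sl$p_adj) * sign(sl$coef)
      rows[[length(rows) + 1L]] <- sl
    }
  }
  if (!length(rows)) stop2("no analyzable (trait, concentration) slice")
  out <- do.call(rbind, rows)
  out[, c("unit_id", "trait_name", "concentration_label", "n_pos", "n_neg",
          "cohen_d", "coef", "p", "p_adj", "signed_log10_p_adj", "ridged")]
}

## logistic fit of y ~ score + covariate; Wald p for the score
## coefficient, with a ridge fallback on separation
logistic_unit_fit <- function(y, score, covar) {
  fit <- suppressWarnings(
    stats::glm(y ~ score + covar, family = stats::binomial()))
  b <- stats::coef(fit)["score"]
  separated <- !fit$converged || is.na(b) || abs(b) > 20 ||
    fit$deviance < 1e-6
  if (!separated) {
    sm <- summary(fit)$coefficients
    return(list(coef = unname(b), p = sm["score", "Pr(>|z|)"],
                ridged = FALSE))
  }
  rf <- ridge_logistic(cbind(1, score, covar), y, lambda = 1e-4)
  list(coef = rf$coef[2L], p = rf$p[2L], ridged = TRUE)
}

## minimal ridge-penalized logistic regression (penalty off the
## intercept); Wald p from the penalized information matrix
ridge_logistic <- function(x, y, lambda = 1e-4, max_iter = 100L,
                           tol = 1e-8) {
  p <- ncol(x)
  pen <- diag(c(0, rep(lambda, p - 1L)), p)
  beta <- rep(0, p)
  for (i in seq_len(max_iter)) {
    eta <- drop(x %*% beta)
    mu <- 1 / (1 + exp(-eta))
    w <- pmax(mu * (1 - mu), 1e-10)
    info <- crossprod(x, x * w) + pen
    grad <- crossprod(x, y - mu) - pen %*% beta
    step <- solve(info, grad)
    beta <- beta + drop(step)
    if (max(abs(step)) < tol) break
  }
  eta <- drop(x %*% beta)
  mu <- 1 / (1 + exp(-eta))
  w <- pmax(mu * (1 - mu), 1e-10)
  cov_b <- solve(crossprod(x, x * w) + pen)
  se <- sqrt(diag(cov_b))
  z <- beta / se
  list(coef = beta, se = se,
       p = 2 * stats::pnorm(-abs(z)))
}
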