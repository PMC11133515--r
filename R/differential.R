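#' Model specification for the adjusted analysis
#'
#' @param covariates ordered character vector of sample-table columns used
#'   as adjustment covariates (default sex, diastolic blood pressure and
#'   C-reactive protein). The case/control contrast is always included,
#'   coded control = 0, case = 1.
#' @param profile `"means"` (covariates held at whole-sample means /
#'   proportions when predicting group geometric means) or `"reference"`
#'   (covariates at zero / first level).
#' @return list of class `"model_spec"`.
#' @export
model_spec <- function(covariates = c("sex", "dbp", "crp"),
                       profile = c("means", "reference")) {
  structure(list(covariates = covariates, profile = match.arg(profile)),
            class = "model_spec")
}

# Design matrix [1, group, covariates...] for the modeled samples.
# Two-level character/factor covariates become 0/1 indicators of the
# second sorted level; numeric covariates enter as-is.
.build_design <- function(samples, covariates) {
  n <- nrow(samples)
  if (!all(samples$group %in% c("case", "control"))) {
    stop("group must be 'case' or 'control'")
  }
  X <- cbind("(Intercept)" = rep(1, n),
             group = as.numeric(samples$group == "case"))
  for (cv in covariates) {
    if (!cv %in% colnames(samples)) stop("covariate '", cv, "' not in sample table")
    x <- samples[[cv]]
    if (anyNA(x)) stop("covariate '", cv, "' has missing values for modeled samples")
    if (is.character(x) || is.factor(x)) {
      lev <- sort(unique(as.character(x)))
      if (length(lev) > 2) stop("covariate '", cv, "' has more than 2 levels")
      col <- as.numeric(as.character(x) == lev[length(lev)])
      nm <- if (length(lev) == 2) paste0(cv, lev[2]) else cv
    } else {
      col <- as.numeric(x)
      nm <- cv
    }
    X <- cbind(X, col)
    colnames(X)[ncol(X)] <- nm
  }
  X
}

# Covariate profile rows for the two groups: adjustment covariates fixed
# (at-means or reference), group set to 0 / 1.
.profile_rows <- function(X, profile) {
  p <- ncol(X)
  prof <- if (p > 2) {
    if (profile == "means") colMeans(X[, -(1:2), drop = FALSE]) else rep(0, p - 2)
  } else numeric(0)
  x_control <- c(1, 0, prof)
  x_case <- c(1, 1, prof)
  rbind(control = x_control, case = x_case)
}

#' Fit the adjusted Tobit model for one metabolite
#'
#' Design is `[intercept, group, covariates]`; the response is the
#' standardized log concentration with censored rows bounded at the
#' metabolite's standardized censor bound `c`.
#'
#' @param y standardized log concentrations (censored entries equal `c`).
#' @param censored logical mask.
#' @param cc standardized censor bound (`-Inf`-free scalar; ignored when
#'   nothing is censored).
#' @param samples sample table aligned with `y`.
#' @param spec a [model_spec()].
#' @param id metabolite id used to tag error messages.
#' @return a `"tobit"` object.
#' @export
fit_metabolite <- function(y, censored, cc, samples, spec = model_spec(),
                           id = "metabolite") {
  X <- .build_design(samples, spec$covariates)
  bound <- rep(if (is.finite(cc)) cc else -Inf, length(y))
  tryCatch(
    tobit_fit(X, y, censored, bound = bound),
    error = function(e) stop("metabolite '", id, "': ", conditionMessage(e),
                             call. = FALSE)
  )
}

#' Model-based geometric means per group
#'
#' Evaluates the standardized-scale linear predictor at each group with the
#' adjustment covariates fixed at the model-spec profile, then maps back to
#' concentration units: `gm = exp(m + s * eta)` with the 95% Wald interval
#' `exp(m + s * (eta +/- 1.96 * se(eta)))`, `se(eta)` from the coefficient
#' covariance and the profile vector.
#'
#' @param fit a converged `"tobit"` object from [fit_metabolite()].
#' @param state transform state (`m`, `s`) from [fit_transform()].
#' @param spec the [model_spec()] used for the fit.
#' @return data frame with rows `control`, `case` and columns `gm`, `lo`,
#'   `hi` (uM).
#' @export
group_geometric_means <- function(fit, state, spec = model_spec()) {
  stopifnot(inherits(fit, "tobit"))
  if (!fit$converged) stop("fit did not converge")
  P <- .profile_rows(fit$X, spec$profile)
  Vb <- vcov(fit, "beta")
  eta <- drop(P %*% fit$coefficients)
  se <- sqrt(pmax(0, diag(P %*% Vb %*% t(P))))
  data.frame(
    gm = exp(state$m + state$s * eta),
    lo = exp(state$m + state$s * (eta - 1.96 * se)),
    hi = exp(state$m + state$s * (eta + 1.96 * se)),
    row.names = rownames(P)
  )
}

#' Fold-change from a Tobit fit
#'
#' The ratio of case to control geometric means. With covariates held at a
#' common profile this is `exp(s * beta_group)`, with 95% interval
#' `exp(s * (beta_group +/- 1.96 * se))`.
#'
#' @inheritParams group_geometric_means
#' @return list with `fc`, `lo`, `hi`.
#' @export
fold_change <- function(fit, state) {
  stopifnot(inherits(fit, "tobit"))
  w <- wald_test(fit, "group")
  list(fc = exp(state$s * w$estimate),
       lo = exp(state$s * (w$estimate - 1.96 * w$se)),
       hi = exp(state$s * (w$estimate + 1.96 * w$se)))
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjustment over one family of p-values (all metabolites tested
#' in the same run). Monotone, order-preserving, capped at 1.
#'
#' @param p numeric vector of p-values in `[0, 1]`; `NaN` is rejected.
#' @return adjusted p-values in input order.
#' @export
bh_adjust <- function(p) {
  if (any(is.nan(p))) stop("NaN p-value in input")
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

# Preprocess one metabolite column into its standardized censored response.
# Aggregates (no LOD) are treated as fully observed with an infinite lower
# bound, so the Tobit fit reduces to uncensored Gaussian ML.
.prepare_metabolite <- function(x, lod, scale_basis) {
  keep <- !is.na(x)
  if (is.null(lod)) {
    logs <- log(x[keep])
    m <- mean(logs); s <- stats::sd(logs)
    if (!is.finite(s) || s == 0) stop("zero variance")
    list(y = (logs - m) / s, censored = rep(FALSE, sum(keep)),
         state = list(m = m, s = s, c = -Inf, lod = NA_real_,
                      scale_basis = scale_basis),
         keep = keep)
  } else {
    cv <- substitute_lod_half(x, lod)
    tr <- fit_transform(cv, scale_basis)
    list(y = tr$y, censored = cv$censored, state = tr$state, keep = keep)
  }
}

#' Adjusted differential-abundance analysis of a full panel
#'
#' The end-to-end per-metabolite pipeline: detection filtering (default:
#' at least 20% of observations above the LOD), LOD/2 substitution, log +
#' autoscale transform, adjusted Tobit fit per metabolite, model-based
#' geometric means with 95% CIs, fold-change, Wald p-value on the group
#' contrast and Benjamini-Hochberg FDR over all tested metabolites.
#'
#' @param mat concentration matrix (samples x metabolites, uM); rownames
#'   are sample ids matching `samples$sample_id`.
#' @param samples sample table (see [read_samples()]).
#' @param lods named LOD vector.
#' @param panel a `"metab_panel"`; defaults to [default_panel()].
#' @param spec a [model_spec()].
#' @param min_fraction detection threshold (default 0.20).
#' @param scale_basis autoscale basis, see [fit_transform()].
#' @param include_aggregates append and test the panel's sum variables?
#' @param fdr_family `"all"` (default: aggregates share the FDR family) or
#'   `"measured_only"`.
#' @return data frame of class `"censmetab_results"`, one row per tested
#'   metabolite, ordered by FDR p-value then id: `metabolite`,
#'   `n_below_lb`, `gm_case`, `gm_case_lo`, `gm_case_hi`, `gm_control`,
#'   `gm_control_lo`, `gm_control_hi`, `fc`, `fc_lo`, `fc_hi`, `p_value`,
#'   `fdr_p`, `significant` (FDR < 0.05), `converged`. Attributes carry the
#'   dropped metabolites and any fit failures.
#' @export
run_multivariable <- function(mat, samples, lods, panel = default_panel(),
                              spec = model_spec(), min_fraction = 0.20,
                              scale_basis = c("substituted", "observed_only"),
                              include_aggregates = TRUE,
                              fdr_family = c("all", "measured_only")) {
  scale_basis <- match.arg(scale_basis)
  fdr_family <- match.arg(fdr_family)
  stopifnot(is.matrix(mat), !is.null(rownames(mat)))
  idx <- match(rownames(mat), samples$sample_id)
  if (anyNA(idx)) stop("samples missing from metadata: ",
                       paste(rownames(mat)[is.na(idx)], collapse = ", "))
  samples <- samples[idx, , drop = FALSE]
  .build_design(samples, spec$covariates)  # fail fast on bad covariates
  validate_panel_data(mat, panel, lods)
  if (include_aggregates) {
    have <- intersect(panel$id[panel$is_aggregate], colnames(mat))
    if (length(have) == 0) mat <- compute_aggregates(mat, panel, lods)
  } else {
    mat <- mat[, !colnames(mat) %in% panel$id[panel$is_aggregate],
               drop = FALSE]
  }
  filt <- detection_filter(mat, lods, min_fraction)
  failures <- character(0)
  rows <- list()
  for (id in filt$kept) {
    prep <- tryCatch(.prepare_metabolite(mat[, id], .lod_of(lods, id), scale_basis),
                     error = function(e) NULL)
    if (is.null(prep)) { failures <- c(failures, id); next }
    fit <- tryCatch(
      fit_metabolite(prep$y, prep$censored, prep$state$c,
                     samples[prep$keep, , drop = FALSE], spec, id = id),
      error = function(e) NULL)
    if (is.null(fit) || !fit$converged) { failures <- c(failures, id); next }
    gm <- group_geometric_means(fit, prep$state, spec)
    fc <- fold_change(fit, prep$state)
    w <- wald_test(fit, "group")
    rows[[id]] <- data.frame(
      metabolite = id, n_below_lb = sum(prep$censored),
      gm_case = gm["case", "gm"], gm_case_lo = gm["case", "lo"],
      gm_case_hi = gm["case", "hi"],
      gm_control = gm["control", "gm"], gm_control_lo = gm["control", "lo"],
      gm_control_hi = gm["control", "hi"],
      fc = fc$fc, fc_lo = fc$lo, fc_hi = fc$hi,
      p_value = w$p_value, converged = fit$converged,
      is_aggregate = id %in% panel$id[panel$is_aggregate],
      stringsAsFactors = FALSE)
  }
  if (length(rows) == 0) stop("no metabolite could be fitted")
  res <- do.call(rbind, rows)
  in_family <- if (fdr_family == "all") rep(TRUE, nrow(res)) else !res$is_aggregate
  res$fdr_p <- NA_real_
  res$fdr_p[in_family] <- bh_adjust(res$p_value[in_family])
  res$significant <- !is.na(res$fdr_p) & res$fdr_p < 0.05
  res <- res[order(res$fdr_p, res$metabolite), ]
  rownames(res) <- NULL
  attr(res, "dropped") <- filt$dropped
  attr(res, "failures") <- failures
  attr(res, "spec") <- spec
  class(res) <- c("censmetab_results", "data.frame")
  res
}

#' @export
print.censmetab_results <- function(x, ...) {
  cat("Censored differential-abundance results:", nrow(x), "metabolites tested,",
      sum(x$significant), "significant at FDR < 0.05\n")
  dropped <- attr(x, "dropped")
  if (length(dropped) > 0) {
    cat("Dropped by detection filter:", length(dropped), "\n")
  }
  fails <- attr(x, "failures")
  if (length(fails) > 0) cat("Fit failures:", paste(fails, collapse = ", "), "\n")
  print.data.frame(utils::head(as.data.frame(x)[, c("metabolite", "n_below_lb",
    "gm_case", "gm_control", "fc", "p_value", "fdr_p")], 10), digits = 4)
  if (nrow(x) > 10) cat("... (", nrow(x) - 10, " more rows)\n", sep = "")
  invisible(x)
}

#' Univariate Tobit screen
#'
#' Fits, per metabolite, a Tobit model with a single predictor (default the
#' case/control contrast) on the standardized log concentration and reports
#' that predictor's coefficient.
#'
#' @inheritParams run_multivariable
#' @param predictor one sample-table column name; `"group"` gives the
#'   unadjusted disease contrast.
#' @return data frame: `metabolite`, `estimate`, `se`, `p_value`, `fdr_p`,
#'   one row per metabolite passing the detection filter, alphabetical.
#' @export
run_univariate <- function(mat, samples, lods, panel = default_panel(),
                           predictor = "group", min_fraction = 0.20,
                           scale_basis = "substituted",
                           include_aggregates = TRUE) {
  stopifnot(is.matrix(mat), !is.null(rownames(mat)))
  idx <- match(rownames(mat), samples$sample_id)
  if (anyNA(idx)) stop("samples missing from metadata")
  samp <- samples[idx, , drop = FALSE]
  validate_panel_data(mat, panel, lods)
  if (include_aggregates) {
    have <- intersect(panel$id[panel$is_aggregate], colnames(mat))
    if (length(have) == 0) mat <- compute_aggregates(mat, panel, lods)
  }
  if (predictor == "group") {
    X_all <- .build_design(samp, character(0))
  } else {
    X_all <- .build_design(samp, predictor)[, c(1, 3), drop = FALSE]
  }
  filt <- detection_filter(mat, lods, min_fraction)
  rows <- list()
  for (id in filt$kept) {
    prep <- tryCatch(.prepare_metabolite(mat[, id], .lod_of(lods, id), scale_basis),
                     error = function(e) NULL)
    if (is.null(prep)) next
    fit <- tryCatch(
      tobit_fit(X_all[prep$keep, , drop = FALSE], prep$y, prep$censored,
                bound = rep(prep$state$c, length(prep$y))),
      error = function(e) NULL)
    if (is.null(fit) || !fit$converged) next
    w <- wald_test(fit, 2)
    rows[[id]] <- data.frame(metabolite = id, estimate = w$estimate,
                             se = w$se, p_value = w$p_value,
                             stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$metabolite), , drop = FALSE]
  out$fdr_p <- bh_adjust(out$p_value)
  rownames(out) <- NULL
  out
}

#' Screen candidate covariates against the panel
#'
#' For each candidate column, fits per metabolite a univariate Tobit model
#' with that single predictor and counts associations at p < 0.05. The
#' summary supports choosing an adjustment set; the choice itself stays
#' with the analyst.
#'
#' @inheritParams run_multivariable
#' @param candidates character vector of sample-table columns (numeric or
#'   two-level); constant columns are skipped with a warning.
#' @param alpha significance threshold for the association count.
#' @return data frame: `covariate`, `n_tested`, `n_sig`, `frac_sig`.
#' @export
covariate_screen <- function(mat, samples, lods, panel = default_panel(),
                             candidates = c("sex", "age", "bmi", "dbp", "crp"),
                             alpha = 0.05, min_fraction = 0.20,
                             scale_basis = "substituted") {
  if (length(candidates) == 0) {
    return(data.frame(covariate = character(0), n_tested = integer(0),
                      n_sig = integer(0), frac_sig = numeric(0)))
  }
  idx <- match(rownames(mat), samples$sample_id)
  if (anyNA(idx)) stop("samples missing from metadata")
  samp <- samples[idx, , drop = FALSE]
  filt <- detection_filter(mat, lods, min_fraction)
  rows <- list()
  for (cand in candidates) {
    x <- samp[[cand]]
    if (is.null(x)) stop("candidate '", cand, "' not in sample table")
    if (length(unique(x[!is.na(x)])) < 2) {
      warning("candidate '", cand, "' is constant; skipped")
      next
    }
    X <- .build_design(samp, cand)[, c(1, 3), drop = FALSE]  # intercept + candidate
    n_sig <- 0L; n_tested <- 0L
    for (id in filt$kept) {
      prep <- tryCatch(.prepare_metabolite(mat[, id], .lod_of(lods, id),
                                           scale_basis),
                       error = function(e) NULL)
      if (is.null(prep)) next
      fit <- tryCatch(
        tobit_fit(X[prep$keep, , drop = FALSE], prep$y, prep$censored,
                  bound = rep(prep$state$c, length(prep$y))),
        error = function(e) NULL)
      if (is.null(fit) || !fit$converged) next
      n_tested <- n_tested + 1L
      if (wald_test(fit, 2)$p_value < alpha) n_sig <- n_sig + 1L
    }
    rows[[cand]] <- data.frame(covariate = cand, n_tested = n_tested,
                               n_sig = n_sig,
                               frac_sig = if (n_tested > 0) n_sig / n_tested else NA_real_,
                               stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) out <- data.frame(covariate = character(0),
                                      n_tested = integer(0),
                                      n_sig = integer(0),
                                      frac_sig = numeric(0))
  rownames(out) <- NULL
  out
}

#' Volcano-plot coordinates
#'
#' @param results a `"censmetab_results"` table.
#' @return data frame: `metabolite`, `log2_fc`, `neg_log10_fdr_p`.
#' @export
volcano_table <- function(results) {
  data.frame(metabolite = results$metabolite,
             log2_fc = log2(results$fc),
             neg_log10_fdr_p = -log10(results$fdr_p),
             stringsAsFactors = FALSE)
}
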