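#' LOD/2 substitution for one metabolite
#'
#' Values strictly below the limit of detection are replaced by LOD/2;
#' values at or above the LOD are kept as reported (a value exactly at the
#' bound counts as detected). Missing entries are dropped and counted.
#'
#' @param raw numeric vector of raw concentrations (uM), `NA` allowed.
#' @param lod limit of detection (uM), strictly positive.
#' @return list with `values` (substituted concentrations), `censored`
#'   (logical mask, `TRUE` where raw < LOD), `n_obs`, `n_censored`,
#'   `n_missing` and `lod`.
#' @export
substitute_lod_half <- function(raw, lod) {
  stopifnot(is.numeric(raw), length(lod) == 1, is.finite(lod), lod > 0)
  if (any(raw < 0, na.rm = TRUE)) stop("negative raw concentration")
  n_missing <- sum(is.na(raw))
  x <- raw[!is.na(raw)]
  censored <- x < lod
  x[censored] <- lod / 2
  structure(list(values = x, censored = censored, n_obs = length(x),
                 n_censored = sum(censored), n_missing = n_missing,
                 lod = lod),
            class = "censored_vector")
}

#' @export
print.censored_vector <- function(x, ...) {
  cat("Censored concentration vector: n =", x$n_obs, "(", x$n_censored,
      "below LOD", format(x$lod), ",", x$n_missing, "missing )\n")
  invisible(x)
}

#' Detection-rate filter
#'
#' Keeps a metabolite when at least `min_fraction` of its non-missing
#' observations lie above the LOD (default 20%, i.e. at least 20% of
#' observations greater than the LOD). Aggregate columns, which carry no
#' LOD, are always kept.
#'
#' @param mat concentration matrix (samples x metabolites), possibly with
#'   aggregate columns appended.
#' @param lods named LOD vector for the measured metabolites.
#' @param min_fraction detection threshold in (0, 1].
#' @return list with character vectors `kept` and `dropped`, and
#'   `detection_rate` (named numeric, `NA` for aggregates).
#' @export
detection_filter <- function(mat, lods, min_fraction = 0.20) {
  stopifnot(min_fraction > 0, min_fraction <= 1)
  ids <- colnames(mat)
  rate <- stats::setNames(rep(NA_real_, length(ids)), ids)
  keep <- stats::setNames(rep(TRUE, length(ids)), ids)
  for (id in ids) {
    lod <- .lod_of(lods, id)
    if (is.null(lod)) next  # aggregate: always kept
    x <- mat[, id]
    x <- x[!is.na(x)]
    if (length(x) == 0) stop("no observations for metabolite '", id, "'")
    rate[id] <- mean(x >= lod)
    keep[id] <- rate[id] >= min_fraction
  }
  list(kept = ids[keep], dropped = ids[!keep], detection_rate = rate)
}

#' Log + autoscale transform with censor-bound propagation
#'
#' Natural logs of the LOD/2-substituted concentrations are standardized
#' (autoscaled): centred on their mean `m` and divided by their sample SD
#' `s` (divisor n-1). The metabolite's censoring bound is carried onto the
#' model scale as `c = (log(lod) - m) / s`, so a left-censored Tobit fit on
#' the standardized response uses `c` as its lower bound.
#'
#' By default the moments are computed on all substituted values
#' (`scale_basis = "substituted"`); `"observed_only"` restricts them to
#' uncensored entries.
#'
#' @param cv a `"censored_vector"` from [substitute_lod_half()].
#' @param scale_basis `"substituted"` or `"observed_only"`.
#' @return list with `state` (`m`, `s`, `c`, `lod`, `scale_basis`) and `y`
#'   (standardized log concentrations; censored entries equal `c` exactly).
#' @export
fit_transform <- function(cv, scale_basis = c("substituted", "observed_only")) {
  stopifnot(inherits(cv, "censored_vector"))
  scale_basis <- match.arg(scale_basis)
  if (cv$n_obs < 3) stop("need at least 3 observations to autoscale")
  logs <- log(cv$values)
  basis <- if (scale_basis == "substituted") logs else logs[!cv$censored]
  if (length(basis) < 3) stop("too few uncensored observations for 'observed_only' scaling")
  m <- mean(basis)
  s <- stats::sd(basis)
  if (!is.finite(s) || s == 0) stop("zero variance: metabolite cannot be autoscaled")
  cc <- (log(cv$lod) - m) / s
  y <- (logs - m) / s
  y[cv$censored] <- cc  # censored rows sit exactly at the standardized bound
  list(state = list(m = m, s = s, c = cc, lod = cv$lod,
                    scale_basis = scale_basis),
       y = y)
}

#' Back-transform from the standardized log scale to concentrations
#' @param y standardized values.
#' @param state transform state from [fit_transform()].
#' @return concentrations (uM).
#' @export
inverse_transform <- function(y, state) exp(state$m + state$s * y)

#' Descriptive statistics of a censored vector
#'
#' Mean, SD and the 5th/25th/50th/75th/95th percentiles of the
#' LOD/2-substituted concentrations (percentiles by linear interpolation,
#' `quantile` type 7), with counts of observations below the LOD.
#'
#' @param cv a `"censored_vector"`.
#' @return one-row `data.frame` with columns `n`, `n_below_lod`, `mean`,
#'   `sd`, `p5`, `p25`, `p50`, `p75`, `p95`.
#' @export
describe <- function(cv) {
  stopifnot(inherits(cv, "censored_vector"), cv$n_obs >= 1)
  q <- stats::quantile(cv$values, c(0.05, 0.25, 0.50, 0.75, 0.95),
                       type = 7, names = FALSE)
  data.frame(n = cv$n_obs, n_below_lod = cv$n_censored,
             mean = mean(cv$values),
             sd = if (cv$n_obs > 1) stats::sd(cv$values) else NA_real_,
             p5 = q[1], p25 = q[2], p50 = q[3], p75 = q[4], p95 = q[5])
}

#' Descriptive table for a whole matrix
#'
#' Applies [describe()] per metabolite, by group and overall.
#'
#' @param mat concentration matrix.
#' @param lods named LOD vector (aggregates, lacking an LOD, are summarised
#'   with `n_below_lod = 0`).
#' @param groups optional factor/character of per-sample groups; when given,
#'   one block of rows per group level is added.
#' @return `data.frame` with columns `metabolite`, `group` and the
#'   [describe()] statistics.
#' @export
describe_matrix <- function(mat, lods, groups = NULL) {
  one <- function(x, lod, label) {
    cv <- if (is.null(lod)) {
      # aggregates have no LOD; summarise as fully observed
      structure(list(values = x[!is.na(x)], censored = rep(FALSE, sum(!is.na(x))),
                     n_obs = sum(!is.na(x)), n_censored = 0L,
                     n_missing = sum(is.na(x)), lod = NA_real_),
                class = "censored_vector")
    } else substitute_lod_half(x, lod)
    cbind(group = label, describe(cv))
  }
  blocks <- list()
  for (id in colnames(mat)) {
    lod <- .lod_of(lods, id)
    rows <- one(mat[, id], lod, "all")
    if (!is.null(groups)) {
      for (g in unique(as.character(groups))) {
        rows <- rbind(rows, one(mat[groups == g, id], lod, g))
      }
    }
    blocks[[id]] <- cbind(metabolite = id, rows)
  }
  out <- do.call(rbind, blocks)
  rownames(out) <- NULL
  out
}
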