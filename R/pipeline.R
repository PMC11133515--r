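#' Run configuration for the end-to-end analysis
#'
#' Every default reproduces the analysis conventions the package
#' implements: 20% detection threshold, FDR level 0.05, sex/DBP/CRP
#' adjustment, autoscale moments on LOD/2-substituted values, at-means
#' covariate profile.
#'
#' @param concentrations,samples,lods input file paths.
#' @param sep,dec input dialect (field separator, decimal mark).
#' @param covariates adjustment covariates.
#' @param detect_min detection threshold.
#' @param fdr_level significance level on the FDR-adjusted p-value.
#' @param scale_basis `"substituted"` or `"observed_only"`.
#' @param profile covariate profile for geometric means, `"means"` or
#'   `"reference"`.
#' @param include_aggregates test the panel's sum variables?
#' @param out_dir output directory (created if absent).
#' @param seed seed (used by simulation only).
#' @return list of class `"run_config"`.
#' @export
run_config <- function(concentrations = NULL, samples = NULL, lods = NULL,
                       sep = "\t", dec = ".",
                       covariates = c("sex", "dbp", "crp"),
                       detect_min = 0.20, fdr_level = 0.05,
                       scale_basis = "substituted", profile = "means",
                       include_aggregates = TRUE, out_dir = ".", seed = 1) {
  structure(list(concentrations = concentrations, samples = samples,
                 lods = lods, sep = sep, dec = dec, covariates = covariates,
                 detect_min = detect_min, fdr_level = fdr_level,
                 scale_basis = scale_basis, profile = profile,
                 include_aggregates = include_aggregates,
                 out_dir = out_dir, seed = seed),
            class = "run_config")
}

#' Read a flat key=value configuration file
#'
#' Lines of the form `key = value`; `#` starts a comment. Comma-separated
#' values become vectors; numerics are coerced. Unknown keys are an error.
#'
#' @param path file path.
#' @param overrides named list applied on top of the file (e.g. parsed
#'   command-line flags).
#' @return a [run_config()].
#' @export
read_run_config <- function(path, overrides = list()) {
  defaults <- run_config()
  vals <- list()
  if (!is.null(path)) {
    lines <- readLines(path, warn = FALSE)
    lines <- sub("#.*$", "", lines)
    lines <- trimws(lines)
    lines <- lines[nzchar(lines)]
    for (ln in lines) {
      kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
      if (length(kv) < 2) stop("malformed config line: '", ln, "'")
      key <- trimws(kv[1])
      val <- trimws(paste(kv[-1], collapse = "="))
      if (!key %in% names(defaults)) stop("unknown config key: '", key, "'")
      if (grepl(",", val) && !key %in% c("sep", "dec")) {
        val <- trimws(strsplit(val, ",", fixed = TRUE)[[1]])
      }
      num <- suppressWarnings(as.numeric(val))
      if (length(num) == length(val) && !anyNA(num)) val <- num
      if (identical(val, "TRUE") || identical(val, "true")) val <- TRUE
      if (identical(val, "FALSE") || identical(val, "false")) val <- FALSE
      vals[[key]] <- val
    }
  }
  for (key in names(overrides)) {
    if (!key %in% names(defaults)) stop("unknown config key: '", key, "'")
    if (!is.null(overrides[[key]])) vals[[key]] <- overrides[[key]]
  }
  cfg <- utils::modifyList(defaults, vals)
  class(cfg) <- "run_config"
  cfg
}

# Atomic writer: everything lands under final names only after all content
# is computed; partially written outputs are never left behind.
.write_atomic <- function(writers, out_dir) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  tmp <- character(0)
  final <- character(0)
  on.exit(unlink(tmp[file.exists(tmp)]), add = TRUE)
  for (name in names(writers)) {
    t <- file.path(out_dir, paste0(".tmp.", name))
    writers[[name]](t)
    tmp <- c(tmp, t)
    final <- c(final, file.path(out_dir, name))
  }
  for (i in seq_along(tmp)) {
    if (!file.rename(tmp[i], final[i])) stop("could not write ", final[i])
  }
  invisible(final)
}

.fmt_num <- function(x) {
  ifelse(is.na(x), "NA", sprintf("%.10g", x))
}

#' Write a results table as TSV
#'
#' Tab-separated, `"."` decimals, 10 significant digits (byte-identical for
#' identical results regardless of input dialect or locale).
#'
#' @param results a `"censmetab_results"` table (or any data frame).
#' @param path output path.
#' @export
write_results_tsv <- function(results, path) {
  df <- as.data.frame(results)
  for (j in seq_along(df)) if (is.numeric(df[[j]])) df[[j]] <- .fmt_num(df[[j]])
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Draw a volcano plot
#'
#' log2 fold-change against -log10 FDR-adjusted p, with the FDR reference
#' line at `fdr_level` (solid) and 0.10 (dotted), and vertical fold-change
#' reference lines at 0.5 and 2.0.
#'
#' @param vt a [volcano_table()] data frame.
#' @param fdr_level horizontal reference level.
#' @param fc_lines fold-change reference values.
#' @param main plot title.
#' @export
plot_volcano <- function(vt, fdr_level = 0.05, fc_lines = c(0.5, 2.0),
                         main = "Volcano plot") {
  sig <- vt$neg_log10_fdr_p > -log10(fdr_level)
  graphics::plot(vt$log2_fc, vt$neg_log10_fdr_p,
                 pch = 19, cex = 0.7,
                 col = ifelse(sig, "firebrick", "grey40"),
                 xlab = expression(log[2] ~ "fold-change"),
                 ylab = expression(-log[10] ~ "FDR p-value"),
                 main = main)
  graphics::abline(h = -log10(fdr_level), lty = 1, col = "grey20")
  graphics::abline(h = -log10(0.10), lty = 3, col = "grey50")
  graphics::abline(v = log2(fc_lines), lty = 2, col = "grey50")
  invisible(vt)
}

#' Run the full analysis from input files
#'
#' Reads the concentration, sample and LOD tables declared in the config,
#' runs the adjusted differential-abundance pipeline, and writes to
#' `out_dir`: `results.tsv` (per-metabolite geometric means, CIs,
#' fold-change, p and FDR p), `descriptives.tsv`, `volcano.tsv`, a
#' `volcano.svg` when an SVG device is available, and `run.log`. Outputs
#' are written atomically: a validation or fit error leaves no partial
#' files. Per-metabolite diagnostics go to the log connection.
#'
#' @param config a [run_config()].
#' @param panel a `"metab_panel"`.
#' @return the results table, invisibly.
#' @export
cmd_run <- function(config, panel = default_panel()) {
  stopifnot(inherits(config, "run_config"))
  for (f in c("concentrations", "samples", "lods")) {
    if (is.null(config[[f]])) stop("config lacks input path '", f, "'")
    if (!file.exists(config[[f]])) stop("input file not found: ", config[[f]])
  }
  log_lines <- character(0)
  say <- function(...) {
    msg <- paste0(...)
    message(msg)
    log_lines <<- c(log_lines, msg)
  }
  say("reading inputs (sep='", ifelse(config$sep == "\t", "\\t", config$sep),
      "', dec='", config$dec, "')")
  mat <- read_concentrations(config$concentrations, config$sep, config$dec)
  samples <- read_samples(config$samples, config$sep, config$dec)
  lods <- read_lods(config$lods, config$sep, config$dec)
  say("loaded ", nrow(mat), " samples x ", ncol(mat), " metabolites")
  spec <- model_spec(covariates = config$covariates, profile = config$profile)
  res <- run_multivariable(mat, samples, lods, panel, spec = spec,
                           min_fraction = config$detect_min,
                           scale_basis = config$scale_basis,
                           include_aggregates = config$include_aggregates)
  res$significant <- res$fdr_p < config$fdr_level
  dropped <- attr(res, "dropped")
  say("tested ", nrow(res), " metabolites; ", length(dropped),
      " dropped by the ", 100 * config$detect_min, "% detection filter; ",
      sum(res$significant, na.rm = TRUE), " significant at FDR < ",
      config$fdr_level)
  for (f in attr(res, "failures")) say("fit failure: ", f)
  groups <- samples$group[match(rownames(mat), samples$sample_id)]
  desc <- describe_matrix(mat, lods, groups)
  vt <- volcano_table(res)
  writers <- list(
    "results.tsv" = function(p) write_results_tsv(res, p),
    "descriptives.tsv" = function(p) write_results_tsv(desc, p),
    "volcano.tsv" = function(p) write_results_tsv(vt, p),
    "run.log" = function(p) writeLines(log_lines, p)
  )
  if (capabilities("cairo")) {
    writers[["volcano.svg"]] <- function(p) {
      grDevices::svg(p, width = 7, height = 6)
      on.exit(grDevices::dev.off())
      plot_volcano(vt, fdr_level = config$fdr_level)
    }
  }
  .write_atomic(writers, config$out_dir)
  invisible(res)
}

#' Simulate a cohort and write its dataset files
#'
#' @param cfg a [sim_config()].
#' @param out_dir output directory; writes `concentrations.tsv`,
#'   `samples.tsv`, `lods.tsv` and `truth.tsv`.
#' @return the simulated bundle, invisibly.
#' @export
cmd_simulate <- function(cfg, out_dir = ".") {
  sim <- simulate_cohort(cfg)
  truth_df <- data.frame(metabolite = cfg$metabolite,
                         true_fc = sim$truth$fc,
                         censor_quantile = sim$truth$censor_quantile,
                         log_mean = sim$truth$log_mean,
                         log_sd = sim$truth$log_sd)
  .write_atomic(list(
    "concentrations.tsv" = function(p) write_concentrations(sim$concentrations, p),
    "samples.tsv" = function(p) write_samples(sim$samples, p),
    "lods.tsv" = function(p) write_lods(sim$lods, p),
    "truth.tsv" = function(p) write_results_tsv(truth_df, p)
  ), out_dir)
  invisible(sim)
}

#' Write the descriptive-statistics table for input files
#'
#' @param config a [run_config()] naming the input files.
#' @param path output TSV path.
#' @return the descriptive table, invisibly.
#' @export
cmd_describe <- function(config, path = file.path(config$out_dir, "descriptives.tsv")) {
  mat <- read_concentrations(config$concentrations, config$sep, config$dec)
  samples <- read_samples(config$samples, config$sep, config$dec)
  lods <- read_lods(config$lods, config$sep, config$dec)
  groups <- samples$group[match(rownames(mat), samples$sample_id)]
  desc <- describe_matrix(mat, lods, groups)
  .write_atomic(stats::setNames(
    list(function(p) write_results_tsv(desc, p)), basename(path)),
    dirname(path))
  invisible(desc)
}

#' Path to the packaged reference results table
#'
#' The published multivariable Tobit results for the 32 vs 32 PWS-vs-EOB
#' plasma cohort the package's conventions follow: the 28 FDR-significant
#' metabolites with group geometric means, 95% CIs, fold-changes and
#' (FDR-adjusted) p-values, transcribed with the original decimal-comma
#' dialect. P-values printed as `<0.0001` carry that bound as value with
#' `p_censored = yes`.
#'
#' @return file path inside the installed package.
#' @export
reference_results_path <- function() {
  system.file("extdata", "reference_results.tsv", package = "censmetab",
              mustWork = TRUE)
}

#' Read the packaged reference results table
#'
#' @return data frame with numeric columns parsed from the decimal-comma
#'   dialect; see [reference_results_path()].
#' @export
read_reference_results <- function() {
  path <- reference_results_path()
  raw <- utils::read.table(path, sep = "\t", header = TRUE,
                           check.names = FALSE, colClasses = "character",
                           quote = "", comment.char = "")
  num_cols <- setdiff(colnames(raw), c("metabolite", "p_censored"))
  for (col in num_cols) {
    raw[[col]] <- as.numeric(gsub(",", ".", raw[[col]], fixed = TRUE))
  }
  raw$n_below_lb <- as.integer(raw$n_below_lb)
  raw$p_censored <- raw$p_censored == "yes"
  raw
}
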