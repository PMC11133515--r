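#' Readers and writers for concentration, LOD and sample tables
#'
#' All inputs are delimited text. The dialect (field separator and decimal
#' mark) is declared by the caller; published tables in this field often use
#' the decimal comma, so both `dec = "."` and `dec = ","` are supported.
#' Output is always written with `"."` decimals and tab separation.
#'
#' @name panel_io
NULL

.parse_numeric <- function(x, dec, what, rows, cols) {
  x <- trimws(x)
  if (dec == ",") x <- gsub(",", ".", x, fixed = TRUE)
  bad_mark <- grepl("<", x, fixed = TRUE)
  if (any(bad_mark)) {
    i <- which(bad_mark)[1]
    stop(what, ": censoring markup such as '<LOD' is not accepted ",
         "(row ", rows[i], ", column '", cols[i], "'); censoring is derived ",
         "from the LOD table")
  }
  out <- suppressWarnings(as.numeric(x))
  failed <- is.na(out) & !(x %in% c("", "NA", "na", "NaN"))
  if (any(failed)) {
    i <- which(failed)[1]
    stop(what, ": unparseable cell '", x[i], "' at row ", rows[i],
         ", column '", cols[i], "'")
  }
  out
}

#' Read a wide concentration matrix
#'
#' First column holds sample ids, the header row metabolite ids, cells are
#' non-negative concentrations (uM). Empty cells and `NA` become missing
#' values; `"<LOD"`-style markup is rejected because censoring is derived
#' from the LOD table, never from cell markup.
#'
#' @param path file path.
#' @param sep field separator (default tab).
#' @param dec decimal mark, `"."` or `","`.
#' @return numeric matrix, samples in rows (rownames = sample ids),
#'   metabolites in columns.
#' @export
read_concentrations <- function(path, sep = "\t", dec = ".") {
  stopifnot(dec %in% c(".", ","))
  raw <- utils::read.table(path, sep = sep, header = TRUE, check.names = FALSE,
                           colClasses = "character", quote = "\"",
                           comment.char = "")
  if (ncol(raw) < 2) stop("concentration file needs a sample-id column and at least one metabolite")
  sample_ids <- trimws(raw[[1]])
  if (anyDuplicated(sample_ids) > 0) {
    stop("duplicated sample ids: ",
         paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", "))
  }
  met_ids <- colnames(raw)[-1]
  if (anyDuplicated(met_ids) > 0) {
    stop("duplicated metabolite ids: ",
         paste(unique(met_ids[duplicated(met_ids)]), collapse = ", "))
  }
  cells <- as.matrix(raw[, -1, drop = FALSE])
  rows <- rep(sample_ids, times = ncol(cells))
  cols <- rep(met_ids, each = nrow(cells))
  vals <- .parse_numeric(as.vector(cells), dec, "concentration matrix", rows, cols)
  if (any(vals < 0, na.rm = TRUE)) {
    i <- which(vals < 0)[1]
    stop("negative concentration at row ", rows[i], ", column '", cols[i], "'")
  }
  mat <- matrix(vals, nrow = nrow(cells), ncol = ncol(cells),
                dimnames = list(sample_ids, met_ids))
  mat
}

#' Write a concentration matrix
#'
#' Tab-separated, `"."` decimals, full precision (round-trips losslessly
#' through [read_concentrations()]).
#'
#' @param mat numeric matrix with sample rownames.
#' @param path output file path.
#' @param id_col header name for the sample-id column.
#' @export
write_concentrations <- function(mat, path, id_col = "sample_id") {
  df <- data.frame(rownames(mat), mat, check.names = FALSE,
                   stringsAsFactors = FALSE)
  colnames(df)[1] <- id_col
  utils::write.table(format(df, digits = 17, trim = TRUE, scientific = FALSE),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a per-metabolite LOD table
#'
#' Two columns: metabolite id, LOD (uM, strictly positive).
#'
#' @inheritParams read_concentrations
#' @return named numeric vector of LODs.
#' @export
read_lods <- function(path, sep = "\t", dec = ".") {
  stopifnot(dec %in% c(".", ","))
  raw <- utils::read.table(path, sep = sep, header = TRUE, check.names = FALSE,
                           colClasses = "character", quote = "\"",
                           comment.char = "")
  if (nrow(raw) == 0) stop("LOD file is empty")
  ids <- trimws(raw[[1]])
  if (anyDuplicated(ids) > 0) {
    stop("duplicated metabolite ids in LOD table: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  lod <- .parse_numeric(raw[[2]], dec, "LOD table", ids, rep("LOD", nrow(raw)))
  if (any(is.na(lod))) stop("missing LOD for: ", paste(ids[is.na(lod)], collapse = ", "))
  if (any(lod <= 0)) {
    stop("LOD must be strictly positive; offenders: ",
         paste(ids[lod <= 0], collapse = ", "))
  }
  stats::setNames(lod, ids)
}

#' Write an LOD table
#' @param lods named numeric vector.
#' @param path output file path.
#' @export
write_lods <- function(lods, path) {
  utils::write.table(
    data.frame(metabolite = names(lods),
               lod = format(unname(lods), digits = 17, trim = TRUE,
                            scientific = FALSE)),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a sample metadata table
#'
#' Required columns: `sample_id`, `group` (`case`/`control`), `sex`
#' (`M`/`F`). Any further columns (age, bmi, dbp, crp, drug flags, ...) are
#' parsed as numeric where possible and kept as-is otherwise.
#'
#' @inheritParams read_concentrations
#' @return a `data.frame` with one row per sample.
#' @export
read_samples <- function(path, sep = "\t", dec = ".") {
  stopifnot(dec %in% c(".", ","))
  raw <- utils::read.table(path, sep = sep, header = TRUE, check.names = FALSE,
                           colClasses = "character", quote = "\"",
                           comment.char = "")
  req <- c("sample_id", "group", "sex")
  miss <- setdiff(req, colnames(raw))
  if (length(miss) > 0) stop("sample table lacks columns: ", paste(miss, collapse = ", "))
  raw$sample_id <- trimws(raw$sample_id)
  if (anyDuplicated(raw$sample_id) > 0) {
    stop("duplicated sample ids: ",
         paste(unique(raw$sample_id[duplicated(raw$sample_id)]), collapse = ", "))
  }
  if (!all(raw$group %in% c("case", "control"))) {
    stop("group must be 'case' or 'control'")
  }
  if (!all(raw$sex %in% c("M", "F"))) stop("sex must be 'M' or 'F'")
  for (col in setdiff(colnames(raw), req)) {
    x <- trimws(raw[[col]])
    if (dec == ",") x <- gsub(",", ".", x, fixed = TRUE)
    num <- suppressWarnings(as.numeric(x))
    if (!any(is.na(num) & !(x %in% c("", "NA")))) raw[[col]] <- num
  }
  raw
}

#' Write a sample metadata table
#' @param samples a sample data frame.
#' @param path output file path.
#' @export
write_samples <- function(samples, path) {
  utils::write.table(samples, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Append aggregate ("sum") columns to a concentration matrix
#'
#' Each aggregate of the panel becomes one column: the sum of its member
#' concentrations, with below-LOD members contributing LOD/2 (a sum of
#' positive terms is always observed, so aggregates are never censored and
#' carry no LOD). Missing members propagate to a missing sum.
#'
#' @param mat concentration matrix of measured metabolites.
#' @param panel a `"metab_panel"` with aggregate definitions.
#' @param lods named LOD vector covering every member metabolite.
#' @return the matrix with one extra column per aggregate.
#' @export
compute_aggregates <- function(mat, panel, lods) {
  stopifnot(inherits(panel, "metab_panel"))
  members <- attr(panel, "members")
  if (length(members) == 0) return(mat)
  collide <- intersect(names(members), colnames(mat))
  if (length(collide) > 0) {
    stop("aggregate name(s) already present as measured columns: ",
         paste(collide, collapse = ", "))
  }
  for (a in names(members)) {
    mem <- members[[a]]
    miss <- setdiff(mem, colnames(mat))
    if (length(miss) > 0) {
      stop("aggregate '", a, "' members missing from matrix: ",
           paste(miss, collapse = ", "))
    }
    sub <- mat[, mem, drop = FALSE]
    for (m in mem) {
      lod <- .lod_of(lods, m)
      if (is.null(lod)) stop("no LOD for aggregate member '", m, "'")
      v <- sub[, m]
      v[!is.na(v) & v < lod] <- lod / 2
      sub[, m] <- v
    }
    mat <- cbind(mat, rowSums(sub))
    colnames(mat)[ncol(mat)] <- a
  }
  mat
}

# LOD lookup returning NULL (not an error) for ids without an LOD,
# e.g. aggregate columns.
.lod_of <- function(lods, id) {
  if (id %in% names(lods)) unname(lods[[id]]) else NULL
}
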