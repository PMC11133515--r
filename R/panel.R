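#' Metabolite panel construction and validation
#'
#' A panel is a data frame with one row per analyte and columns
#' `id`, `class`, `unit`, `is_aggregate`, plus an attribute `members`
#' (a named list mapping each aggregate id to its member ids).
#' Aggregate ("sum") variables are derived columns such as `lysoPC_s`
#' and carry no LOD of their own.
#'
#' @param id character vector of analyte identifiers.
#' @param class metabolite class, one of [metabolite_classes()], recycled.
#' @param aggregates named list: aggregate id -> character vector of member
#'   ids (each with at least two members, all present in `id`).
#' @param unit concentration unit, stored as metadata.
#' @return A `data.frame` of class `"metab_panel"`.
#' @seealso [default_panel()] for the packaged 188-metabolite panel.
#' @export
make_panel <- function(id, class, aggregates = list(), unit = "uM") {
  if (anyDuplicated(id) > 0) {
    stop("duplicated metabolite ids in panel: ",
         paste(unique(id[duplicated(id)]), collapse = ", "))
  }
  class <- rep_len(class, length(id))
  bad <- setdiff(unique(class), metabolite_classes())
  if (length(bad) > 0) {
    stop("unknown metabolite class(es): ", paste(bad, collapse = ", "))
  }
  agg_ids <- names(aggregates)
  if (length(aggregates) > 0) {
    if (is.null(agg_ids) || any(agg_ids == "")) stop("aggregates must be named")
    if (any(agg_ids %in% id)) {
      stop("aggregate name collides with a measured metabolite: ",
           paste(intersect(agg_ids, id), collapse = ", "))
    }
    for (a in agg_ids) {
      mem <- aggregates[[a]]
      if (length(mem) < 2) {
        stop("aggregate '", a, "' must reference at least 2 members")
      }
      missing_mem <- setdiff(mem, id)
      if (length(missing_mem) > 0) {
        stop("aggregate '", a, "' references unknown members: ",
             paste(missing_mem, collapse = ", "))
      }
    }
  }
  panel <- data.frame(
    id = c(id, agg_ids),
    class = c(class, rep("aggregate", length(agg_ids))),
    unit = unit,
    is_aggregate = c(rep(FALSE, length(id)), rep(TRUE, length(agg_ids))),
    stringsAsFactors = FALSE
  )
  attr(panel, "members") <- aggregates
  class(panel) <- c("metab_panel", "data.frame")
  panel
}

#' Recognised metabolite classes
#'
#' The eight analyte classes of the packaged panel. `"aggregate"` marks
#' derived sum variables.
#' @return character vector of class names.
#' @export
metabolite_classes <- function() {
  c("amino_acid", "biogenic_amine", "hexose", "acylcarnitine",
    "sphingolipid", "lysoPC_a", "PC_aa", "PC_ae", "aggregate")
}

# Analyte name blocks for the packaged 188-metabolite targeted panel
# (21 amino acids, 21 biogenic amines, 1 hexose, 40 acylcarnitines,
#  15 sphingolipids, 90 glycerophospholipids = 14 lysoPC a + 38 PC aa +
#  38 PC ae), standard p180-style nomenclature.
.panel_amino_acids <- c(
  "Ala", "Arg", "Asn", "Asp", "Cit", "Gln", "Glu", "Gly", "His", "Ile",
  "Leu", "Lys", "Met", "Orn", "Phe", "Pro", "Ser", "Thr", "Trp", "Tyr",
  "Val"
)

.panel_biogenic_amines <- c(
  "Ac-Orn", "ADMA", "alpha-AAA", "Carnosine", "Creatinine", "DOPA",
  "Dopamine", "Histamine", "Kynurenine", "Met-SO", "Nitro-Tyr", "PEA",
  "Putrescine", "Sarcosine", "SDMA", "Serotonin", "Spermidine",
  "Spermine", "t4-OH-Pro", "Taurine", "total-DMA"
)

.panel_acylcarnitines <- c(
  "C0", "C2", "C3", "C3-DC (C4-OH)", "C3-OH", "C3:1", "C4", "C4:1", "C5",
  "C5-DC (C6-OH)", "C5-M-DC", "C5-OH (C3-DC-M)", "C5:1", "C5:1-DC",
  "C6 (C4:1-DC)", "C6:1", "C7-DC", "C8", "C9", "C10", "C10:1", "C10:2",
  "C12", "C12-DC", "C12:1", "C14", "C14:1", "C14:1-OH", "C14:2",
  "C14:2-OH", "C16", "C16-OH", "C16:1", "C16:1-OH", "C16:2", "C16:2-OH",
  "C18", "C18:1", "C18:1-OH", "C18:2"
)

.panel_sphingolipids <- c(
  "SM (OH) C14:1", "SM (OH) C16:1", "SM (OH) C22:1", "SM (OH) C22:2",
  "SM (OH) C24:1", "SM C16:0", "SM C16:1", "SM C18:0", "SM C18:1",
  "SM C20:2", "SM C22:3", "SM C24:0", "SM C24:1", "SM C26:0", "SM C26:1"
)

.panel_lysopc <- paste("lysoPC a", c(
  "C14:0", "C16:0", "C16:1", "C17:0", "C18:0", "C18:1", "C18:2", "C20:3",
  "C20:4", "C24:0", "C26:0", "C26:1", "C28:0", "C28:1"
))

.panel_pc_aa <- paste("PC aa", c(
  "C24:0", "C26:0", "C28:1", "C30:0", "C30:2", "C32:0", "C32:1", "C32:2",
  "C32:3", "C34:1", "C34:2", "C34:3", "C34:4", "C36:0", "C36:1", "C36:2",
  "C36:3", "C36:4", "C36:5", "C36:6", "C38:0", "C38:1", "C38:3", "C38:4",
  "C38:5", "C38:6", "C40:1", "C40:2", "C40:3", "C40:4", "C40:5", "C40:6",
  "C42:0", "C42:1", "C42:2", "C42:4", "C42:5", "C42:6"
))

.panel_pc_ae <- paste("PC ae", c(
  "C30:0", "C30:1", "C30:2", "C32:1", "C32:2", "C34:0", "C34:1", "C34:2",
  "C34:3", "C36:0", "C36:1", "C36:2", "C36:3", "C36:4", "C36:5", "C38:0",
  "C38:1", "C38:2", "C38:3", "C38:4", "C38:5", "C38:6", "C40:1", "C40:2",
  "C40:3", "C40:4", "C40:5", "C40:6", "C42:0", "C42:1", "C42:2", "C42:3",
  "C42:4", "C42:5", "C44:3", "C44:4", "C44:5", "C44:6"
))

#' The packaged 188-metabolite targeted panel
#'
#' Builds the default plasma panel: 21 amino acids, 21 biogenic amines,
#' 1 hexose (H1), 40 acylcarnitines, 15 sphingolipids and 90
#' glycerophospholipids (14 lysoPC a, 38 PC aa, 38 PC ae), with three
#' derived class sums (`lysoPC_s`, `PC aa_s`, `PC ae_s`).
#'
#' @return A `"metab_panel"` data frame with 188 measured analytes plus
#'   3 aggregates.
#' @examples
#' p <- default_panel()
#' table(p$class)
#' @export
default_panel <- function() {
  make_panel(
    id = c(.panel_amino_acids, .panel_biogenic_amines, "H1",
           .panel_acylcarnitines, .panel_sphingolipids, .panel_lysopc,
           .panel_pc_aa, .panel_pc_ae),
    class = c(rep("amino_acid", length(.panel_amino_acids)),
              rep("biogenic_amine", length(.panel_biogenic_amines)),
              "hexose",
              rep("acylcarnitine", length(.panel_acylcarnitines)),
              rep("sphingolipid", length(.panel_sphingolipids)),
              rep("lysoPC_a", length(.panel_lysopc)),
              rep("PC_aa", length(.panel_pc_aa)),
              rep("PC_ae", length(.panel_pc_ae))),
    aggregates = list(
      "lysoPC_s" = .panel_lysopc,
      "PC aa_s" = .panel_pc_aa,
      "PC ae_s" = .panel_pc_ae
    )
  )
}

#' Per-class analyte counts of a panel
#'
#' @param panel a `"metab_panel"` object.
#' @param include_aggregates count aggregate entries as their own class?
#' @return named integer vector of counts.
#' @export
panel_class_counts <- function(panel, include_aggregates = FALSE) {
  stopifnot(inherits(panel, "metab_panel"))
  p <- if (include_aggregates) panel else panel[!panel$is_aggregate, ]
  tab <- table(factor(p$class, levels = metabolite_classes()))
  out <- as.integer(tab)
  names(out) <- names(tab)
  if (!include_aggregates) out <- out[names(out) != "aggregate"]
  out
}

#' Member ids of an aggregate variable
#' @param panel a `"metab_panel"` object.
#' @param id aggregate identifier.
#' @return character vector of member ids.
#' @export
aggregate_members <- function(panel, id) {
  stopifnot(inherits(panel, "metab_panel"))
  members <- attr(panel, "members")
  if (!id %in% names(members)) stop("'", id, "' is not an aggregate of this panel")
  members[[id]]
}

#' @export
print.metab_panel <- function(x, ...) {
  n_meas <- sum(!x$is_aggregate)
  cat("Metabolite panel:", n_meas, "measured analytes,",
      sum(x$is_aggregate), "aggregates\n")
  cnt <- panel_class_counts(x)
  cnt <- cnt[cnt > 0]
  cat(paste0("  ", names(cnt), ": ", cnt, collapse = "\n"), "\n")
  invisible(x)
}

#' Validate a concentration matrix and LOD table against a panel
#'
#' Checks that every measured (non-aggregate) metabolite in the matrix is
#' known to the panel and carries exactly one strictly positive LOD.
#'
#' @param mat concentration matrix (see [read_concentrations()]).
#' @param panel a `"metab_panel"` object.
#' @param lods named numeric vector of LODs (see [read_lods()]).
#' @return invisibly `TRUE`; stops with a message listing offenders otherwise.
#' @export
validate_panel_data <- function(mat, panel, lods) {
  stopifnot(inherits(panel, "metab_panel"))
  ids <- colnames(mat)
  unknown <- setdiff(ids, panel$id)
  if (length(unknown) > 0) {
    stop("metabolites absent from panel: ", paste(unknown, collapse = ", "))
  }
  measured <- ids[!ids %in% panel$id[panel$is_aggregate]]
  no_lod <- setdiff(measured, names(lods))
  if (length(no_lod) > 0) {
    stop("measured metabolites without an LOD: ",
         paste(no_lod, collapse = ", "))
  }
  agg_lod <- intersect(names(lods), panel$id[panel$is_aggregate])
  if (length(agg_lod) > 0) {
    stop("aggregate variables must not carry an LOD: ",
         paste(agg_lod, collapse = ", "))
  }
  invisible(TRUE)
}
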