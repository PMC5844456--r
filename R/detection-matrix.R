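# Five-valued detection alphabet used in compound screening tables.
# CSV symbol -> state: D detected, N not_detected, P partial (compound found
# in a part of the analysed individuals/species only), I inconclusive
# (no conclusive data), M missing (no data collected for that cell).
.detection_symbols <- c(D = "detected", N = "not_detected", P = "partial",
                        I = "inconclusive", M = "missing")

#' The five detection states
#'
#' @return Character vector of the five admissible cell states of a
#'   detection matrix.
#' @export
detection_states <- function() unname(.detection_symbols)

#' Read a compound-detection table
#'
#' Reads a taxa-by-compounds screening table in which each cell records one
#' of five detection states (see [detection_states()]), encoded in the CSV as
#' single letters `D`, `N`, `P`, `I`, `M`. The header row must name compound
#' codes known to the supplied library; the first column holds the taxon
#' label.
#'
#' @param path Path to the detection CSV.
#' @param library A `compound_library` (default: the packaged quinone
#'   library) used to validate the column codes.
#' @param lineage Optional path to (or data frame of) a lineage sidecar table
#'   with columns `taxon`, `suborder`, `superfamily`, `family`, `subfamily`,
#'   `genus`, used by rank filters in [summarize_detections()].
#' @return An object of class `detection_matrix`: a list with elements
#'   `states` (character matrix, taxa x compounds, values in
#'   [detection_states()]), `library`, and `lineage` (data frame or `NULL`).
#' @export
#' @examples
#' dm <- read_detection_table(chemo_example("detections_eupnoi.csv"))
#' dm
read_detection_table <- function(path, library = quinone_library(),
                                 lineage = NULL) {
  if (!file.exists(path)) stop("detection table not found: ", path,
                               call. = FALSE)
  if (file.size(path) == 0) {
    stop("detection table is empty: ", path, call. = FALSE)
  }
  fields <- count.fields(path, sep = ",", quote = "\"")
  if (length(fields) < 2) {
    stop("detection table has no data rows: ", path, call. = FALSE)
  }
  ragged <- which(fields != fields[1])
  if (length(ragged) > 0) {
    stop("ragged row in detection table: row ", ragged[1] - 1L,
         " has ", fields[ragged[1]], " fields, expected ", fields[1],
         call. = FALSE)
  }
  raw <- read.csv(path, stringsAsFactors = FALSE, encoding = "UTF-8",
                  check.names = FALSE)
  if (ncol(raw) < 2) stop("detection table needs a taxon column and at least ",
                          "one compound column", call. = FALSE)
  codes <- names(raw)[-1]
  unknown <- setdiff(codes, library$code)
  if (length(unknown) > 0) {
    stop("unknown compound code in column(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  taxa <- raw[[1]]
  if (anyDuplicated(taxa)) {
    stop("duplicate taxon label(s): ",
         paste(unique(taxa[duplicated(taxa)]), collapse = ", "),
         call. = FALSE)
  }
  cells <- as.matrix(raw[-1])
  ok <- matrix(cells %in% names(.detection_symbols), nrow = nrow(cells))
  bad <- which(!ok, arr.ind = TRUE)
  if (nrow(bad) > 0) {
    stop("invalid detection symbol ", sQuote(cells[bad[1, , drop = FALSE]]),
         " at taxon ", sQuote(taxa[bad[1, 1]]),
         ", column ", sQuote(codes[bad[1, 2]]),
         " (expected one of D, N, P, I, M)", call. = FALSE)
  }
  states <- matrix(.detection_symbols[cells], nrow = nrow(cells),
                   dimnames = list(taxa, codes))
  if (is.character(lineage)) lineage <- read_lineage(lineage)
  if (!is.null(lineage)) {
    lineage <- lineage[lineage$taxon %in% taxa, , drop = FALSE]
  }
  structure(list(states = states,
                 library = library[library$code %in% codes, , drop = FALSE],
                 lineage = lineage),
            class = "detection_matrix")
}

#' Read a taxon lineage sidecar table
#'
#' @param path CSV with columns `taxon`, `suborder`, `superfamily`, `family`,
#'   `subfamily`, `genus` (higher ranks may be empty where a terminal is an
#'   aggregate above that rank).
#' @return A data frame.
#' @export
read_lineage <- function(path) {
  if (!file.exists(path)) stop("lineage table not found: ", path,
                               call. = FALSE)
  lin <- read.csv(path, stringsAsFactors = FALSE, encoding = "UTF-8")
  needed <- c("taxon", "suborder", "superfamily", "family", "subfamily",
              "genus")
  missing_cols <- setdiff(needed, names(lin))
  if (length(missing_cols) > 0) {
    stop("lineage table is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(lin$taxon)) {
    stop("duplicate taxon in lineage table", call. = FALSE)
  }
  lin
}

#' Combine detection matrices over disjoint taxon sets
#'
#' Stacks detection matrices that share the same compound columns, e.g. the
#' per-suborder screening tables of a study.
#'
#' @param ... `detection_matrix` objects.
#' @return A single `detection_matrix`.
#' @export
bind_detection_matrices <- function(...) {
  mats <- list(...)
  if (length(mats) == 1 && is.list(mats[[1]]) &&
      !inherits(mats[[1]], "detection_matrix")) {
    mats <- mats[[1]]
  }
  stopifnot(length(mats) >= 1,
            all(vapply(mats, inherits, logical(1), "detection_matrix")))
  codes <- colnames(mats[[1]]$states)
  for (m in mats[-1]) {
    if (!identical(colnames(m$states), codes)) {
      stop("detection matrices have different compound columns",
           call. = FALSE)
    }
  }
  states <- do.call(rbind, lapply(mats, `[[`, "states"))
  if (anyDuplicated(rownames(states))) {
    stop("duplicate taxon label(s) across matrices: ",
         paste(unique(rownames(states)[duplicated(rownames(states))]),
               collapse = ", "), call. = FALSE)
  }
  lineages <- Filter(Negate(is.null), lapply(mats, `[[`, "lineage"))
  lineage <- if (length(lineages) > 0) do.call(rbind, lineages) else NULL
  structure(list(states = states, library = mats[[1]]$library,
                 lineage = lineage),
            class = "detection_matrix")
}

#' @export
print.detection_matrix <- function(x, ...) {
  cat("Compound-detection matrix:", nrow(x$states), "taxa x",
      ncol(x$states), "compounds\n")
  tab <- table(factor(x$states, levels = detection_states()))
  cat("cells:", paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
  if (!is.null(x$lineage)) cat("lineage ranks attached\n")
  invisible(x)
}

#' Summarise positive detections under taxon and state filters
#'
#' Counts, over a filtered slice of a detection matrix, how many compounds
#' have at least one cell in the given states, and how many taxa are positive
#' per compound. Used to reproduce the compiled counts of a screening study
#' (e.g. number of distinct quinones detected, or species per genus positive
#' for a compound).
#'
#' @param x A `detection_matrix`.
#' @param states Detection states counted as positive (default: detected or
#'   partial).
#' @param compounds Optional compound codes to restrict to.
#' @param taxa Optional explicit taxon labels to restrict to.
#' @param suborder,superfamily,family,subfamily,genus Optional lineage-rank
#'   filters (require a lineage table; unknown rank values are an error).
#' @return A list of class `detection_summary` with `n_taxa`,
#'   `n_compounds_positive`, and `taxa_per_compound` (named integer vector).
#' @export
#' @examples
#' dm <- read_detection_table(chemo_example("detections_eupnoi.csv"),
#'                            lineage = chemo_example("lineages.csv"))
#' summarize_detections(dm, genus = "Megabunus", compounds = "BQ",
#'                      states = "detected")
summarize_detections <- function(x, states = c("detected", "partial"),
                                 compounds = NULL, taxa = NULL,
                                 suborder = NULL, superfamily = NULL,
                                 family = NULL, subfamily = NULL,
                                 genus = NULL) {
  stopifnot(inherits(x, "detection_matrix"))
  bad_states <- setdiff(states, detection_states())
  if (length(bad_states) > 0) {
    stop("unknown detection state(s): ", paste(bad_states, collapse = ", "),
         call. = FALSE)
  }
  m <- x$states
  keep <- rep(TRUE, nrow(m))
  if (!is.null(taxa)) {
    bad <- setdiff(taxa, rownames(m))
    if (length(bad) > 0) stop("unknown taxon: ", paste(bad, collapse = ", "),
                              call. = FALSE)
    keep <- keep & rownames(m) %in% taxa
  }
  ranks <- list(suborder = suborder, superfamily = superfamily,
                family = family, subfamily = subfamily, genus = genus)
  ranks <- Filter(Negate(is.null), ranks)
  if (length(ranks) > 0) {
    if (is.null(x$lineage)) {
      stop("rank filters need a lineage table (see read_detection_table)",
           call. = FALSE)
    }
    lin <- x$lineage[match(rownames(m), x$lineage$taxon), , drop = FALSE]
    for (rk in names(ranks)) {
      vals <- ranks[[rk]]
      bad <- setdiff(vals, x$lineage[[rk]])
      if (length(bad) > 0) {
        stop("unknown ", rk, " value: ", paste(bad, collapse = ", "),
             call. = FALSE)
      }
      keep <- keep & !is.na(lin[[rk]]) & lin[[rk]] %in% vals
    }
  }
  if (!is.null(compounds)) {
    bad <- setdiff(compounds, colnames(m))
    if (length(bad) > 0) stop("unknown compound code: ",
                              paste(bad, collapse = ", "), call. = FALSE)
    m <- m[, compounds, drop = FALSE]
  }
  m <- m[keep, , drop = FALSE]
  pos <- matrix(m %in% states, nrow = nrow(m), dimnames = dimnames(m))
  taxa_per_compound <- colSums(pos)
  structure(list(n_taxa = nrow(m),
                 n_compounds_positive = sum(taxa_per_compound > 0),
                 taxa_per_compound = taxa_per_compound,
                 states = states),
            class = "detection_summary")
}

#' @export
print.detection_summary <- function(x, ...) {
  cat("Detections over", x$n_taxa, "taxa (positive states:",
      paste(x$states, collapse = ", "), ")\n")
  cat("compounds with >= 1 positive cell:", x$n_compounds_positive, "\n")
  pos <- x$taxa_per_compound[x$taxa_per_compound > 0]
  if (length(pos) > 0) {
    cat("taxa positive per compound:\n")
    print(pos)
  }
  invisible(x)
}
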