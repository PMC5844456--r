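#' Read a compound reference library
#'
#' A compound library records, for each short compound code, the full name,
#' the compound class, the Kovats retention index (RI), the molecular ion and
#' the diagnostic EI fragment ions. It drives both detection-table validation
#' (column codes must be known) and RI-based peak identification.
#'
#' The expected CSV columns are `code`, `name`, `compound_class`, `ri`,
#' `molecular_ion` and `diagnostic_ions` (semicolon-separated m/z integers,
#' listed in descending order). `ri`, `molecular_ion` and `diagnostic_ions`
#' may be empty for compounds recorded only as presence/absence classes.
#'
#' @param path Path to a library CSV.
#' @return A data frame of class `compound_library` with one row per
#'   compound; `diagnostic_ions` is a list column of integer vectors.
#' @seealso [quinone_library()] for the packaged quinone library.
#' @export
read_compound_library <- function(path) {
  if (!file.exists(path)) stop("library file not found: ", path, call. = FALSE)
  lib <- read.csv(path, stringsAsFactors = FALSE, encoding = "UTF-8")
  needed <- c("code", "name", "compound_class", "ri", "molecular_ion",
              "diagnostic_ions")
  missing_cols <- setdiff(needed, names(lib))
  if (length(missing_cols) > 0) {
    stop("library is missing column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(lib$code)) {
    stop("duplicate compound codes in library: ",
         paste(unique(lib$code[duplicated(lib$code)]), collapse = ", "),
         call. = FALSE)
  }
  lib$ri <- as.numeric(lib$ri)
  if (any(!is.na(lib$ri) & lib$ri <= 0)) {
    stop("retention indices must be positive", call. = FALSE)
  }
  lib$molecular_ion <- as.integer(lib$molecular_ion)
  ions <- strsplit(as.character(lib$diagnostic_ions), ";", fixed = TRUE)
  lib$diagnostic_ions <- lapply(ions, function(v) {
    v <- suppressWarnings(as.integer(v[nzchar(v)]))
    if (anyNA(v)) stop("non-integer diagnostic ion in library", call. = FALSE)
    v
  })
  for (i in seq_len(nrow(lib))) {
    v <- lib$diagnostic_ions[[i]]
    if (length(v) > 1 && any(diff(v) > 0)) {
      stop("diagnostic ions must be sorted in descending order (code ",
           lib$code[i], ")", call. = FALSE)
    }
    if (length(v) > 0 && !is.na(lib$molecular_ion[i]) &&
        any(v >= lib$molecular_ion[i] + 2)) {
      stop("diagnostic ion above molecular ion + 2 (code ", lib$code[i], ")",
           call. = FALSE)
    }
  }
  class(lib) <- c("compound_library", "data.frame")
  lib
}

#' Packaged quinone reference library
#'
#' GC-MS reference data (retention indices, molecular ions, diagnostic EI
#' fragments) for the nine quinonic compounds recorded from harvestman scent
#' glands -- 1,4-benzoquinone (BQ), 1,4-naphthoquinone (NQ),
#' 1,4-naphthalenediol (ND), 6-methyl-1,4-naphthoquinone (MNQ),
#' 4-chloro-1,2-naphthoquinone (CNQ), 2-methoxy-1,4-naphthoquinone (MOQ),
#' methoxy-methyl-1,4-naphthoquinone (MMOQ), 2-methyl-9,10-anthraquinone
#' (MAQ), 1,2-dimethyl-9,10-anthraquinone (DMAQ) -- plus the alkylated
#' benzoquinone class (ABQ) recorded from laniatorean secretions as a
#' presence/absence class without reference RI.
#'
#' @return A `compound_library` data frame (see [read_compound_library()]).
#' @export
quinone_library <- function() {
  read_compound_library(chemo_example("quinone_library.csv"))
}
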