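#' Read an n-alkane ladder
#'
#' @param path CSV with columns `n` (carbon number) and `t` (retention time,
#'   minutes); at least two rows, both columns strictly increasing.
#' @return A data frame of class `alkane_ladder`.
#' @export
read_alkane_ladder <- function(path) {
  lad <- read.csv(path, stringsAsFactors = FALSE)
  alkane_ladder(lad$n, lad$t)
}

#' Construct an alkane ladder
#'
#' @param n Integer carbon numbers, strictly increasing.
#' @param t Retention times in minutes, strictly increasing.
#' @return A data frame of class `alkane_ladder`.
#' @export
alkane_ladder <- function(n, t) {
  if (is.null(n) || is.null(t) || length(n) != length(t) || length(n) < 2) {
    stop("an alkane ladder needs matching n and t with >= 2 entries",
         call. = FALSE)
  }
  if (any(diff(n) <= 0) || any(diff(t) <= 0)) {
    stop("alkane ladder must be strictly increasing in n and t",
         call. = FALSE)
  }
  structure(data.frame(n = as.integer(n), t = as.numeric(t)),
            class = c("alkane_ladder", "data.frame"))
}

#' Kovats retention index
#'
#' Computes the retention index of a peak eluting at `t_x` by linear
#' interpolation between the alkanes bracketing it:
#' `RI = 100 * n0 + 100 * (t_x - t_n0) / (t_n1 - t_n0)`, with `n0` the
#' carbon number of the alkane eluting directly before the peak. Linear
#' interpolation is the appropriate form for a linear oven temperature
#' programme; an alkane itself indexes exactly to `100 * n`.
#'
#' @param t_x Retention time(s) in minutes.
#' @param ladder An [alkane_ladder()].
#' @param extrapolate Permit linear extrapolation (with a warning) beyond
#'   the ladder span; off by default.
#' @return Numeric retention indices, dimensionless.
#' @export
#' @examples
#' lad <- alkane_ladder(9:10, c(9, 10))
#' kovats_ri(9.5, lad)   # 950
kovats_ri <- function(t_x, ladder, extrapolate = FALSE) {
  stopifnot(inherits(ladder, "alkane_ladder"))
  out_of_range <- t_x < ladder$t[1] | t_x > ladder$t[nrow(ladder)]
  if (any(out_of_range)) {
    if (!extrapolate) {
      stop("retention time ", format(t_x[out_of_range][1]),
           " outside the ladder span [", ladder$t[1], ", ",
           ladder$t[nrow(ladder)], "] min (set extrapolate = TRUE to allow)",
           call. = FALSE)
    }
    warning("extrapolating beyond the alkane ladder", call. = FALSE)
  }
  i <- findInterval(t_x, ladder$t, rightmost.closed = TRUE)
  i <- pmin(pmax(i, 1L), nrow(ladder) - 1L)
  n0 <- ladder$n[i]; t0 <- ladder$t[i]; t1 <- ladder$t[i + 1L]
  dn <- ladder$n[i + 1L] - n0
  100 * n0 + 100 * dn * (t_x - t0) / (t1 - t0)
}

#' Identify a peak against a compound library
#'
#' Ranks library compounds as candidates for a peak, by retention-index
#' window and diagnostic-ion overlap. A candidate must satisfy
#' `|RI_peak - RI_lib| <= ri_tol` and have at least `min_ion_frac` of its
#' diagnostic ions present among the peak's observed ions (set membership
#' with unit m/z tolerance). Candidates are ordered by RI distance, then
#' decreasing ion overlap, then compound code (a deterministic tie-break).
#'
#' @param ri Retention index of the peak.
#' @param ions Observed m/z values of the peak (non-empty).
#' @param library A `compound_library`; entries without an RI are skipped.
#' @param ri_tol RI window half-width (index units). The default of 10 is
#'   conservative: the closest isomer pair in the packaged library is 41
#'   units apart.
#' @param min_ion_frac Minimum fraction of library diagnostic ions that must
#'   be present in the peak.
#' @return A data frame of candidates: `code`, `name`, `ri`, `ri_dist`,
#'   `ion_overlap`; zero rows when nothing matches.
#' @export
#' @examples
#' identify_compound(2277, c(236, 235, 221, 207), quinone_library())
identify_compound <- function(ri, ions, library, ri_tol = 10,
                              min_ion_frac = 0.5) {
  stopifnot(length(ri) == 1, is.numeric(ri))
  if (!inherits(library, "compound_library") || nrow(library) == 0) {
    stop("a non-empty compound library is required", call. = FALSE)
  }
  if (length(ions) == 0) stop("peak has no observed ions", call. = FALSE)
  stopifnot(ri_tol >= 0, min_ion_frac > 0, min_ion_frac <= 1)
  lib <- library[!is.na(library$ri), , drop = FALSE]
  if (nrow(lib) == 0) {
    return(data.frame(code = character(0), name = character(0),
                      ri = numeric(0), ri_dist = numeric(0),
                      ion_overlap = numeric(0)))
  }
  ri_dist <- abs(lib$ri - ri)
  overlap <- vapply(lib$diagnostic_ions, function(dv) {
    if (length(dv) == 0) return(1)
    mean(vapply(dv, function(ion) any(abs(ions - ion) <= 1), logical(1)))
  }, numeric(1))
  keep <- ri_dist <= ri_tol & overlap >= min_ion_frac
  out <- data.frame(code = lib$code[keep], name = lib$name[keep],
                    ri = lib$ri[keep], ri_dist = ri_dist[keep],
                    ion_overlap = overlap[keep], stringsAsFactors = FALSE)
  out <- out[order(out$ri_dist, -out$ion_overlap, out$code), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Read a peak list
#'
#' @param path CSV with columns `t` (retention time, minutes) and `ions`
#'   (semicolon-separated observed m/z values).
#' @return A data frame with `t` numeric and `ions` a list column of
#'   numeric vectors.
#' @export
read_peaks <- function(path) {
  pk <- read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("t", "ions") %in% names(pk))) {
    stop("peak list needs columns `t` and `ions`", call. = FALSE)
  }
  pk$ions <- lapply(strsplit(as.character(pk$ions), ";", fixed = TRUE),
                    function(v) as.numeric(v[nzchar(v)]))
  pk
}

#' Annotate a peak list against a library
#'
#' Computes the Kovats RI of every peak and identifies it against the
#' library, returning one row per (peak, candidate).
#'
#' @param peaks Data frame as returned by [read_peaks()] (columns `t`,
#'   `ions`).
#' @param ladder An [alkane_ladder()].
#' @param library A `compound_library`.
#' @inheritParams identify_compound
#' @param extrapolate Passed to [kovats_ri()].
#' @return A data frame: `peak`, `t`, `ri`, `rank`, `code`, `name`,
#'   `ri_dist`, `ion_overlap`. Peaks with no candidate get one row with NA
#'   candidate fields.
#' @export
annotate_peaks <- function(peaks, ladder, library, ri_tol = 10,
                           min_ion_frac = 0.5, extrapolate = FALSE) {
  ri <- kovats_ri(peaks$t, ladder, extrapolate = extrapolate)
  rows <- lapply(seq_len(nrow(peaks)), function(i) {
    cand <- identify_compound(ri[i], peaks$ions[[i]], library,
                              ri_tol = ri_tol, min_ion_frac = min_ion_frac)
    if (nrow(cand) == 0) {
      data.frame(peak = i, t = peaks$t[i], ri = ri[i], rank = NA_integer_,
                 code = NA_character_, name = NA_character_,
                 ri_dist = NA_real_, ion_overlap = NA_real_,
                 stringsAsFactors = FALSE)
    } else {
      data.frame(peak = i, t = peaks$t[i], ri = ri[i],
                 rank = seq_len(nrow(cand)), code = cand$code,
                 name = cand$name, ri_dist = cand$ri_dist,
                 ion_overlap = cand$ion_overlap, stringsAsFactors = FALSE)
    }
  })
  do.call(rbind, rows)
}
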