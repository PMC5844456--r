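#' Define a character-coding policy
#'
#' A coding policy maps detection-table compound columns onto named binary
#' phylogenetic characters. For each output character it names the set of
#' contributing compound codes; the state-collapse rule is fixed: any
#' contributing cell in `positive_states` makes the character `present`;
#' otherwise any cell in `negative_states` makes it `absent`; otherwise
#' (only inconclusive/missing evidence) the character is `missing`.
#'
#' Partial detections count as positive evidence by default: a compound found
#' in part of the analysed material still proves the terminal can produce it.
#'
#' @param characters Named list; each element a character vector of compound
#'   codes contributing to that character.
#' @param positive_states,negative_states Detection states treated as
#'   positive resp. negative evidence.
#' @return An object of class `coding_policy`.
#' @seealso [default_coding_policy()]
#' @export
coding_policy <- function(characters,
                          positive_states = c("detected", "partial"),
                          negative_states = "not_detected") {
  stopifnot(is.list(characters), length(characters) >= 1)
  if (is.null(names(characters)) || any(!nzchar(names(characters)))) {
    stop("every character must be named", call. = FALSE)
  }
  bad <- setdiff(c(positive_states, negative_states), detection_states())
  if (length(bad) > 0) stop("unknown detection state(s): ",
                            paste(bad, collapse = ", "), call. = FALSE)
  structure(list(characters = characters,
                 positive_states = positive_states,
                 negative_states = negative_states),
            class = "coding_policy")
}

#' Default quinone coding policy
#'
#' Emits two binary characters: `NQ_class` (naphthoquinones and relatives:
#' NQ, MNQ, MOQ, MMOQ, ND, CNQ) and `BQ_class` (benzoquinones: BQ, ABQ).
#' The naphthalenediol ND is grouped with the naphthoquinones, with which it
#' co-occurs biosynthetically. Anthraquinones (MAQ, DMAQ) are compiled in
#' detection tables but excluded from the default characters; set
#' `include_anthraquinones = TRUE` to add an `AQ_class` character.
#'
#' @param include_anthraquinones Add an `AQ_class` character (MAQ, DMAQ)?
#' @return A `coding_policy`.
#' @export
default_coding_policy <- function(include_anthraquinones = FALSE) {
  chars <- list(NQ_class = c("NQ", "MNQ", "MOQ", "MMOQ", "ND", "CNQ"),
                BQ_class = c("BQ", "ABQ"))
  if (include_anthraquinones) chars$AQ_class <- c("MAQ", "DMAQ")
  coding_policy(chars)
}

#' Binarize a detection matrix into phylogenetic characters
#'
#' Collapses the five-valued detection states of each taxon into
#' present/absent/missing per character, following a [coding_policy()].
#'
#' @param x A `detection_matrix`.
#' @param policy A `coding_policy` (default: [default_coding_policy()]).
#' @return A `character_matrix`: a character matrix (taxa x characters) with
#'   values in `present`, `absent`, `missing`, carrying the policy as an
#'   attribute.
#' @export
#' @examples
#' dm <- read_detection_table(chemo_example("detections_eupnoi.csv"))
#' cm <- binarize(dm)
#' cm["Megabunus_armatus", ]
binarize <- function(x, policy = default_coding_policy()) {
  stopifnot(inherits(x, "detection_matrix"), inherits(policy, "coding_policy"))
  m <- x$states
  missing_codes <- setdiff(unlist(policy$characters), colnames(m))
  if (length(missing_codes) > 0) {
    stop("coding policy references compound code(s) absent from the matrix: ",
         paste(missing_codes, collapse = ", "), call. = FALSE)
  }
  out <- matrix("missing", nrow = nrow(m), ncol = length(policy$characters),
                dimnames = list(rownames(m), names(policy$characters)))
  for (ch in names(policy$characters)) {
    sub <- m[, policy$characters[[ch]], drop = FALSE]
    has_pos <- apply(sub, 1, function(v) any(v %in% policy$positive_states))
    has_neg <- apply(sub, 1, function(v) any(v %in% policy$negative_states))
    out[, ch] <- ifelse(has_pos, "present",
                        ifelse(has_neg, "absent", "missing"))
  }
  structure(out, policy = policy, class = c("character_matrix", "matrix"))
}

#' @export
print.character_matrix <- function(x, ...) {
  cat("Binary character matrix:", nrow(x), "taxa x", ncol(x), "characters\n")
  for (ch in colnames(x)) {
    tab <- table(factor(x[, ch], levels = c("present", "absent", "missing")))
    cat(" ", ch, ": ", paste(names(tab), tab, sep = "=", collapse = ", "),
        "\n", sep = "")
  }
  invisible(x)
}

#' Write a character matrix as CSV
#'
#' @param x A `character_matrix`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_character_csv <- function(x, path) {
  stopifnot(inherits(x, "character_matrix"))
  df <- data.frame(taxon = rownames(x), unclass(x)[, , drop = FALSE],
                   check.names = FALSE, row.names = NULL)
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a character matrix as a NEXUS CHARACTERS block
#'
#' Encodes present as `1`, absent as `0` and missing as `?` and delegates the
#' NEXUS serialisation to \pkg{ape}.
#'
#' @param x A `character_matrix`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_character_nexus <- function(x, path) {
  stopifnot(inherits(x, "character_matrix"))
  sym <- c(present = "1", absent = "0", missing = "?")
  rows <- lapply(seq_len(nrow(x)), function(i) unname(sym[x[i, ]]))
  names(rows) <- rownames(x)
  ape::write.nexus.data(rows, file = path, format = "standard",
                        interleaved = FALSE)
  invisible(path)
}
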