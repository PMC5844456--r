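#' Read and validate a rooted tree with polytomies
#'
#' Thin wrapper around [ape::read.tree()] adding the validation this package
#' needs: exactly one tree, a root, unique leaf labels, and no unary internal
#' nodes (singletons are collapsed). Branch lengths are kept if present but
#' ignored by the parsimony machinery. Polytomies are preserved and treated
#' as hard (simultaneous divergence) downstream.
#'
#' @param path Path to a Newick file, or a literal Newick string containing
#'   `(` and `;`.
#' @return An [ape::phylo] object.
#' @export
#' @examples
#' tr <- read_phylo("((A,B),(C,D,E));")
read_phylo <- function(path) {
  is_text <- grepl("\\(", path) && grepl(";", path)
  tr <- tryCatch(
    if (is_text) ape::read.tree(text = path) else {
      if (!file.exists(path)) stop("tree file not found: ", path,
                                   call. = FALSE)
      ape::read.tree(path)
    },
    error = function(e) stop("Newick parse error: ", conditionMessage(e),
                             call. = FALSE))
  if (is.null(tr)) stop("Newick parse error: malformed tree", call. = FALSE)
  if (inherits(tr, "multiPhylo")) {
    if (length(tr) != 1) stop("expected exactly one tree", call. = FALSE)
    tr <- tr[[1]]
  }
  dup <- unique(tr$tip.label[duplicated(tr$tip.label)])
  if (length(dup) > 0) {
    stop("duplicate leaf label(s): ", paste(dup, collapse = ", "),
         call. = FALSE)
  }
  # the outermost Newick node is taken as the root; a basal polytomy is a
  # hard multifurcation at the root, not an unrooted tree
  ape::collapse.singles(tr)
}

#' Write a tree to Newick
#'
#' @param tree An [ape::phylo] object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_phylo <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' Packaged composite Opiliones tree
#'
#' The rooted composite harvestman phylogeny used by the packaged case study:
#' suborder backbone (Cyphophthalmi,(Laniatores,(Eupnoi,Dyspnoi))), with the
#' published group-level arrangements encoded as labelled clades and hard
#' polytomies (see the packaged `tree_manifest.yaml` for the conventions and
#' the one placement decided here, Protolophidae inside the Phalangioidea
#' polytomy). Terminals match the packaged detection tables; sampling gaps
#' (Caddoidea, Neopilionidae, Monoscutidae, Acropsopilionidae,
#' Nipponopsalididae) are single placeholder leaves.
#'
#' @return An [ape::phylo] object with 90 leaves and labelled internal nodes.
#' @export
opiliones_tree <- function() {
  read_phylo(chemo_example("composite_opiliones.nwk"))
}

#' Packaged Opiliones detection data
#'
#' Reads and combines the packaged per-suborder detection tables (Eupnoi;
#' Dyspnoi; Laniatores + Cyphophthalmi) with the lineage sidecar attached.
#'
#' @param tables Which packaged tables to combine.
#' @return A `detection_matrix`.
#' @export
opiliones_detections <- function(tables = c("eupnoi", "dyspnoi",
                                            "laniatores_cyphophthalmi")) {
  files <- paste0("detections_", tables, ".csv")
  lin <- chemo_example("lineages.csv")
  mats <- lapply(files, function(f) read_detection_table(chemo_example(f),
                                                         lineage = lin))
  if (length(mats) == 1) mats[[1]] else bind_detection_matrices(mats)
}

#' Bind a character matrix to a tree
#'
#' Aligns a `character_matrix` to the leaves of a tree, producing the bound
#' analysis object consumed by [sankoff()]. Tree leaves without data are
#' handled per `on_unmatched`; matrix taxa absent from the tree are always
#' reported (in `$dropped_taxa`), and are an error under `"error"`.
#'
#' @param tree An [ape::phylo] object.
#' @param chars A `character_matrix` (see [binarize()]).
#' @param on_unmatched One of `"code_missing"` (default: leaves without data
#'   are coded missing), `"prune_tree"` (such leaves are dropped), or
#'   `"error"`.
#' @return An object of class `chemo_phylo`: list with `tree`, `states`
#'   (leaves x characters, values present/absent/missing, in tree tip
#'   order), `filled_tips`, `dropped_taxa`.
#' @export
bind_characters <- function(tree, chars,
                            on_unmatched = c("code_missing", "prune_tree",
                                             "error")) {
  on_unmatched <- match.arg(on_unmatched)
  stopifnot(inherits(tree, "phylo"), inherits(chars, "character_matrix"))
  tips <- tree$tip.label
  common <- intersect(tips, rownames(chars))
  if (length(common) == 0) {
    stop("no overlap between tree leaves and matrix taxa", call. = FALSE)
  }
  dropped <- setdiff(rownames(chars), tips)
  unscored <- setdiff(tips, rownames(chars))
  if (on_unmatched == "error" && (length(dropped) > 0 || length(unscored) > 0)) {
    stop("unmatched taxa: ",
         paste(c(dropped, unscored), collapse = ", "), call. = FALSE)
  }
  if (on_unmatched == "prune_tree" && length(unscored) > 0) {
    tree <- ape::drop.tip(tree, unscored, collapse.singles = TRUE)
    tips <- tree$tip.label
    unscored <- character(0)
  }
  states <- matrix("missing", nrow = length(tips), ncol = ncol(chars),
                   dimnames = list(tips, colnames(chars)))
  found <- intersect(tips, rownames(chars))
  states[found, ] <- unclass(chars)[found, , drop = FALSE]
  structure(list(tree = tree, states = states,
                 filled_tips = unscored, dropped_taxa = dropped),
            class = "chemo_phylo")
}

#' @export
print.chemo_phylo <- function(x, ...) {
  cat("Characters bound to tree:", length(x$tree$tip.label), "leaves,",
      ncol(x$states), "character(s):", paste(colnames(x$states),
                                             collapse = ", "), "\n")
  if (length(x$filled_tips) > 0) {
    cat("leaves coded missing (no data):", length(x$filled_tips), "\n")
  }
  if (length(x$dropped_taxa) > 0) {
    cat("matrix taxa not on tree (dropped):",
        paste(x$dropped_taxa, collapse = ", "), "\n")
  }
  invisible(x)
}

# Resolve a clade name to the tree edge above it.
# Accepts internal node labels and leaf labels; "root_stem" denotes the
# virtual stem above the root and is returned as 0L.
clade_edge <- function(tree, name) {
  if (name == "root_stem") return(0L)
  ntip <- length(tree$tip.label)
  node <- NA_integer_
  if (name %in% tree$tip.label) {
    node <- match(name, tree$tip.label)
  } else if (!is.null(tree$node.label) && name %in% tree$node.label) {
    node <- ntip + match(name, tree$node.label)
  }
  if (is.na(node)) {
    stop("clade not found on tree: ", sQuote(name), call. = FALSE)
  }
  e <- which(tree$edge[, 2] == node)
  # the edge above the root is the virtual stem
  if (length(e) == 0) 0L else e
}
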