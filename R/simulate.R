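#' Random rooted tree with polytomies
#'
#' Generates a random rooted topology and collapses each internal edge with
#' probability `polytomy_prob`, so the hard-polytomy code paths of the
#' reconstruction machinery are exercised. All edge lengths are set to 1.
#'
#' @param n_leaves Number of leaves (>= 2).
#' @param polytomy_prob Probability that an internal edge is collapsed.
#' @return An [ape::phylo] object.
#' @export
sim_polytomy_tree <- function(n_leaves, polytomy_prob = 0.2) {
  stopifnot(n_leaves >= 2, polytomy_prob >= 0, polytomy_prob < 1)
  tr <- ape::rtree(n_leaves, rooted = TRUE)
  ntip <- length(tr$tip.label)
  internal <- tr$edge[, 2] > ntip
  len <- rep(1, nrow(tr$edge))
  len[internal & runif(nrow(tr$edge)) < polytomy_prob] <- 0
  tr$edge.length <- len
  tr <- ape::di2multi(tr, tol = 1e-8)
  tr$edge.length <- rep(1, nrow(tr$edge))
  tr
}

#' Simulate a binary-trait history on a tree
#'
#' Runs a two-state continuous-time Markov chain (gain rate `q01`, loss rate
#' `q10`, events per unit branch length) from the root towards the tips,
#' starting in state `absent`. Exact event times are drawn per edge, so the
#' full history -- node states and the typed event list -- is returned, not
#' just the tip pattern.
#'
#' @param tree An [ape::phylo]; edge lengths are used if present, otherwise
#'   every edge has length `edge_length`.
#' @param q01 Gain rate (absent to present), >= 0.
#' @param q10 Loss rate (present to absent), >= 0.
#' @param edge_length Fallback edge length when the tree has none.
#' @param seed Optional integer seed, recorded in the output.
#' @return An object of class `simulated_history`: list with `tip_states`
#'   (named vector, `present`/`absent`), `node_states` (all nodes),
#'   `events` (data frame: edge, type, time), the rates and the seed.
#' @export
simulate_history <- function(tree, q01, q10, edge_length = 1, seed = NULL) {
  stopifnot(inherits(tree, "phylo"), q01 >= 0, q10 >= 0)
  if (!is.null(seed)) set.seed(seed)
  E <- tree$edge
  lens <- if (!is.null(tree$edge.length)) tree$edge.length else
    rep(edge_length, nrow(E))
  ord <- .edge_orders(tree)
  ntip <- length(tree$tip.label)
  state <- integer(ntip + tree$Nnode)  # 1 = absent, 2 = present
  state[ord$root] <- 1L
  rates <- c(q01, q10)
  ev_edge <- integer(0); ev_type <- character(0); ev_time <- numeric(0)
  for (ei in ord$pre) {
    s <- state[E[ei, 1]]
    tpos <- 0
    repeat {
      r <- rates[s]
      if (r <= 0) break
      tpos <- tpos + rexp(1, r)
      if (tpos > lens[ei]) break
      ev_edge <- c(ev_edge, ei)
      ev_type <- c(ev_type, if (s == 1L) "gain" else "loss")
      ev_time <- c(ev_time, tpos)
      s <- 3L - s
    }
    state[E[ei, 2]] <- s
  }
  state_names <- c("absent", "present")
  tips <- setNames(state_names[state[seq_len(ntip)]], tree$tip.label)
  structure(list(tree = tree,
                 tip_states = tips,
                 node_states = state_names[state],
                 events = data.frame(edge = ev_edge, type = ev_type,
                                     time = ev_time,
                                     stringsAsFactors = FALSE),
                 q01 = q01, q10 = q10, seed = seed),
            class = "simulated_history")
}

# Conditioned history with exactly one gain and no losses: one edge drawn
# with probability proportional to its length carries the gain.
.single_gain_history <- function(tree, edge_length = 1) {
  E <- tree$edge
  lens <- if (!is.null(tree$edge.length)) tree$edge.length else
    rep(edge_length, nrow(E))
  gain_edge <- sample.int(nrow(E), 1, prob = lens)
  ord <- .edge_orders(tree)
  ntip <- length(tree$tip.label)
  state <- integer(ntip + tree$Nnode)
  state[ord$root] <- 1L
  for (ei in ord$pre) {
    state[E[ei, 2]] <- if (ei == gain_edge) 2L else state[E[ei, 1]]
  }
  state_names <- c("absent", "present")
  structure(list(tree = tree,
                 tip_states = setNames(state_names[state[seq_len(ntip)]],
                                       tree$tip.label),
                 node_states = state_names[state],
                 events = data.frame(edge = gain_edge, type = "gain",
                                     time = lens[gain_edge] / 2,
                                     stringsAsFactors = FALSE),
                 q01 = 0, q10 = 0, seed = NULL),
            class = "simulated_history")
}

#' @export
print.simulated_history <- function(x, ...) {
  cat("Simulated binary-trait history:",
      sum(x$tip_states == "present"), "of", length(x$tip_states),
      "tips present;", nrow(x$events), "event(s)\n")
  invisible(x)
}

#' Build a noisy detection table from a simulated history
#'
#' Emulates the structure of a compound-screening table: each `present` tip
#' receives a `detected` cell for one randomly chosen compound of the
#' character's contributing set, every other cell is `not_detected`, and a
#' `noise` fraction of cells is then replaced by `inconclusive`. With
#' `noise = 0`, [binarize()] recovers the simulated tip states exactly.
#'
#' @param history A [simulate_history()] result.
#' @param character Which policy character the trait represents.
#' @param policy A [coding_policy()].
#' @param library A `compound_library` defining the table columns.
#' @param noise Probability that a cell is replaced by `inconclusive`;
#'   `0 <= noise < 1`.
#' @param seed Optional integer seed.
#' @return A `detection_matrix`.
#' @export
make_detection_fixture <- function(history, character = "NQ_class",
                                   policy = default_coding_policy(),
                                   library = quinone_library(),
                                   noise = 0, seed = NULL) {
  stopifnot(inherits(history, "simulated_history"), noise >= 0, noise < 1)
  if (!is.null(seed)) set.seed(seed)
  if (!(character %in% names(policy$characters))) {
    stop("character not in policy: ", character, call. = FALSE)
  }
  pool <- policy$characters[[character]]
  taxa <- names(history$tip_states)
  states <- matrix("not_detected", length(taxa), nrow(library),
                   dimnames = list(taxa, library$code))
  for (tx in taxa[history$tip_states == "present"]) {
    states[tx, sample(pool, 1)] <- "detected"
  }
  flip <- matrix(runif(length(states)) < noise, nrow = nrow(states))
  states[flip] <- "inconclusive"
  structure(list(states = states, library = library, lineage = NULL),
            class = "detection_matrix")
}

#' Build a GC fixture that round-trips through RI identification
#'
#' Constructs a linear-time alkane ladder and back-computes, for every
#' library compound with a retention index, the retention time at which
#' [kovats_ri()] recovers that index exactly; each generated peak carries
#' the compound's diagnostic ions (plus the molecular ion).
#'
#' @param library A `compound_library`.
#' @param n_range Carbon-number range of the ladder (default C9--C36, the
#'   usual standard mix).
#' @param t_start Retention time of the first alkane, minutes.
#' @param minutes_per_carbon Elution-time spacing between consecutive
#'   alkanes.
#' @return A list with `ladder` (an [alkane_ladder()]) and `peaks` (data
#'   frame: `code`, `t`, `ions` list column).
#' @export
make_gc_fixture <- function(library, n_range = c(9, 36), t_start = 5,
                            minutes_per_carbon = 1) {
  stopifnot(inherits(library, "compound_library"))
  n <- seq(n_range[1], n_range[2])
  lad <- alkane_ladder(n, t_start + (n - n[1]) * minutes_per_carbon)
  lib <- library[!is.na(library$ri), , drop = FALSE]
  if (nrow(lib) > 0 &&
      (any(lib$ri < 100 * n[1]) || any(lib$ri > 100 * n[length(n)]))) {
    stop("library RI outside the ladder span", call. = FALSE)
  }
  t_x <- vapply(lib$ri, function(ri) {
    n0 <- min(max(floor(ri / 100), lad$n[1]), lad$n[nrow(lad)] - 1L)
    i <- match(n0, lad$n)
    lad$t[i] + (ri / 100 - n0) / (lad$n[i + 1L] - n0) *
      (lad$t[i + 1L] - lad$t[i])
  }, numeric(1))
  ions <- lapply(seq_len(nrow(lib)), function(i)
    c(lib$molecular_ion[i][!is.na(lib$molecular_ion[i])],
      lib$diagnostic_ions[[i]]))
  peaks <- data.frame(code = lib$code, t = t_x, stringsAsFactors = FALSE)
  peaks$ions <- ions
  list(ladder = lad, peaks = peaks)
}

#' Write a GC fixture to CSV files
#'
#' @param fixture A [make_gc_fixture()] result.
#' @param ladder_path,peaks_path Output paths.
#' @return Invisibly, the two paths.
#' @export
write_gc_fixture <- function(fixture, ladder_path, peaks_path) {
  write.csv(fixture$ladder, ladder_path, row.names = FALSE, quote = FALSE)
  pk <- data.frame(t = fixture$peaks$t,
                   ions = vapply(fixture$peaks$ions, paste,
                                 character(1), collapse = ";"),
                   stringsAsFactors = FALSE)
  write.csv(pk, peaks_path, row.names = FALSE, quote = FALSE)
  invisible(c(ladder_path, peaks_path))
}

#' Ancestry-recovery experiment
#'
#' Validates the asymmetric-cost reconstruction against ground truth: for
#' each replicate a binary-trait history is simulated on the tree, the tip
#' pattern is reconstructed with the given step matrix (stem fixed to
#' `absent`), and the exact minimum origin count over all MPRs is compared
#' with the true number of gains. With `condition = "single_gain"` each
#' replicate carries exactly one gain and no losses (the low-rate regime),
#' where recovery must be exact.
#'
#' @param tree Tree to simulate on; if `NULL` a random polytomy tree with
#'   `n_leaves` leaves is drawn once.
#' @param q01,q10 Gain/loss rate vectors; the experiment runs over their
#'   full grid (ignored under `condition = "single_gain"`).
#' @param n_rep Replicates per grid cell.
#' @param condition `"none"` (free simulation) or `"single_gain"`.
#' @param cost Step matrix for the reconstruction.
#' @param n_leaves,polytomy_prob Passed to [sim_polytomy_tree()] when no
#'   tree is given.
#' @param seed Optional integer seed, recorded in the output.
#' @return A data frame with one row per (q01, q10) cell: `mean_bias`
#'   (reconstructed minus true origin count), `exact_recovery` (fraction of
#'   replicates with the true gain count recovered exactly),
#'   `root_accuracy` (fraction in which the root state is uniquely and
#'   correctly reconstructed), plus means of the true and reconstructed
#'   counts. The seed is attached as an attribute.
#' @export
recovery_experiment <- function(tree = NULL, q01 = 0.1, q10 = 0.05,
                                n_rep = 100, condition = c("none",
                                                           "single_gain"),
                                cost = step_matrix(), n_leaves = 16,
                                polytomy_prob = 0.2, seed = NULL) {
  condition <- match.arg(condition)
  stopifnot(n_rep >= 1)
  if (!is.null(seed)) set.seed(seed)
  if (is.null(tree)) tree <- sim_polytomy_tree(n_leaves, polytomy_prob)
  grid <- if (condition == "single_gain") data.frame(q01 = 0, q10 = 0) else
    expand.grid(q01 = q01, q10 = q10)
  state_names <- rownames(cost)
  gi <- match("absent", state_names); gj <- match("present", state_names)
  stem_idx <- gi
  base <- unclass(cost)
  edge_cost <- function(e) base
  out <- vector("list", nrow(grid))
  for (g in seq_len(nrow(grid))) {
    bias <- numeric(n_rep); exact <- logical(n_rep); rootok <- logical(n_rep)
    tg <- numeric(n_rep); ro <- numeric(n_rep)
    for (r in seq_len(n_rep)) {
      h <- if (condition == "single_gain") .single_gain_history(tree) else
        simulate_history(tree, grid$q01[g], grid$q10[g])
      true_gains <- sum(h$events$type == "gain")
      tipc <- .tip_cost(h$tip_states[tree$tip.label], state_names)
      dp <- .sankoff_dp(tree, tipc, edge_cost, base[stem_idx, ])
      orange <- .origin_range(tree, tipc, edge_cost, base, stem_idx,
                              dp$cost, gi, gj)
      amin <- which(dp$root_total == dp$cost)
      bias[r] <- orange[["min"]] - true_gains
      exact[r] <- orange[["min"]] == true_gains
      tg[r] <- true_gains; ro[r] <- orange[["min"]]
      true_root <- match(h$node_states[dp$root], state_names)
      rootok[r] <- length(amin) == 1 && amin == true_root
    }
    out[[g]] <- data.frame(q01 = grid$q01[g], q10 = grid$q10[g],
                           n_rep = n_rep, mean_bias = mean(bias),
                           exact_recovery = mean(exact),
                           root_accuracy = mean(rootok),
                           mean_true_gains = mean(tg),
                           mean_min_origins = mean(ro))
  }
  res <- do.call(rbind, out)
  attr(res, "seed") <- seed
  attr(res, "condition") <- condition
  res
}
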