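#' Build a state-transition cost (step) matrix
#'
#' The default models the chemosystematic asymmetry between acquiring and
#' losing a biosynthetic pathway: a gain (absent to present) costs twice a
#' loss (present to absent), reflecting that a new compound needs a
#' hierarchical multi-step synthesis machinery while a loss can result from
#' inactivating a single enzyme.
#'
#' @param gain Cost of an absent-to-present change.
#' @param loss Cost of a present-to-absent change.
#' @param states Ordered state names (the order fixes tie-breaking in MPR
#'   enumeration).
#' @param cost Optional full square cost matrix (overrides `gain`/`loss`);
#'   `dimnames` taken from `states`, diagonal must be zero, entries
#'   non-negative.
#' @return A `step_matrix` (a numeric matrix with class attribute).
#' @export
#' @examples
#' step_matrix()          # the default 2:1 regime
#' step_matrix(1, 1)      # symmetric unit costs (Fitch-equivalent)
step_matrix <- function(gain = 2, loss = 1, states = c("absent", "present"),
                        cost = NULL) {
  if (is.null(cost)) {
    stopifnot(length(states) == 2)
    cost <- matrix(c(0, loss, gain, 0), 2, 2,
                   dimnames = list(from = states, to = states))
  } else {
    stopifnot(is.matrix(cost), nrow(cost) == ncol(cost),
              nrow(cost) == length(states))
    dimnames(cost) <- list(from = states, to = states)
  }
  if (any(diag(cost) != 0)) stop("cost(i -> i) must be 0", call. = FALSE)
  if (any(cost < 0)) stop("costs must be non-negative", call. = FALSE)
  structure(cost, class = c("step_matrix", "matrix"))
}

#' Gain:loss cost ratio of a binary step matrix
#'
#' @param sm A `step_matrix` over states `absent`, `present`.
#' @return `cost(absent -> present) / cost(present -> absent)`.
#' @export
gain_loss_ratio <- function(sm) {
  stopifnot(inherits(sm, "step_matrix"),
            all(c("absent", "present") %in% rownames(sm)))
  sm["absent", "present"] / sm["present", "absent"]
}

# ---- internal tree traversal helpers -------------------------------------

# Edge indices of `tree$edge` in preorder (parents before children) and
# postorder (children before parents), by iterative DFS from the root.
.edge_orders <- function(tree) {
  E <- tree$edge
  root <- setdiff(E[, 1], E[, 2])[1]
  kids <- split(seq_len(nrow(E)), factor(E[, 1], levels = sort(unique(E[, 1]))))
  pre <- integer(nrow(E)); post <- integer(nrow(E))
  np <- 0L; npo <- 0L
  stack <- list(list(node = root, i = 1L))
  while (length(stack) > 0) {
    top <- stack[[length(stack)]]
    ch <- kids[[as.character(top$node)]]
    if (is.null(ch) || top$i > length(ch)) {
      if (length(stack) > 1) {
        # record the edge into this node on exit
        below <- stack[[length(stack) - 1]]
        ei <- kids[[as.character(below$node)]][below$i - 1L]
        npo <- npo + 1L; post[npo] <- ei
      }
      stack[[length(stack)]] <- NULL
    } else {
      ei <- ch[top$i]
      stack[[length(stack)]]$i <- top$i + 1L
      np <- np + 1L; pre[np] <- ei
      stack[[length(stack) + 1]] <- list(node = E[ei, 2], i = 1L)
    }
  }
  list(pre = pre, post = post, root = root)
}

# Leaf cost rows: 0 at the observed state and Inf elsewhere; a missing leaf
# gets 0 at every state (the standard Sankoff treatment: it constrains
# nothing and never changes the optimum).
.tip_cost <- function(tip_states, state_names) {
  k <- length(state_names)
  out <- matrix(Inf, length(tip_states), k)
  for (i in seq_along(tip_states)) {
    s <- tip_states[i]
    if (s == "missing") {
      out[i, ] <- 0
    } else {
      j <- match(s, state_names)
      if (is.na(j)) stop("leaf state ", sQuote(s),
                         " not among step-matrix states", call. = FALSE)
      out[i, j] <- 0
    }
  }
  out
}

# The Sankoff dynamic programme. edge_cost is a function(edge_index) -> k x k
# matrix; stem_cost is a length-k vector added at the root (zeros = free
# root). Returns the per-node cost table and the minimum total cost.
.sankoff_dp <- function(tree, tipc, edge_cost, stem_cost) {
  E <- tree$edge
  ntip <- length(tree$tip.label)
  k <- ncol(tipc)
  ord <- .edge_orders(tree)
  S <- matrix(0, ntip + tree$Nnode, k)
  S[seq_len(ntip), ] <- tipc
  for (ei in ord$post) {
    p <- E[ei, 1]; ch <- E[ei, 2]
    cm <- edge_cost(ei)
    tmp <- cm + matrix(S[ch, ], k, k, byrow = TRUE)
    S[p, ] <- S[p, ] + apply(tmp, 1, min)
  }
  total <- stem_cost + S[ord$root, ]
  list(S = S, cost = min(total), root = ord$root, root_total = total,
       ord = ord)
}

# Backtrack every minimum-cost node-state assignment, up to `cap`.
# Deterministic order: root states in step-matrix state order, then depth-
# first along the preorder edge sequence, states in matrix order at each
# node. Returns integer state-index vectors over all nodes.
.enumerate_mprs <- function(tree, dp, edge_cost, cap) {
  E <- tree$edge
  res <- vector("list", 0)
  truncated <- FALSE
  pre <- dp$ord$pre
  rec <- function(i, av) {
    if (truncated) return()
    if (i > length(pre)) {
      if (length(res) >= cap) { truncated <<- TRUE; return() }
      res[[length(res) + 1L]] <<- av
      return()
    }
    ei <- pre[i]; p <- E[ei, 1]; ch <- E[ei, 2]
    v <- edge_cost(ei)[av[p], ] + dp$S[ch, ]
    for (t in which(v == min(v))) {
      av[ch] <- t
      rec(i + 1L, av)
    }
  }
  av0 <- integer(nrow(dp$S))
  for (s in which(dp$root_total == dp$cost)) {
    av0[dp$root] <- s
    rec(1L, av0)
    if (truncated) break
  }
  list(mprs = res, truncated = truncated)
}

# Exact min/max number of gains over all MPRs without enumerating them:
# rescale integer costs by K and add/subtract a one-unit gain marker, so the
# DP optimises (total cost, gains) lexicographically. Requires integer
# costs; K exceeds the largest possible gain count.
.origin_range <- function(tree, tipc, edge_cost, stem_cost_mat, stem_idx,
                          base_cost, gi, gj) {
  K <- nrow(tree$edge) + 2
  shift <- function(m, d) { m2 <- m * K; m2[gi, gj] <- m2[gi, gj] + d; m2 }
  stem_vec <- function(m) if (is.null(stem_idx)) rep(0, ncol(m)) else m[stem_idx, ]
  lo <- .sankoff_dp(tree, tipc * K, function(e) shift(edge_cost(e), 1),
                    stem_vec(shift(stem_cost_mat, 1)))
  hi <- .sankoff_dp(tree, tipc * K, function(e) shift(edge_cost(e), -1),
                    stem_vec(shift(stem_cost_mat, -1)))
  c(min = lo$cost - K * base_cost, max = K * base_cost - hi$cost)
}

# Normalise the (x, character) pair: either a chemo_phylo plus a character
# name, or a bare phylo plus a named vector of tip states.
.as_bound <- function(x, character) {
  if (inherits(x, "chemo_phylo")) {
    if (length(character) != 1 || !(character %in% colnames(x$states))) {
      stop("character not found in bound matrix: ", sQuote(character[1]),
           call. = FALSE)
    }
    list(tree = x$tree, tip_states = x$states[x$tree$tip.label, character])
  } else if (inherits(x, "phylo")) {
    if (is.null(names(character)) ||
        !all(x$tip.label %in% names(character))) {
      stop("with a bare tree, `character` must be a named vector covering ",
           "every leaf", call. = FALSE)
    }
    list(tree = x, tip_states = character[x$tip.label])
  } else {
    stop("`x` must be a chemo_phylo (see bind_characters) or a phylo",
         call. = FALSE)
  }
}

#' Minimum-cost ancestral state reconstruction (Sankoff parsimony)
#'
#' Fits a minimum-cost ancestral state reconstruction of a discrete character
#' on a rooted tree (polytomies allowed and treated as hard) under an
#' arbitrary step matrix, by the Sankoff dynamic programme. All
#' most-parsimonious reconstructions (MPRs) are enumerated up to `mpr_cap`,
#' gain and loss events are counted per MPR, and the exact range of origin
#' (gain) counts over all MPRs is computed.
#'
#' By default a virtual stem above the root is fixed to `absent`, so a
#' character already present at the root is charged as a gain on the stem:
#' appropriate for traits modelled as innovations. Set `stem_state = NULL`
#' for a free root.
#'
#' @param x A `chemo_phylo` from [bind_characters()], or a bare
#'   [ape::phylo] (then `character` is a named vector of tip states, values
#'   among the step-matrix states or `"missing"`).
#' @param character Character name (for a `chemo_phylo`) or named tip-state
#'   vector (for a `phylo`).
#' @param cost A [step_matrix()].
#' @param stem_state Fixed pre-root state (default `"absent"`), or `NULL`
#'   for a free root.
#' @param mpr_cap Maximum number of MPRs to enumerate; if exceeded the fit is
#'   flagged `truncated` (never silently).
#' @return An object of class `sankoff_fit` with components `cost` (the
#'   minimum total cost, including the stem edge), `cost_table` (per-node,
#'   per-state minimal subtree costs), `mprs` (list of node-state
#'   assignments), `events` (per-MPR gain/loss event tables),
#'   `origin_range`, `truncated`, and the inputs.
#' @seealso [count_events()], [sankoff_brute_force()], [compare_scenarios()]
#' @export
#' @examples
#' tr <- read_phylo("(A,B);")
#' fit <- sankoff(tr, c(A = "present", B = "absent"))
#' fit$cost   # a single gain on A's edge
sankoff <- function(x, character, cost = step_matrix(),
                    stem_state = "absent", mpr_cap = 10000L) {
  b <- .as_bound(x, character)
  .sankoff_fit(b$tree, b$tip_states, cost, stem_state, mpr_cap,
               character = if (inherits(x, "chemo_phylo")) character else
                 deparse(substitute(character)))
}

# Shared fitting routine; edge_cost_list (per-edge k x k matrices) and
# stem_cost_mat allow the scenario module to constrain individual edges.
.sankoff_fit <- function(tree, tip_states, cost, stem_state, mpr_cap,
                         character = "character", edge_cost_list = NULL,
                         stem_cost_mat = NULL) {
  stopifnot(inherits(cost, "step_matrix"))
  state_names <- rownames(cost)
  k <- length(state_names)
  if (is.null(stem_cost_mat)) stem_cost_mat <- unclass(cost)
  stem_idx <- NULL
  if (!is.null(stem_state)) {
    stem_idx <- match(stem_state, state_names)
    if (is.na(stem_idx)) stop("unknown stem state: ", stem_state,
                              call. = FALSE)
  }
  stem_cost <- if (is.null(stem_idx)) rep(0, k) else stem_cost_mat[stem_idx, ]
  tipc <- .tip_cost(tip_states, state_names)
  edge_cost <- if (is.null(edge_cost_list)) {
    base <- unclass(cost)
    function(e) base
  } else {
    function(e) edge_cost_list[[e]]
  }
  dp <- .sankoff_dp(tree, tipc, edge_cost, stem_cost)
  feasible <- is.finite(dp$cost)
  mprs <- list(); truncated <- FALSE
  events <- list()
  orange <- c(min = NA_real_, max = NA_real_)
  if (feasible) {
    enum <- .enumerate_mprs(tree, dp, edge_cost, mpr_cap)
    mprs <- enum$mprs
    truncated <- enum$truncated
    events <- lapply(mprs, .events_one, tree = tree,
                     state_names = state_names, stem_idx = stem_idx)
    vals <- unlist(lapply(seq_len(nrow(tree$edge)), function(e) {
      m <- edge_cost(e)
      m[is.finite(m)]
    }))
    integral <- all(vals %% 1 == 0) &&
      all(stem_cost_mat[is.finite(stem_cost_mat)] %% 1 == 0)
    if (all(c("absent", "present") %in% state_names) && integral) {
      gi <- match("absent", state_names); gj <- match("present", state_names)
      orange <- .origin_range(tree, tipc, edge_cost, stem_cost_mat, stem_idx,
                              dp$cost, gi, gj)
    } else if (length(mprs) > 0 && !truncated) {
      g <- vapply(events, function(ev) sum(ev$type == "gain"), numeric(1))
      orange <- c(min = min(g), max = max(g))
    }
  }
  structure(list(tree = tree, tip_states = tip_states, character = character,
                 step_matrix = cost, stem_state = stem_state,
                 cost = dp$cost, cost_table = dp$S, feasible = feasible,
                 mprs = mprs, events = events, truncated = truncated,
                 origin_range = orange, state_names = state_names),
            class = "sankoff_fit")
}

# Typed change events of one node-state assignment, including the virtual
# stem (edge 0) when a fixed stem state differs from the root state.
.events_one <- function(av, tree, state_names, stem_idx) {
  E <- tree$edge
  changed <- which(av[E[, 1]] != av[E[, 2]])
  from <- state_names[av[E[changed, 1]]]
  to <- state_names[av[E[changed, 2]]]
  edge <- changed
  root <- setdiff(E[, 1], E[, 2])[1]
  if (!is.null(stem_idx) && av[root] != stem_idx) {
    edge <- c(0L, edge)
    from <- c(state_names[stem_idx], from)
    to <- c(state_names[av[root]], to)
  }
  type <- rep("other", length(edge))
  type[from == "absent" & to == "present"] <- "gain"
  type[from == "present" & to == "absent"] <- "loss"
  data.frame(edge = edge, from = from, to = to, type = type,
             stringsAsFactors = FALSE)
}

#' Count gains, losses and origins per most-parsimonious reconstruction
#'
#' @param fit A `sankoff_fit`.
#' @return A data frame with one row per MPR: `gains` (absent-to-present
#'   edges, virtual stem included), `losses`, and `origins` (= gains). The
#'   exact min/max origin count over all MPRs -- also valid when enumeration
#'   was truncated -- is attached as attribute `origin_range`.
#' @export
count_events <- function(fit) {
  stopifnot(inherits(fit, "sankoff_fit"))
  out <- data.frame(
    mpr = seq_along(fit$events),
    gains = vapply(fit$events, function(ev) sum(ev$type == "gain"),
                   numeric(1)),
    losses = vapply(fit$events, function(ev) sum(ev$type == "loss"),
                    numeric(1)))
  out$origins <- out$gains
  attr(out, "origin_range") <- fit$origin_range
  out
}

#' Node states of one most-parsimonious reconstruction
#'
#' @param fit A `sankoff_fit`.
#' @param i MPR index.
#' @return Named character vector of states over tips and internal nodes
#'   (internal nodes named by their labels where present, otherwise
#'   `node<N>`).
#' @export
mpr_states <- function(fit, i = 1L) {
  stopifnot(inherits(fit, "sankoff_fit"), i >= 1, i <= length(fit$mprs))
  av <- fit$mprs[[i]]
  tree <- fit$tree
  ntip <- length(tree$tip.label)
  labs <- c(tree$tip.label,
            if (!is.null(tree$node.label) &&
                length(tree$node.label) == tree$Nnode) {
              ifelse(nzchar(tree$node.label), tree$node.label,
                     paste0("node", ntip + seq_len(tree$Nnode)))
            } else paste0("node", ntip + seq_len(tree$Nnode)))
  setNames(fit$state_names[av], labs)
}

#' Recompute the total cost of one enumerated reconstruction
#'
#' Sums the step costs over all edges (virtual stem included) of MPR `i`,
#' independently of the dynamic programme -- every enumerated MPR re-sums to
#' `fit$cost`.
#'
#' @param fit A `sankoff_fit`.
#' @param i MPR index.
#' @return The total cost, a number.
#' @export
mpr_cost <- function(fit, i = 1L) {
  stopifnot(inherits(fit, "sankoff_fit"), i >= 1, i <= length(fit$mprs))
  av <- fit$mprs[[i]]
  E <- fit$tree$edge
  cm <- unclass(fit$step_matrix)
  total <- sum(cm[cbind(av[E[, 1]], av[E[, 2]])])
  if (!is.null(fit$stem_state)) {
    root <- setdiff(E[, 1], E[, 2])[1]
    total <- total + cm[match(fit$stem_state, fit$state_names), av[root]]
  }
  total
}

#' Exhaustive parsimony oracle for small trees
#'
#' Enumerates every assignment of states to internal nodes (and to
#' missing-data leaves) and returns the exact minimum total cost. Intended
#' as an independent check of [sankoff()]; refuses trees with more than
#' `max_internal` internal nodes.
#'
#' @inheritParams sankoff
#' @param max_internal Refusal threshold on the number of internal nodes.
#' @return The minimum total cost, a number.
#' @export
sankoff_brute_force <- function(x, character, cost = step_matrix(),
                                stem_state = "absent", max_internal = 12L) {
  b <- .as_bound(x, character)
  tree <- b$tree; tip_states <- b$tip_states
  state_names <- rownames(cost)
  k <- length(state_names)
  ntip <- length(tree$tip.label)
  if (tree$Nnode > max_internal) {
    stop("brute force refused: ", tree$Nnode, " internal nodes (limit ",
         max_internal, ")", call. = FALSE)
  }
  free <- c(which(tip_states == "missing"), ntip + seq_len(tree$Nnode))
  if (k^length(free) > 2^21) {
    stop("brute force refused: state space too large", call. = FALSE)
  }
  fixed <- integer(ntip + tree$Nnode)
  obs <- which(tip_states != "missing")
  fixed[obs] <- match(tip_states[obs], state_names)
  grid <- as.matrix(expand.grid(rep(list(seq_len(k)), length(free))))
  E <- tree$edge
  root <- setdiff(E[, 1], E[, 2])[1]
  cm <- unclass(cost)
  stem_idx <- if (is.null(stem_state)) NULL else match(stem_state, state_names)
  best <- Inf
  for (r in seq_len(nrow(grid))) {
    av <- fixed
    av[free] <- grid[r, ]
    total <- sum(cm[cbind(av[E[, 1]], av[E[, 2]])])
    if (!is.null(stem_idx)) total <- total + cm[stem_idx, av[root]]
    if (total < best) best <- total
  }
  best
}

#' @export
print.sankoff_fit <- function(x, ...) {
  cat("Sankoff parsimony reconstruction of", sQuote(x$character), "\n")
  cat("  states:", paste(x$state_names, collapse = ", "),
      "| stem state:",
      if (is.null(x$stem_state)) "(free root)" else x$stem_state, "\n")
  if (!x$feasible) {
    cat("  INFEASIBLE under the given constraints\n")
    return(invisible(x))
  }
  cat("  minimum total cost:", x$cost, "\n")
  cat("  MPRs enumerated:", length(x$mprs),
      if (x$truncated) "(cap reached, truncated)" else "", "\n")
  if (!anyNA(x$origin_range)) {
    cat("  origins (gains) over all MPRs: min", x$origin_range[["min"]],
        "/ max", x$origin_range[["max"]], "\n")
  }
  invisible(x)
}

#' @export
summary.sankoff_fit <- function(object, ...) {
  ev <- count_events(object)
  structure(list(fit = object, events = ev), class = "summary.sankoff_fit")
}

#' @export
print.summary.sankoff_fit <- function(x, ...) {
  print(x$fit)
  if (nrow(x$events) > 0) {
    cat("per-MPR events (first 10):\n")
    print(head(x$events, 10))
  }
  invisible(x)
}

#' Plot a reconstruction on the tree
#'
#' Draws the tree with tips and internal nodes coloured by the states of one
#' most-parsimonious reconstruction.
#'
#' @param x A `sankoff_fit`.
#' @param mpr Which MPR to draw.
#' @param colors Named colours per state (and for `missing` tips).
#' @param ... Passed to [ape::plot.phylo()].
#' @return `x`, invisibly.
#' @export
plot.sankoff_fit <- function(x, mpr = 1L,
                             colors = c(absent = "grey75",
                                        present = "firebrick",
                                        missing = "white"), ...) {
  if (!x$feasible || length(x$mprs) == 0) {
    stop("nothing to plot: no feasible reconstruction", call. = FALSE)
  }
  av <- x$mprs[[mpr]]
  tree <- x$tree
  ntip <- length(tree$tip.label)
  st <- x$state_names[av]
  tip_col <- colors[ifelse(x$tip_states[tree$tip.label] == "missing",
                           "missing", x$tip_states[tree$tip.label])]
  ape::plot.phylo(tree, ...)
  ape::tiplabels(pch = 21, bg = tip_col, cex = 0.8)
  ape::nodelabels(pch = 21, bg = colors[st[(ntip + 1):length(st)]], cex = 0.8)
  invisible(x)
}

#' Tree annotated with reconstructed state sets
#'
#' Returns the fitted tree with each internal node labelled by the set of
#' states it takes across all enumerated MPRs (joined by `|`), ready for
#' [write_phylo()].
#'
#' @param fit A `sankoff_fit`.
#' @return An [ape::phylo] object.
#' @export
annotated_tree <- function(fit) {
  stopifnot(inherits(fit, "sankoff_fit"))
  tree <- fit$tree
  ntip <- length(tree$tip.label)
  sets <- vapply(ntip + seq_len(tree$Nnode), function(nd) {
    paste(sort(unique(vapply(fit$mprs, function(av)
      fit$state_names[av[nd]], character(1)))), collapse = "|")
  }, character(1))
  tree$node.label <- sets
  tree
}

#' Write a JSON reconstruction report
#'
#' @param fit A `sankoff_fit`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_asr_report <- function(fit, path) {
  stopifnot(inherits(fit, "sankoff_fit"))
  ev <- count_events(fit)
  report <- list(character = fit$character,
                 stem_state = fit$stem_state,
                 feasible = fit$feasible,
                 cost = fit$cost,
                 n_mprs = length(fit$mprs),
                 truncated = fit$truncated,
                 origin_min = fit$origin_range[["min"]],
                 origin_max = fit$origin_range[["max"]],
                 mprs = lapply(seq_len(nrow(ev)), function(i) {
                   list(gains = ev$gains[i], losses = ev$losses[i],
                        events = fit$events[[i]])
                 }))
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(path)
}
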