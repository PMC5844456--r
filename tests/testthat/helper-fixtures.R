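# Shared helpers: tiny trees, random parsimony instances, temp CSV writers.

tiny_detection_csv <- function(lines, file = tempfile(fileext = ".csv")) {
  writeLines(lines, file)
  file
}

# Random small parsimony instance: rooted tree with polytomies, random
# binary tip states (optionally with missing), random non-negative integer
# step matrix.
random_instance <- function(n_leaves = NULL, p_missing = 0.15,
                            integer_costs = TRUE) {
  if (is.null(n_leaves)) n_leaves <- sample(4:8, 1)
  tree <- sim_polytomy_tree(n_leaves, polytomy_prob = 0.3)
  states <- sample(c("absent", "present"), n_leaves, replace = TRUE)
  miss <- runif(n_leaves) < p_missing
  states[miss] <- "missing"
  names(states) <- tree$tip.label
  gain <- sample(0:4, 1); loss <- sample(0:4, 1)
  sm <- step_matrix(gain = gain, loss = loss)
  stem <- sample(list("absent", "present", NULL), 1)[[1]]
  list(tree = tree, states = states, sm = sm, stem = stem)
}

# Constrained brute force: exhaustive minimum over internal-node (and
# missing-tip) assignments with the absent->present cost set to Inf on all
# edges outside `allowed` (0 = virtual stem). Independent of the DP.
constrained_brute_force <- function(tree, states, sm, stem_state, allowed) {
  state_names <- rownames(sm)
  k <- length(state_names)
  ntip <- length(tree$tip.label)
  E <- tree$edge
  root <- setdiff(E[, 1], E[, 2])[1]
  gi <- match("absent", state_names); gj <- match("present", state_names)
  base <- unclass(sm)
  banned <- base; banned[gi, gj] <- Inf
  free <- c(which(states[tree$tip.label] == "missing"),
            ntip + seq_len(tree$Nnode))
  fixed <- integer(ntip + tree$Nnode)
  obs <- which(states[tree$tip.label] != "missing")
  fixed[obs] <- match(states[tree$tip.label][obs], state_names)
  grid <- as.matrix(expand.grid(rep(list(seq_len(k)), length(free))))
  stem_idx <- if (is.null(stem_state)) NULL else match(stem_state, state_names)
  stem_mat <- if (0L %in% allowed) base else banned
  best <- Inf
  for (r in seq_len(nrow(grid))) {
    av <- fixed
    av[free] <- grid[r, ]
    total <- 0
    for (e in seq_len(nrow(E))) {
      m <- if (e %in% allowed) base else banned
      total <- total + m[av[E[e, 1]], av[E[e, 2]]]
    }
    if (!is.null(stem_idx)) total <- total + stem_mat[stem_idx, av[root]]
    if (total < best) best <- total
  }
  best
}

opiliones_bound <- function() {
  bind_characters(opiliones_tree(), binarize(opiliones_detections()))
}
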