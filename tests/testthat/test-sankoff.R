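test_that("cherry reconstructions under the 2:1 regime behave as derived", {
  tr <- read_phylo("(A,B);")
  # one present, one absent: a single gain on the present leaf's edge beats
  # a present root (stem gain 2 + loss 1); frozen from the 2-assignment
  # enumeration of sankoff_brute_force
  fit <- sankoff(tr, c(A = "present", B = "absent"))
  expect_equal(fit$cost, 2)
  expect_equal(sankoff_brute_force(tr, c(A = "present", B = "absent")), 2)
  ev <- count_events(fit)
  expect_equal(nrow(ev), 1L)
  expect_equal(ev$gains, 1)
  expect_equal(ev$losses, 0)

  # both present: unique MPR gains once on the virtual stem
  fit2 <- sankoff(tr, c(A = "present", B = "present"))
  expect_equal(fit2$cost, 2)
  expect_length(fit2$mprs, 1L)
  expect_equal(fit2$events[[1]]$edge, 0L)
  expect_equal(fit2$events[[1]]$type, "gain")
  expect_equal(unname(mpr_states(fit2)[["node3"]]), "present")
})

test_that("an all-missing tree costs nothing and an all-absent tree has an eventless unique MPR", {
  tr <- read_phylo("((A,B),(C,D,E));")
  fit <- sankoff(tr, setNames(rep("missing", 5), tr$tip.label))
  expect_equal(fit$cost, 0)
  fit0 <- sankoff(tr, setNames(rep("absent", 5), tr$tip.label))
  expect_equal(fit0$cost, 0)
  expect_length(fit0$mprs, 1L)
  expect_equal(nrow(fit0$events[[1]]), 0L)
  expect_equal(count_events(fit0)$origins, 0)
})

test_that("star-tree cost equals the closed form min(2k, 2 + n - k)", {
  for (n in 4:7) {
    tips <- paste0("t", seq_len(n))
    tr <- read_phylo(paste0("(", paste(tips, collapse = ","), ");"))
    for (k in 0:n) {
      states <- setNames(c(rep("present", k), rep("absent", n - k)), tips)
      fit <- sankoff(tr, states)
      expected <- if (k == 0) 0 else min(2 * k, 2 + (n - k))
      expect_equal(fit$cost, expected, info = paste("n", n, "k", k))
      expect_equal(sankoff_brute_force(tr, states), expected)
    }
  }
})

test_that("a symmetric unit-cost cherry with a free root has two MPRs", {
  tr <- read_phylo("(A,B);")
  fit <- sankoff(tr, c(A = "present", B = "absent"),
                 cost = step_matrix(1, 1), stem_state = NULL)
  expect_equal(fit$cost, 1)
  expect_length(fit$mprs, 2L)
  expect_false(any(duplicated(fit$mprs)))
})

test_that("the dynamic programme agrees with the exhaustive oracle on random instances", {
  set.seed(101)
  for (i in 1:80) {
    inst <- random_instance()
    fit <- sankoff(inst$tree, inst$states, cost = inst$sm,
                   stem_state = inst$stem, mpr_cap = 500L)
    oracle <- sankoff_brute_force(inst$tree, inst$states, cost = inst$sm,
                                  stem_state = inst$stem)
    expect_identical(fit$cost, oracle, info = paste("instance", i))
  }
})

test_that("symmetric unit costs with a free root reproduce Fitch parsimony", {
  skip_if_not_installed("phangorn")
  set.seed(7)
  for (i in 1:25) {
    n <- sample(4:12, 1)
    tr <- ape::rtree(n)
    states <- setNames(sample(c("absent", "present"), n, replace = TRUE),
                       tr$tip.label)
    fit <- sankoff(tr, states, cost = step_matrix(1, 1), stem_state = NULL)
    dat <- phangorn::phyDat(matrix(states[tr$tip.label], ncol = 1,
                                   dimnames = list(tr$tip.label, NULL)),
                            type = "USER", levels = c("absent", "present"))
    expect_equal(fit$cost, phangorn::fitch(tr, dat), info = paste("rep", i))
  }
})

test_that("minimum cost is monotone in every step-matrix entry", {
  set.seed(33)
  for (i in 1:20) {
    inst <- random_instance(p_missing = 0)
    base_fit <- sankoff(inst$tree, inst$states, cost = inst$sm,
                        stem_state = "absent", mpr_cap = 1L)
    for (entry in list(c(1, 2), c(2, 1))) {
      m <- unclass(inst$sm)
      m[entry[1], entry[2]] <- m[entry[1], entry[2]] + sample(1:3, 1)
      bumped <- step_matrix(cost = m, states = rownames(inst$sm))
      fit2 <- sankoff(inst$tree, inst$states, cost = bumped,
                      stem_state = "absent", mpr_cap = 1L)
      expect_gte(fit2$cost, base_fit$cost)
    }
  }
})

test_that("adding a missing-data leaf anywhere never changes the cost", {
  set.seed(55)
  for (i in 1:15) {
    inst <- random_instance(p_missing = 0)
    fit <- sankoff(inst$tree, inst$states, cost = inst$sm,
                   stem_state = "absent", mpr_cap = 1L)
    nwk <- ape::write.tree(inst$tree)
    opens <- gregexpr("(", nwk, fixed = TRUE)[[1]]
    at <- opens[sample.int(length(opens), 1)]
    nwk2 <- paste0(substr(nwk, 1, at), "EXTRA_MISSING:1,",
                   substr(nwk, at + 1, nchar(nwk)))
    tr2 <- read_phylo(nwk2)
    states2 <- c(inst$states, EXTRA_MISSING = "missing")
    fit2 <- sankoff(tr2, states2, cost = inst$sm, stem_state = "absent",
                    mpr_cap = 1L)
    expect_identical(fit2$cost, fit$cost, info = paste("rep", i))
  }
})

test_that("every enumerated MPR re-sums to the minimum and obeys 2g + l", {
  set.seed(77)
  for (i in 1:25) {
    inst <- random_instance()
    fit <- sankoff(inst$tree, inst$states, cost = step_matrix(2, 1),
                   stem_state = "absent", mpr_cap = 300L)
    expect_false(any(duplicated(fit$mprs)))
    ev <- count_events(fit)
    for (m in seq_along(fit$mprs)) {
      expect_equal(mpr_cost(fit, m), fit$cost)
      expect_equal(2 * ev$gains[m] + ev$losses[m], fit$cost)
    }
    if (!fit$truncated && length(fit$mprs) > 0) {
      expect_equal(unname(fit$origin_range[["min"]]), min(ev$gains))
      expect_equal(unname(fit$origin_range[["max"]]), max(ev$gains))
    }
  }
})

test_that("the oracle refuses oversized trees and unknown characters error", {
  tr <- ape::rtree(40)
  states <- setNames(rep("absent", 40), tr$tip.label)
  expect_error(sankoff_brute_force(tr, states), "refused")
  b <- opiliones_bound()
  expect_error(sankoff(b, "PQ_class"), "not found")
})

test_that("reconstruction reports serialise to annotated Newick and JSON", {
  b <- opiliones_bound()
  fit <- sankoff(b, "BQ_class")
  atr <- annotated_tree(fit)
  expect_true(all(atr$node.label %in%
                    c("absent", "present", "absent|present")))
  f <- tempfile(fileext = ".json")
  write_asr_report(fit, f)
  rep <- jsonlite::read_json(f)
  expect_equal(rep$cost, fit$cost)
  expect_equal(rep$n_mprs, length(fit$mprs))
})
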