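#' Define an origin scenario
#'
#' A scenario encodes a hypothesis about where a character may have been
#' gained: gains (absent to present) are permitted only on the edges above
#' the named clades or leaves, and forbidden everywhere else (losses stay
#' unconstrained). Origins are organised in named *groups*: a group listing
#' several edges represents one hypothesised origin whose bearers are not
#' sister on the working tree, and counts once.
#'
#' @param label Scenario label (unique within a comparison).
#' @param character Name of the character the scenario constrains.
#' @param origins Named list of character vectors of clade names (internal
#'   node labels or leaf labels); the special name `"root_stem"` permits a
#'   gain on the virtual stem above the root.
#' @param required If `TRUE`, reconstructions in which some origin group
#'   carries no gain are rejected.
#' @return An object of class `scenario`.
#' @export
scenario <- function(label, character, origins, required = TRUE) {
  stopifnot(is.character(label), length(label) == 1,
            is.character(character), length(character) == 1,
            is.list(origins), length(origins) >= 1)
  if (is.null(names(origins)) || any(!nzchar(names(origins)))) {
    stop("every origin group must be named", call. = FALSE)
  }
  structure(list(label = label, character = character,
                 origins = lapply(origins, as.character),
                 required = isTRUE(required)),
            class = "scenario")
}

#' Read scenarios from a YAML file
#'
#' @param path Path to a YAML list of scenarios, each with fields `label`,
#'   `character`, `origins` (named lists of clade names) and optional
#'   `required`.
#' @return A list of [scenario()] objects.
#' @export
read_scenarios <- function(path) {
  raw <- yaml::read_yaml(path)
  lapply(raw, function(s) {
    scenario(label = s$label, character = s$character, origins = s$origins,
             required = if (is.null(s$required)) TRUE else s$required)
  })
}

#' Packaged Opiliones origin scenarios
#'
#' The six competing hypotheses for quinone evolution in harvestman scent
#' glands: three for the naphthoquinone-class character (NQ-A: independent
#' origins in Cyphophthalmi, in the dyspnoan producers and in Phalangiidae;
#' NQ-B: Cyphophthalmi and Palpatores; NQ-C: a single origin on the
#' Opiliones stem) and three for the benzoquinone-class character (BQ-D:
#' Gonyleptoidea, Gyantinae, the Dicranopalpus group and Phalangiidae;
#' BQ-E: Palpatores and Gonyleptoidea; BQ-F: a single origin on the common
#' stem of Palpatores + Laniatores).
#'
#' @return A list of [scenario()] objects.
#' @export
opiliones_scenarios <- function() {
  read_scenarios(chemo_example("scenarios.yaml"))
}

#' @export
print.scenario <- function(x, ...) {
  cat("Scenario", x$label, "for character", sQuote(x$character),
      if (x$required) "(all origin groups required)" else "(optional)", "\n")
  for (g in names(x$origins)) {
    cat("  ", g, ": ", paste(x$origins[[g]], collapse = ", "), "\n", sep = "")
  }
  invisible(x)
}

#' Constrained minimum-cost reconstruction under a scenario
#'
#' Runs the Sankoff dynamic programme with edge-specific cost matrices: on
#' edges outside the scenario's allowed gain edges the absent-to-present
#' cost is infinite. If the scenario is `required`, minimum-cost
#' reconstructions in which some origin group carries no gain are rejected
#' (the check applies among minimum-cost solutions). An infeasible scenario
#' yields a result with `feasible = FALSE`, not an error.
#'
#' @param x A `chemo_phylo` (see [bind_characters()]).
#' @param scn A [scenario()].
#' @inheritParams sankoff
#' @return A `scenario_fit` (also a `sankoff_fit`), with additional
#'   components `scenario` and `origins_used` (per MPR, the number of origin
#'   groups carrying at least one gain).
#' @export
constrained_sankoff <- function(x, scn, cost = step_matrix(),
                                stem_state = "absent", mpr_cap = 10000L) {
  stopifnot(inherits(scn, "scenario"))
  b <- .as_bound(x, scn$character)
  tree <- b$tree
  state_names <- rownames(cost)
  gi <- match("absent", state_names); gj <- match("present", state_names)
  if (is.na(gi) || is.na(gj)) {
    stop("scenario constraints need states `absent` and `present`",
         call. = FALSE)
  }
  group_edges <- lapply(scn$origins, function(g)
    vapply(g, clade_edge, integer(1), tree = tree))
  allowed <- unlist(group_edges, use.names = FALSE)
  base <- unclass(cost)
  banned <- base; banned[gi, gj] <- Inf
  edge_cost_list <- lapply(seq_len(nrow(tree$edge)), function(e)
    if (e %in% allowed) base else banned)
  stem_cost_mat <- if (0L %in% allowed) base else banned
  fit <- .sankoff_fit(tree, b$tip_states, cost, stem_state, mpr_cap,
                      character = scn$character,
                      edge_cost_list = edge_cost_list,
                      stem_cost_mat = stem_cost_mat)
  fit$scenario <- scn
  if (fit$feasible && length(fit$mprs) > 0) {
    gain_edges <- lapply(fit$events, function(ev)
      ev$edge[ev$type == "gain"])
    used <- vapply(gain_edges, function(ge)
      sum(vapply(group_edges, function(g) any(g %in% ge), logical(1))),
      numeric(1))
    if (scn$required) {
      ok <- used == length(group_edges)
      if (!any(ok)) {
        fit$feasible <- FALSE
        fit$infeasibility <- "no minimum-cost reconstruction gains in every origin group"
        fit$mprs <- list(); fit$events <- list()
        used <- numeric(0)
      } else {
        fit$mprs <- fit$mprs[ok]
        fit$events <- fit$events[ok]
        used <- used[ok]
      }
    }
    fit$origins_used <- used
  } else {
    fit$origins_used <- numeric(0)
    if (!fit$feasible) fit$infeasibility <- "no finite-cost reconstruction"
  }
  class(fit) <- c("scenario_fit", class(fit))
  fit
}

#' @export
print.scenario_fit <- function(x, ...) {
  cat("Scenario", x$scenario$label, "--")
  if (!x$feasible) {
    cat(" INFEASIBLE:", x$infeasibility, "\n")
    return(invisible(x))
  }
  cat(" cost", x$cost, "with", length(x$mprs), "reconstruction(s)\n")
  if (length(x$origins_used) > 0) {
    cat("  origin groups used:", paste(sort(unique(x$origins_used)),
                                       collapse = "/"),
        "of", length(x$scenario$origins), "\n")
  }
  NextMethod()
}

#' Rank origin scenarios by constrained parsimony cost
#'
#' Fits every scenario as a constrained reconstruction and tabulates costs,
#' event counts and origin counts, ordered by (cost, label). All scenarios
#' must address the same character; a constrained cost is never below the
#' unconstrained minimum, which is reported alongside.
#'
#' @param x A `chemo_phylo`.
#' @param scenarios List of [scenario()] objects (at least two).
#' @inheritParams sankoff
#' @return A `scenario_ranking`: list with `table` (data frame: label,
#'   feasible, cost, gains, losses, origins, delta_cost), `character`, and
#'   `unconstrained_cost`; fits kept in `$fits`.
#' @export
compare_scenarios <- function(x, scenarios, cost = step_matrix(),
                              stem_state = "absent", mpr_cap = 10000L) {
  stopifnot(is.list(scenarios), length(scenarios) >= 2,
            all(vapply(scenarios, inherits, logical(1), "scenario")))
  labels <- vapply(scenarios, `[[`, character(1), "label")
  if (anyDuplicated(labels)) {
    stop("duplicate scenario label(s): ",
         paste(unique(labels[duplicated(labels)]), collapse = ", "),
         call. = FALSE)
  }
  chars <- unique(vapply(scenarios, `[[`, character(1), "character"))
  if (length(chars) != 1) {
    stop("scenarios address different characters: ",
         paste(chars, collapse = ", "), call. = FALSE)
  }
  fits <- lapply(scenarios, function(s)
    constrained_sankoff(x, s, cost = cost, stem_state = stem_state,
                        mpr_cap = mpr_cap))
  free <- sankoff(x, chars, cost = cost, stem_state = stem_state,
                  mpr_cap = 1L)
  tab <- do.call(rbind, lapply(fits, function(f) {
    ev <- count_events(f)
    data.frame(label = f$scenario$label,
               feasible = f$feasible,
               cost = if (f$feasible) f$cost else Inf,
               gains_min = if (nrow(ev) > 0) min(ev$gains) else NA_real_,
               gains_max = if (nrow(ev) > 0) max(ev$gains) else NA_real_,
               losses_min = if (nrow(ev) > 0) min(ev$losses) else NA_real_,
               losses_max = if (nrow(ev) > 0) max(ev$losses) else NA_real_,
               origins = if (length(f$origins_used) > 0)
                 min(f$origins_used) else NA_real_,
               stringsAsFactors = FALSE)
  }))
  tab <- tab[order(tab$cost, tab$label), , drop = FALSE]
  best <- min(tab$cost)
  tab$delta_cost <- tab$cost - best
  rownames(tab) <- NULL
  structure(list(table = tab, character = chars,
                 unconstrained_cost = free$cost, fits = fits),
            class = "scenario_ranking")
}

#' @export
print.scenario_ranking <- function(x, ...) {
  cat("Scenario ranking for character", sQuote(x$character),
      "(unconstrained minimum cost:", x$unconstrained_cost, ")\n")
  print(x$table)
  invisible(x)
}
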