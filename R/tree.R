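# The converging tree.  The root is the desired phenotype assignment;
# the children of a control set are the minimal assignments that force
# its Boolean equations one step earlier (system_solutions).  Two
# removal rules prune the search: rule 1 drops a candidate containing an
# already-found control set as a sub-assignment with equal values
# ("included"), rule 2 drops a candidate assigning some node the
# opposite of a parent or ancestor value ("contradictory").  The
# surviving non-root sets form the phenotype control kernel (PCK).

#' Test the first removal rule: is a candidate included in a found set?
#'
#' A candidate is *included* in another control set when that set's
#' assignment is a sub-assignment of the candidate with identical
#' values: a smaller perturbation already achieves at least as much.
#' Equal assignments include each other, so a re-discovered set is
#' removed in favour of its earlier occurrence.
#'
#' @param candidate Named 0/1 vector.
#' @param others List of named 0/1 vectors (the control sets found so far).
#' @return Logical with attribute `witness` (the first including set, or
#'   `NULL`).
#' @export
is_included <- function(candidate, others) {
  candidate <- canonical_assignment(candidate)
  for (o in others) {
    o <- canonical_assignment(o)
    if (is_subassignment(o, candidate)) {
      return(structure(TRUE, witness = o))
    }
  }
  structure(FALSE, witness = NULL)
}

#' Test the second removal rule: does a candidate contradict its ancestors?
#'
#' A candidate child set is *contradictory* when it assigns some node the
#' opposite of the value that node carries in the union of the
#' candidate's parent and ancestor sets: clamping the child then breaks
#' the very chain through which it was derived.
#'
#' @param candidate Named 0/1 vector.
#' @param ancestors List of named 0/1 vectors (parent, then higher
#'   ancestors up to the root).
#' @return Logical with attribute `witness` (the first clashing ancestor
#'   set, or `NULL`).
#' @export
is_contradictory <- function(candidate, ancestors) {
  candidate <- canonical_assignment(candidate)
  for (a in ancestors) {
    a <- canonical_assignment(a)
    if (assignments_conflict(candidate, a)) {
      return(structure(TRUE, witness = a))
    }
  }
  structure(FALSE, witness = NULL)
}

# ---- tree bookkeeping ---------------------------------------------------

tree_new <- function(net, phenotype) {
  root <- canonical_assignment(phenotype)
  sets <- list(list(id = 1L, assignment = root, level = 0L, parent = NA_integer_,
                    removed = FALSE, reason = "none", expanded = FALSE,
                    deleted = FALSE, context = list()))
  list(sets = sets, net = net, status = "building", root = 1L)
}

tree_surviving <- function(tree, max_level = Inf) {
  Filter(function(s) !s$deleted && !s$removed && s$level <= max_level, tree$sets)
}

tree_level_ids <- function(tree, level) {
  ids <- vapply(tree$sets, function(s) {
    if (!s$deleted && !s$removed && s$level == level) s$id else NA_integer_
  }, integer(1))
  ids[!is.na(ids)]
}

# The assignments a set's derivation relies on: its parent's assignment
# plus everything the parent itself was derived under.  For an untouched
# tree this is exactly the parent/ancestor chain; a set moved during
# restructuring keeps the context of its original derivation, because
# the values along that (now deleted) chain are still what make it a
# control set, and contradicting them must still remove a child.
tree_derivation_context <- function(tree, id) {
  s <- tree$sets[[id]]
  c(list(s$assignment), s$context)
}

tree_is_ancestor <- function(tree, anc_id, id) {
  cur <- tree$sets[[id]]$parent
  while (!is.na(cur)) {
    if (cur == anc_id) return(TRUE)
    cur <- tree$sets[[cur]]$parent
  }
  FALSE
}

tree_descendants <- function(tree, id) {
  out <- integer(0)
  frontier <- id
  while (length(frontier) > 0L) {
    kids <- vapply(tree$sets, function(s) {
      if (!s$deleted && !is.na(s$parent) && s$parent %in% frontier) s$id
      else NA_integer_
    }, integer(1))
    kids <- kids[!is.na(kids)]
    out <- c(out, kids)
    frontier <- kids
  }
  out
}

tree_add_set <- function(tree, assignment, level, parent, removed = FALSE,
                         reason = "none", context = list()) {
  id <- length(tree$sets) + 1L
  tree$sets[[id]] <- list(id = id, assignment = assignment, level = level,
                          parent = parent, removed = removed, reason = reason,
                          expanded = FALSE, deleted = FALSE, context = context)
  tree
}

tree_config_key <- function(tree) {
  alive <- tree_surviving(tree)
  keys <- vapply(alive, function(s) {
    ctx <- paste(sort(vapply(s$context, assignment_key, character(1))),
                 collapse = "&")
    paste0(s$level, ":", assignment_key(s$assignment), "<", ctx)
  }, character(1))
  paste(sort(keys), collapse = ";")
}

# ---- expansion ----------------------------------------------------------

#' Expand one parent control set of a converging tree
#'
#' Computes the candidate children via [system_solutions()] (for the root
#' the trivial self-perturbation is also a candidate, which the first
#' rule immediately removes), applies removal rule 1 against all control
#' sets found so far, rule 2 against the parent/ancestor union, and then
#' checks whether any surviving child is a strict sub-assignment of an
#' already-found set: such superseded sets are removed with their
#' descendants, or, when one of them is a parent or ancestor (the
#' restructuring case), the tree is rebuilt from the lowest such level.
#'
#' @param tree A `converging_tree` under construction.
#' @param parent_id Integer id of the parent set to expand.
#' @param net The `boolean_network` the tree is built on.
#' @return List with the updated `tree`, the surviving `children`
#'   (list of assignments) and `restart_level` (`NA` or the level from
#'   which construction must resume after restructuring).
#' @export
expand_parent <- function(tree, parent_id, net) {
  parent <- tree$sets[[parent_id]]
  # the root keeps its self-perturbation among the candidates (it is
  # then removed as included in the root); singleton non-root parents
  # exclude their own node entirely
  candidates <- system_solutions(parent$assignment, net,
                                 exclude_self = parent_id != tree$root &&
                                   length(parent$assignment) == 1L)
  candidates <- sort_assignments(candidates)
  level <- parent$level + 1L
  ancestors <- tree_derivation_context(tree, parent_id)
  surviving <- list()
  for (cand in candidates) {
    found <- lapply(tree_surviving(tree), `[[`, "assignment")
    if (isTRUE(as.logical(is_included(cand, found)))) {
      tree <- tree_add_set(tree, cand, level, parent_id,
                           removed = TRUE, reason = "included")
      next
    }
    if (isTRUE(as.logical(is_contradictory(cand, ancestors)))) {
      tree <- tree_add_set(tree, cand, level, parent_id,
                           removed = TRUE, reason = "contradictory")
      next
    }
    tree <- tree_add_set(tree, cand, level, parent_id, context = ancestors)
    surviving[[length(surviving) + 1L]] <- cand
  }
  tree$sets[[parent_id]]$expanded <- TRUE

  # Step 1-1-3: earlier sets strictly containing a surviving child are
  # superseded by the smaller perturbation.
  restart_level <- NA_integer_
  child_ids <- tree_level_ids(tree, level)
  child_ids <- child_ids[vapply(child_ids, function(i) {
    identical(tree$sets[[i]]$parent, parent_id)
  }, logical(1))]
  for (cid in child_ids) {
    cand <- tree$sets[[cid]]$assignment
    superseded <- Filter(function(s) {
      s$id != cid && s$id != tree$root &&
        length(cand) < length(s$assignment) &&
        is_subassignment(cand, s$assignment)
    }, tree_surviving(tree))
    if (length(superseded) == 0L) next
    anc_hit <- Filter(function(s) {
      any(vapply(child_ids, function(i) tree_is_ancestor(tree, s$id, i),
                 logical(1)))
    }, superseded)
    if (length(anc_hit) == 0L) {
      # Case 3-1: remove the superseded sets and their descendants
      for (s in superseded) {
        for (d in c(s$id, tree_descendants(tree, s$id))) {
          tree$sets[[d]]$removed <- TRUE
          if (tree$sets[[d]]$reason == "none") {
            tree$sets[[d]]$reason <- "included"
          }
        }
      }
    } else {
      # Case 3-2: restructure from the lowest affected level
      L <- min(vapply(anc_hit, `[[`, integer(1), "level"))
      at_L <- Filter(function(s) s$level == L, superseded)
      # superseded sets above the cut that are not ancestors (L is the
      # lowest ancestor level, so everything below it is a plain
      # included set) are removed with their descendants as in Case 3-1
      below_L <- Filter(function(s) s$level < L, superseded)
      for (s in below_L) {
        for (d in c(s$id, tree_descendants(tree, s$id))) {
          tree$sets[[d]]$removed <- TRUE
          if (tree$sets[[d]]$reason == "none") {
            tree$sets[[d]]$reason <- "included"
          }
        }
      }
      new_parent <- if (length(at_L) > 0L) at_L[[1L]]$parent else NA_integer_
      # move the including children to level L, re-parented
      movers <- Filter(function(i) {
        any(vapply(at_L, function(s) {
          is_subassignment(tree$sets[[i]]$assignment, s$assignment)
        }, logical(1)))
      }, child_ids)
      for (s in at_L) tree$sets[[s$id]]$removed <- TRUE
      for (s in at_L) tree$sets[[s$id]]$reason <- "included"
      for (i in movers) {
        tree$sets[[i]]$level <- L
        tree$sets[[i]]$parent <- new_parent
      }
      # drop everything strictly below level L (the moved children excepted)
      for (k in seq_along(tree$sets)) {
        s <- tree$sets[[k]]
        if (!s$deleted && s$level > L && !(s$id %in% movers)) {
          tree$sets[[k]]$deleted <- TRUE
        }
      }
      for (k in seq_along(tree$sets)) {
        if (!tree$sets[[k]]$deleted && tree$sets[[k]]$level >= L) {
          tree$sets[[k]]$expanded <- FALSE
        }
      }
      restart_level <- L
      break
    }
  }
  children <- lapply(Filter(function(s) {
    !s$deleted && !s$removed && identical(s$parent, parent_id)
  }, tree$sets), `[[`, "assignment")
  list(tree = tree, children = children, restart_level = restart_level)
}

#' Build the converging tree of a phenotype specification
#'
#' Starts from the root set (the desired phenotype assignment) and
#' expands level by level, parents in sorted order, until every frontier
#' set is a leaf, the level cap is reached, or the restructuring loop
#' guard trips.  The network should already carry any input/mutation
#' clamps; clamp values are folded into the rules when equations are
#' solved.
#'
#' @param net A `boolean_network`.
#' @param phenotype Named 0/1 vector of desired phenotype values, e.g.
#'   `c(P = 0)`.
#' @param max_level Optional level cap; the default safety cap is
#'   `length(net$nodes) + 1`.
#' @return A `converging_tree` with `status` one of `"complete"`,
#'   `"level_capped"`, `"aborted"`.
#' @examples
#' tree <- build_converging_tree(example_network(), c(P = 0))
#' extract_pck(tree)
#' @export
build_converging_tree <- function(net, phenotype, max_level = NULL) {
  stopifnot(inherits(net, "boolean_network"))
  phenotype <- canonical_assignment(phenotype)
  if (length(phenotype) == 0L) stop("empty phenotype specification", call. = FALSE)
  missing <- setdiff(names(phenotype), net$nodes)
  if (length(missing) > 0L) {
    stop("phenotype node(s) absent from network: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  cap <- length(net$nodes) + 1L
  if (!is.null(max_level)) cap <- min(cap, as.integer(max_level))
  tree <- tree_new(net, phenotype)
  tree$phenotype <- phenotype
  level <- 0L
  seen_configs <- character(0)
  repeat {
    frontier <- Filter(function(s) {
      !s$deleted && !s$removed && s$level == level && !s$expanded
    }, tree$sets)
    if (length(frontier) == 0L) {
      deeper <- Filter(function(s) {
        !s$deleted && !s$removed && s$level > level && !s$expanded
      }, tree$sets)
      if (length(deeper) == 0L) {
        tree$status <- "complete"
        break
      }
      level <- level + 1L
      next
    }
    if (level >= cap) {
      tree$status <- "level_capped"
      break
    }
    cfg <- paste0(level, "|", tree_config_key(tree))
    if (cfg %in% seen_configs) {
      tree$status <- "aborted"
      break
    }
    seen_configs <- c(seen_configs, cfg)
    keys <- vapply(frontier, function(s) assignment_key(s$assignment), character(1))
    frontier <- frontier[order(lengths(lapply(frontier, `[[`, "assignment")),
                               keys, method = "radix")]
    restarted <- FALSE
    for (s in frontier) {
      if (tree$sets[[s$id]]$deleted || tree$sets[[s$id]]$removed ||
          tree$sets[[s$id]]$expanded) next
      res <- expand_parent(tree, s$id, net)
      tree <- res$tree
      if (!is.na(res$restart_level)) {
        level <- res$restart_level
        restarted <- TRUE
        break
      }
    }
    if (!restarted) level <- level + 1L
  }
  class(tree) <- "converging_tree"
  tree
}

#' Extract the phenotype control kernel from a converging tree
#'
#' The PCK is the collection of all surviving (non-removed) control sets
#' of the tree, root excluded.  The tree's completion status travels
#' with the result so a level-capped or aborted kernel is clearly
#' labelled as partial.
#'
#' @param tree A `converging_tree`.
#' @return A `pck` object: `control_sets` (list of named 0/1 vectors,
#'   deterministic order), `levels` (their tree levels) and `status`.
#' @export
extract_pck <- function(tree) {
  stopifnot(inherits(tree, "converging_tree"))
  alive <- Filter(function(s) s$id != tree$root, tree_surviving(tree))
  ord <- order(vapply(alive, `[[`, integer(1), "level"),
               lengths(lapply(alive, `[[`, "assignment")),
               vapply(alive, function(s) assignment_key(s$assignment), character(1)),
               method = "radix")
  alive <- alive[ord]
  structure(list(control_sets = lapply(alive, `[[`, "assignment"),
                 levels = vapply(alive, `[[`, integer(1), "level"),
                 phenotype = tree$phenotype,
                 status = tree$status),
            class = "pck")
}

#' Find control sets containing a given node, layer-guided
#'
#' A node outside the layered network can appear in no control set, so
#' the tree is not built at all in that case.  Otherwise the converging
#' tree is built to at least the node's layer index (a control set
#' containing the node cannot appear at a lower level) and the surviving
#' sets containing the node are returned.
#'
#' @param net A `boolean_network`.
#' @param phenotype Named 0/1 vector of desired phenotype values.
#' @param node Node name of interest.
#' @param extra_levels Levels to build beyond the node's layer index.
#' @return List with `control_sets` (possibly empty), `layer` (the
#'   node's layer index or `NA`), and `tree` (`NULL` when not built).
#' @export
find_sets_containing <- function(net, phenotype, node, extra_levels = 0L) {
  lay <- build_layered_network(net, phenotype)
  if (!(node %in% names(lay$layer_of))) {
    return(list(control_sets = list(), layer = NA_integer_, tree = NULL))
  }
  depth <- lay$layer_of[[node]] + as.integer(extra_levels)
  tree <- build_converging_tree(net, phenotype, max_level = max(depth, 1L))
  pck <- extract_pck(tree)
  hits <- Filter(function(a) node %in% names(a), pck$control_sets)
  list(control_sets = hits, layer = lay$layer_of[[node]], tree = tree)
}

#' @export
print.converging_tree <- function(x, ...) {
  alive <- Filter(function(s) !s$deleted, x$sets)
  cat("Converging tree (", x$status, "): root ",
      format_assignment(x$sets[[x$root]]$assignment), "\n", sep = "")
  lv <- vapply(alive, `[[`, integer(1), "level")
  for (k in sort(unique(lv))) {
    if (k == 0L) next
    at <- Filter(function(s) s$level == k, alive)
    lab <- vapply(at, function(s) {
      tag <- if (s$removed) paste0(" [removed: ", s$reason, "]") else ""
      paste0(format_assignment(s$assignment), tag)
    }, character(1))
    cat("  level ", k, ": ", paste(lab, collapse = "  "), "\n", sep = "")
  }
  invisible(x)
}

#' @export
print.pck <- function(x, ...) {
  cat("Phenotype control kernel (", x$status, "): ",
      length(x$control_sets), " minimal control set",
      if (length(x$control_sets) != 1L) "s", "\n", sep = "")
  for (i in seq_along(x$control_sets)) {
    cat("  ", format_assignment(x$control_sets[[i]]),
        "  (level ", x$levels[i], ")\n", sep = "")
  }
  invisible(x)
}
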