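# Minimal forcing assignments of a single Boolean equation, and their
# combination across the system of equations defined by a parent control
# set.  A forcing assignment for n = f(x_1..x_a) is a partial assignment
# of the rule's direct inputs under which f equals n for *every*
# completion of the unassigned inputs -- a prime implicant of the
# indicator function [f = n].

# Truth table of a rule over its own inputs: list(vars, values) where
# values[i] is the output on the i-th row of the standard enumeration
# (first variable most significant).
rule_truth_table <- function(rule) {
  vars <- rule_inputs(rule)
  k <- length(vars)
  if (k == 0L) {
    v <- eval_rule(rule, stats::setNames(list(), character(0)), 1L)
    return(list(vars = character(0), values = v))
  }
  bits <- state_bits(seq_len(2^k) - 1, k)
  vals <- lapply(seq_len(k), function(j) bits[, j])
  names(vals) <- vars
  list(vars = vars, values = eval_rule(rule, vals, 2^k), bits = bits)
}

#' All minimal partial assignments forcing a rule to a target value
#'
#' Enumerates the rule's truth table and returns every minimal partial
#' assignment of its direct inputs under which the rule evaluates to
#' `value` for all completions of the remaining inputs (the prime
#' implicants of the indicator function).  An empty assignment is
#' returned when the rule is constantly equal to `value`; an empty *list*
#' (flagged `unsatisfiable`) when the rule can never equal `value`.
#'
#' @param rule A `logic_rule` or `threshold_rule`.
#' @param value Target value, 0 or 1.
#' @param max_indegree Refusal bound for truth-table enumeration.
#' @return List of canonical named 0/1 vectors, sorted by (size, names,
#'   values); attribute `unsatisfiable` is `TRUE` when no assignment can
#'   force the value.
#' @examples
#' r <- parse_logic_model("P, C & E")$rules$P
#' forcing_solutions(r, 0)  # list(c(C = 0), c(E = 0))
#' @export
forcing_solutions <- function(rule, value, max_indegree = 16L) {
  value <- as.integer(value)
  stopifnot(value %in% c(0L, 1L))
  vars <- rule_inputs(rule)
  k <- length(vars)
  if (k > max_indegree) {
    stop("rule in-degree ", k, " exceeds the truth-table bound of ",
         max_indegree, call. = FALSE)
  }
  tt <- rule_truth_table(rule)
  hit <- tt$values == value
  if (all(hit)) {
    return(structure(list(canonical_assignment(integer(0))), unsatisfiable = FALSE))
  }
  if (!any(hit)) {
    return(structure(list(), unsatisfiable = TRUE))
  }
  sols <- list()
  for (size in seq_len(k)) {
    subsets <- utils::combn(k, size, simplify = FALSE)
    for (sub in subsets) {
      vcombs <- state_bits(seq_len(2^size) - 1, size)
      for (ri in seq_len(nrow(vcombs))) {
        cand <- vcombs[ri, ]
        names(cand) <- tt$vars[sub]
        cand <- canonical_assignment(cand)
        if (any(vapply(sols, is_subassignment, logical(1), b = cand))) next
        rows <- rep(TRUE, length(tt$values))
        for (jj in seq_along(sub)) {
          rows <- rows & (tt$bits[, sub[jj]] == vcombs[ri, jj])
        }
        if (all(tt$values[rows] == value)) {
          sols[[length(sols) + 1L]] <- cand
        }
      }
    }
  }
  structure(sort_assignments(sols), unsatisfiable = FALSE)
}

# Deterministic (size, names, values) ordering of a list of assignments.
sort_assignments <- function(sols) {
  if (length(sols) <= 1L) return(sols)
  keys <- vapply(sols, assignment_key, character(1))
  sizes <- lengths(sols)
  sols[order(sizes, keys, method = "radix")]
}

# Drop assignments that strictly contain another member of the list.
minimal_assignments <- function(sols) {
  if (length(sols) <= 1L) return(sols)
  keys <- vapply(sols, assignment_key, character(1))
  sols <- sols[!duplicated(keys)]
  keep <- rep(TRUE, length(sols))
  for (i in seq_along(sols)) {
    for (j in seq_along(sols)) {
      if (i == j || !keep[i]) next
      if (length(sols[[j]]) < length(sols[[i]]) &&
          is_subassignment(sols[[j]], sols[[i]])) {
        keep[i] <- FALSE
        break
      }
    }
  }
  sols[keep]
}

#' Combine per-equation forcing solutions across a parent control set
#'
#' A parent control set `{(N_1..N_g) = (n_1..n_g)}` is generated one step
#' earlier by any assignment that simultaneously satisfies every equation
#' `n_m = f_{N_m}(...)`.  Each equation's candidate perturbations are its
#' minimal forcing solutions *plus the trivial self-perturbation*
#' `{N_m = n_m}` (keeping that coordinate clamped): the worked
#' constructions list the target node itself among the candidate nodes,
#' and the self-candidate is what lets a clamp of one coordinate stand in
#' for the upstream cause of another.  The candidates are combined by the
#' Cartesian product of the per-equation sets, merging each tuple by
#' union; tuples that assign some node both values are dropped, the
#' merged results are deduplicated and filtered to subset-minimal
#' elements.  For a singleton parent `{K = v}` (other than the tree
#' root), all solutions re-assigning `K` are excluded, which in
#' particular removes the bare self-copy.  Network clamps are folded into
#' the rules first.  If any parent node is an input or clamped node (no
#' usable equation) the result is empty and the parent is a leaf.
#'
#' @param parent Named 0/1 vector: the parent control set.
#' @param net A `boolean_network`.
#' @param max_indegree Passed to [forcing_solutions()].
#' @param exclude_self Drop solutions that re-assign the parent's own
#'   node (applied by the tree to singleton non-root parents).
#' @return List of canonical assignments in deterministic order.
#' @export
system_solutions <- function(parent, net, max_indegree = 16L,
                             exclude_self = length(parent) == 1L) {
  stopifnot(inherits(net, "boolean_network"))
  parent <- canonical_assignment(parent)
  if (length(parent) == 0L) return(list())
  per_eq <- vector("list", length(parent))
  for (i in seq_along(parent)) {
    u <- names(parent)[i]
    r <- effective_rule(net, u)
    if (is.null(r)) return(list())  # input or clamped node: no equation
    sols <- forcing_solutions(r, parent[[i]], max_indegree = max_indegree)
    # the trivial self-perturbation: keep this coordinate clamped
    sols <- c(sols, list(parent[i]))
    keys <- vapply(sols, assignment_key, character(1))
    per_eq[[i]] <- sols[!duplicated(keys)]
  }
  combos <- expand.grid(lapply(per_eq, seq_along), KEEP.OUT.ATTRS = FALSE)
  merged <- list()
  for (ri in seq_len(nrow(combos))) {
    parts <- lapply(seq_along(per_eq), function(j) per_eq[[j]][[combos[ri, j]]])
    ok <- TRUE
    for (a in seq_along(parts)) {
      for (b in seq_len(a - 1L)) {
        if (assignments_conflict(parts[[a]], parts[[b]])) {
          ok <- FALSE
          break
        }
      }
      if (!ok) break
    }
    if (!ok) next
    m <- canonical_assignment(unlist(parts, use.names = TRUE))
    # a solution must not contradict the very values it maintains (the
    # second removal rule would discard it against the parent anyway)
    if (assignments_conflict(m, parent)) next
    merged[[length(merged) + 1L]] <- m
  }
  if (exclude_self && length(parent) == 1L) {
    self <- names(parent)
    merged <- Filter(function(a) !(self %in% names(a)), merged)
  }
  sort_assignments(minimal_assignments(merged))
}
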