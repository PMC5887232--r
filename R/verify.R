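# Ground truth for any-to-multiple phenotype control: clamp a control
# set, enumerate (or sample) the attractors of the controlled network,
# and require the desired phenotype values on every attractor state.
#
# A phenotype value must be *generated* by the network, not merely
# imposed: when a control set clamps a phenotype node itself, that
# node's original update rule is evaluated on each attractor state and
# must produce the desired value.  Without this, clamping the phenotype
# node trivially "passes" while the underlying circuit still drives the
# opposite value.

#' Verify that a control set forces the desired phenotype
#'
#' Clamps `control`, finds the attractors of the controlled network, and
#' checks that every state of every attractor carries the desired value
#' of every phenotype node (cyclic attractors must satisfy the
#' specification in all of their states: an oscillating phenotype is a
#' failure).  Exhaustive mode is exact; sampled mode checks the
#' attractors reached from seeded random initial states.
#'
#' @param net A `boolean_network`.
#' @param control Named 0/1 vector (may be empty: the uncontrolled
#'   network).
#' @param phenotype Named 0/1 vector of desired phenotype values.
#' @param method `"exhaustive"` or `"sampled"`.
#' @param n_init,seed,max_free Passed to [find_attractors()].
#' @return A `verification_report`: `holds`, `counterexample` (`NULL` or
#'   a list with the violating attractor, one of its states as a
#'   reachable initial condition, and the violated node),
#'   `attractors_after`, plus the mode metadata.
#' @examples
#' verify_control_set(example_network(), c(C = 0), c(P = 0))
#' @export
verify_control_set <- function(net, control, phenotype,
                               method = c("exhaustive", "sampled"),
                               n_init = 1000L, seed = NULL, max_free = 22L) {
  stopifnot(inherits(net, "boolean_network"))
  method <- match.arg(method)
  control <- canonical_assignment(control)
  phenotype <- canonical_assignment(phenotype)
  missing <- setdiff(names(phenotype), net$nodes)
  if (length(missing) > 0L) {
    stop("phenotype node(s) absent from network: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  cnet <- apply_control(net, control)
  atts <- find_attractors(cnet, method = method, n_init = n_init, seed = seed,
                          max_free = max_free)
  holds <- TRUE
  counterexample <- NULL
  for (a in atts$attractors) {
    for (ri in seq_len(nrow(a$states))) {
      s <- a$states[ri, ]
      for (p in names(phenotype)) {
        d <- phenotype[[p]]
        val <- s[[p]]
        gen <- val
        if (p %in% names(cnet$clamps) && !is.null(net$rules[[p]])) {
          vals <- as.list(s)
          gen <- eval_rule(net$rules[[p]], vals, 1L)
        }
        if (val != d || gen != d) {
          holds <- FALSE
          counterexample <- list(initial_state = s, attractor = a,
                                 violated_node = p)
          break
        }
      }
      if (!holds) break
    }
    if (!holds) break
  }
  structure(list(holds = holds, control = control, phenotype = phenotype,
                 mode = method, seed = atts$seed, n_init = atts$n_init,
                 counterexample = counterexample, attractors_after = atts),
            class = "verification_report")
}

#' Check subset-minimality of a control set
#'
#' A control set is minimal when no proper subset (the empty set
#' included) already forces the phenotype.  All `2^|c| - 1` proper
#' subsets are verified, so the set must be small.
#'
#' @inheritParams verify_control_set
#' @return Logical with attribute `failing_subset`: the first (smallest)
#'   proper subset that passes verification, or `NULL` when the set is
#'   minimal.
#' @export
verify_minimality <- function(net, control, phenotype,
                              method = c("exhaustive", "sampled"),
                              n_init = 1000L, seed = NULL, max_free = 22L) {
  method <- match.arg(method)
  control <- canonical_assignment(control)
  k <- length(control)
  if (k == 0L) return(structure(TRUE, failing_subset = NULL))
  for (size in 0:(k - 1L)) {
    subs <- if (size == 0L) list(integer(0)) else
      utils::combn(k, size, simplify = FALSE)
    for (sub in subs) {
      subset <- control[sub]
      rep <- verify_control_set(net, subset, phenotype, method = method,
                                n_init = n_init, seed = seed,
                                max_free = max_free)
      if (rep$holds) {
        return(structure(FALSE, failing_subset = canonical_assignment(subset)))
      }
    }
  }
  structure(TRUE, failing_subset = NULL)
}

#' Brute-force enumeration of all minimal forcing assignments
#'
#' Exhaustively searches all partial assignments of up to `max_size`
#' nodes, keeping those that pass exhaustive verification and are not
#' supersets of a smaller forcing assignment.  This is the independent
#' oracle for the kernel property: every forcing assignment must contain
#' at least one kernel member.  By default candidates range over the
#' non-phenotype free nodes, matching the method's setting of
#' controlling only non-phenotype nodes.  With
#' `include_phenotype = TRUE` phenotype-node clamps are enumerated too;
#' such a clamp only passes when the node's own rule regenerates the
#' desired value on every attractor state (see [verify_control_set()]),
#' so trivial self-clamps are rejected on dynamical grounds.
#'
#' @param net A `boolean_network` with at most 12 free nodes.
#' @param phenotype Named 0/1 vector of desired phenotype values.
#' @param max_size Largest assignment size searched (at most 3).
#' @param include_phenotype Also enumerate clamps of phenotype nodes.
#' @return List of canonical assignments in deterministic order.
#' @export
brute_force_kernel <- function(net, phenotype, max_size = 2L,
                               include_phenotype = FALSE) {
  stopifnot(inherits(net, "boolean_network"))
  phenotype <- canonical_assignment(phenotype)
  nodes <- free_nodes(net)
  if (length(nodes) > 12L) {
    stop("brute-force search refused: ", length(nodes), " free nodes (max 12)",
         call. = FALSE)
  }
  if (!include_phenotype) nodes <- setdiff(nodes, names(phenotype))
  if (max_size > 3L) stop("brute-force search refused: max_size > 3", call. = FALSE)
  empty_rep <- verify_control_set(net, integer(0), phenotype)
  if (empty_rep$holds) {
    return(list(canonical_assignment(integer(0))))
  }
  found <- list()
  for (size in seq_len(max_size)) {
    if (size > length(nodes)) break
    for (sub in utils::combn(length(nodes), size, simplify = FALSE)) {
      vcombs <- state_bits(seq_len(2^size) - 1, size)
      for (ri in seq_len(nrow(vcombs))) {
        cand <- vcombs[ri, ]
        names(cand) <- nodes[sub]
        cand <- canonical_assignment(cand)
        if (any(vapply(found, is_subassignment, logical(1), b = cand))) next
        rep <- verify_control_set(net, cand, phenotype)
        if (rep$holds) found[[length(found) + 1L]] <- cand
      }
    }
  }
  sort_assignments(found)
}

#' @export
print.verification_report <- function(x, ...) {
  cat("Verification (", x$mode, "): control ", format_assignment(x$control),
      ", phenotype ", format_assignment(x$phenotype), " -> ",
      if (x$holds) "HOLDS" else "FAILS", "\n", sep = "")
  if (!x$holds) {
    cat("  violated node:", x$counterexample$violated_node, "\n")
    cat("  reachable violating state:",
        paste(x$counterexample$initial_state, collapse = ""), "\n")
  }
  invisible(x)
}
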