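# Independent oracles used by the test suite.  Each deliberately takes a
# different route than the package implementation: forcing solutions by
# raw partial-assignment enumeration, attractors via strongly connected
# components of the state-transition graph (igraph), and layering via
# shortest paths on the regulator graph (igraph).

suppressPackageStartupMessages(library(igraph))

# Truth table of a rule as a function of its inputs, via the public API.
oracle_rule_outputs <- function(net, node, input_states) {
  apply(input_states, 1L, function(row) {
    # complete to a full state; non-input nodes are irrelevant for the rule
    s <- stats::setNames(rep(0L, length(net$nodes)), net$nodes)
    s[colnames(input_states)] <- row
    synchronous_step(net, s)[[node]]
  })
}

# All minimal partial assignments of `vars` forcing `node`'s rule to
# `value`, by enumerating every one of the 3^k partial assignments and
# testing every completion.
oracle_forcing <- function(net, node, value) {
  vars <- all_rule_inputs(net, node)
  k <- length(vars)
  if (k == 0L) {
    s <- stats::setNames(rep(0L, length(net$nodes)), net$nodes)
    out <- synchronous_step(net, s)[[node]]
    return(if (out == value) list(stats::setNames(integer(0), character(0)))
           else list())
  }
  full <- as.matrix(expand.grid(rep(list(0:1), k)))
  colnames(full) <- vars
  outs <- oracle_rule_outputs(net, node, full)
  partials <- as.matrix(expand.grid(rep(list(c(NA, 0L, 1L)), k)))
  colnames(partials) <- vars
  forcing <- list()
  for (ri in seq_len(nrow(partials))) {
    p <- partials[ri, ]
    fixed <- !is.na(p)
    rows <- rep(TRUE, nrow(full))
    for (v in vars[fixed]) rows <- rows & (full[, v] == p[[v]])
    if (all(outs[rows] == value)) {
      a <- p[fixed]
      forcing[[length(forcing) + 1L]] <- a[order(names(a))]
    }
  }
  # minimality filter
  is_sub <- function(a, b) all(names(a) %in% names(b)) && all(b[names(a)] == a)
  keep <- vapply(seq_along(forcing), function(i) {
    !any(vapply(seq_along(forcing), function(j) {
      j != i && length(forcing[[j]]) < length(forcing[[i]]) &&
        is_sub(forcing[[j]], forcing[[i]])
    }, logical(1)))
  }, logical(1))
  out <- forcing[keep]
  keys <- vapply(out, function(a) paste0(names(a), "=", a, collapse = ","),
                 character(1))
  out[order(lengths(out), keys, method = "radix")]
}

all_rule_inputs <- function(net, node) {
  r <- net$rules[[node]]
  if (is.null(r)) character(0) else r$inputs
}

# Attractor state sets via strongly connected components of the full
# state-transition graph.
oracle_attractor_states <- function(net) {
  nodes <- setdiff(net$nodes, names(net$clamps))
  nf <- length(nodes)
  m <- 2^nf
  codes <- seq_len(m) - 1
  succ <- vapply(codes, function(code) {
    bits <- as.integer(intToBits(code))[nf:1]
    s <- stats::setNames(rep(0L, length(net$nodes)), net$nodes)
    s[nodes] <- bits
    for (u in names(net$clamps)) s[u] <- net$clamps[[u]]
    nxt <- synchronous_step(net, s)
    sum(nxt[nodes] * 2^(nf - seq_len(nf)))
  }, numeric(1))
  g <- igraph::graph_from_edgelist(cbind(as.character(codes),
                                         as.character(succ)))
  comp <- igraph::components(g, mode = "strong")
  att <- list()
  for (ci in seq_len(comp$no)) {
    members <- as.numeric(names(comp$membership)[comp$membership == ci])
    if (length(members) > 1L) {
      att[[length(att) + 1L]] <- sort(members)
    } else if (succ[members + 1] == members) {
      att[[length(att) + 1L]] <- members
    }
  }
  att[order(vapply(att, `[`, numeric(1), 1L))]
}

# Layered sets via reversed-edge BFS / shortest paths on the regulator
# graph read from the update rules.
oracle_layers <- function(net, pheno) {
  edges <- character(0)
  for (u in net$nodes) {
    regs <- if (u %in% names(net$clamps)) character(0) else all_rule_inputs(net, u)
    regs <- setdiff(regs, names(net$clamps))
    for (v in regs) edges <- c(edges, v, u)  # regulator -> target
  }
  g <- igraph::make_empty_graph(directed = TRUE) +
    igraph::vertices(net$nodes)
  if (length(edges) > 0L) g <- g + igraph::edges(edges)
  d <- igraph::distances(g, v = net$nodes, to = pheno, mode = "out")
  short <- apply(d, 1L, min)
  lay <- split(net$nodes[is.finite(short)], short[is.finite(short)])
  list(layers = lapply(unname(lay), sort),
       non_influential = net$nodes[!is.finite(short)])
}

# Convenience: assignments-as-sets comparison helpers.
assignment_keys <- function(sets) {
  vapply(sets, function(a) paste0(names(a), "=", a, collapse = ","), character(1))
}
expect_same_assignment_sets <- function(got, want) {
  expect_setequal(assignment_keys(got), assignment_keys(want))
}
contains_some_member <- function(assignment, members) {
  any(vapply(members, function(m) {
    all(names(m) %in% names(assignment)) && all(assignment[names(m)] == m)
  }, logical(1)))
}
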