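# Packaged models and the seeded random network generator.

#' The seven-node worked example network
#'
#' A small Boolean network with one phenotype node `P` used throughout
#' the documentation.  The rules for `P`, `C`, `E` and `A` are given
#' directly by the source diagram's text; the rules for `B`, `D` and `F`
#' are transcribed from the diagram and pinned by several independent
#' dynamical facts (see the packaged model file
#' `extdata/example_network.bnet` for the transcription notes): the
#' uncontrolled network has exactly the two point attractors
#' `(A..F,P) = (1,0,1,1,1,1,1)` and `(0,...,0)`; clamping `{C=0}` drives
#' every state to the all-zero attractor and clamping `{B=1}` to
#' `(0,1,0,0,0,0,0)`; and the six singleton clamps `{C=0}, {E=0},
#' {B=1}, {D=0}, {A=0}, {F=0}` are exactly the single-node assignments
#' that force `P = 0`.
#'
#' @return A `boolean_network` of 7 nodes.
#' @examples
#' extract_pck(build_converging_tree(example_network(), c(P = 0)))
#' @export
example_network <- function() {
  path <- system.file("extdata", "example_network.bnet", package = "pckernel")
  if (path == "") {
    stop("packaged example model not found; is pckernel installed?",
         call. = FALSE)
  }
  parse_logic_model(path)
}

#' Load a transcription of the 53-node MAPK logic model
#'
#' The MAPK proliferation/apoptosis signalling model (53 nodes, 88
#' links, logic update rules) is distributed as a spreadsheet supplement
#' of its source publication and is not bundled with this package.  To
#' analyse it, transcribe the update rules into the plain-text logic
#' format (one `"Target, expression"` line per node) and pass the file
#' path here; the loader checks the expected node count.
#'
#' @param path Path to a transcribed rule file, or `NULL`.
#' @return A `boolean_network` of 53 nodes.
#' @export
mapk_fixture <- function(path = NULL) {
  load_transcribed_model(path, "MAPK", n_nodes = 53L, kind = "logic")
}

#' Load a transcription of the 96-node cancer signalling threshold model
#'
#' The cancer cell signalling model (96 nodes, 265 links, signed
#' threshold update rules) is distributed as a spreadsheet supplement of
#' its source publication and is not bundled with this package.  To
#' analyse it, transcribe the edge list into a `source,target,weight`
#' CSV and pass the file path here; the loader checks the expected node
#' count.
#'
#' @param path Path to a transcribed edge-table CSV, or `NULL`.
#' @param tie_policy Tie rule handed to [parse_threshold_model()]; the
#'   transcription should record which policy reproduces the source
#'   model's attractors.
#' @return A `boolean_network` of 96 nodes.
#' @export
cancer_fixture <- function(path = NULL, tie_policy = "zero") {
  load_transcribed_model(path, "cancer signalling", n_nodes = 96L,
                         kind = "threshold", tie_policy = tie_policy)
}

load_transcribed_model <- function(path, label, n_nodes, kind,
                                   tie_policy = "zero") {
  if (is.null(path) || !file.exists(path %||% "")) {
    stop("no transcription of the ", label, " model is available: ",
         "the source model is a spreadsheet supplement that must be ",
         "transcribed by hand (", kind, " format) and passed via `path`. ",
         "Nothing is fabricated in its place.", call. = FALSE)
  }
  net <- if (kind == "logic") parse_logic_model(path)
  else parse_threshold_model(path, tie_policy = tie_policy)
  if (length(net$nodes) != n_nodes) {
    stop("transcribed ", label, " model has ", length(net$nodes),
         " nodes; expected ", n_nodes, call. = FALSE)
  }
  net
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Generate a seeded random Boolean network
#'
#' Draws a network with `n_nodes` nodes and a designated phenotype node.
#' With `connected = TRUE` (default) every node is guaranteed a
#' regulatory path to the phenotype node, so the whole network is
#' layered -- the regime in which kernel-property tests are meaningful.
#' Rule families: `"nested"` builds read-once AND/OR trees with random
#' leaf negations (every listed regulator is essential), `"table"` draws
#' a uniform random truth table (restricted to its essential inputs and
#' rebuilt as a disjunctive normal form), `"threshold"` draws signed
#' unit/double weights.  The same configuration and seed always
#' reproduce the identical network.
#'
#' @param n_nodes Number of nodes (the last node, named `P`, is the
#'   phenotype node; the others are `N1`, `N2`, ...).
#' @param min_indegree,max_indegree In-degree range for each rule.
#' @param family `"nested"`, `"table"` or `"threshold"`.
#' @param connected Guarantee every node a path to the phenotype node.
#' @param seed Integer seed (required).
#' @return A `boolean_network`; all nodes carry rules (no input nodes).
#' @examples
#' random_network(6, seed = 1)
#' @export
random_network <- function(n_nodes, min_indegree = 1L, max_indegree = 3L,
                           family = c("nested", "table", "threshold"),
                           connected = TRUE, seed) {
  family <- match.arg(family)
  stopifnot(n_nodes >= 2L, min_indegree >= 1L, max_indegree >= min_indegree)
  if (missing(seed)) stop("random_network needs an explicit seed", call. = FALSE)
  with_seed(seed, {
    nodes <- c(paste0("N", seq_len(n_nodes - 1L)), "P")
    # spanning structure: node i (i >= 2, in the order P, N1, N2, ...)
    # regulates some earlier node, so every node reaches P
    ordered <- c("P", nodes[-n_nodes])
    required <- vector("list", n_nodes)  # regulators forced into each rule
    names(required) <- nodes
    if (connected) {
      for (i in 2:n_nodes) {
        tgt <- ordered[sample.int(i - 1L, 1L)]
        required[[tgt]] <- c(required[[tgt]], ordered[i])
      }
    }
    rules <- list()
    for (u in nodes) {
      req <- unique(required[[u]])
      ks <- seq(min_indegree, max_indegree)
      k <- ks[sample.int(length(ks), 1L)]
      k <- max(k, length(req))
      pool <- setdiff(nodes, req)
      regs <- c(req, sample(pool, min(k - length(req), length(pool))))
      regs <- sample(regs)  # shuffle so required regulators sit anywhere
      rules[[u]] <- switch(family,
        nested = new_logic_rule(u, random_readonce_expr(regs)),
        table = random_table_rule(u, regs),
        threshold = new_threshold_rule(u, regs,
          sample(c(-2L, -1L, 1L, 2L), length(regs), replace = TRUE)))
    }
    new_boolean_network(nodes, rules)
  })
}

# Read-once AND/OR tree with negated leaves: every variable essential.
random_readonce_expr <- function(vars) {
  leaf <- function(v) if (stats::runif(1) < 0.4) ast_not(ast_var(v)) else ast_var(v)
  if (length(vars) == 1L) return(leaf(vars))
  split_at <- sample.int(length(vars) - 1L, 1L)
  left <- random_readonce_expr(vars[seq_len(split_at)])
  right <- random_readonce_expr(vars[-seq_len(split_at)])
  if (stats::runif(1) < 0.5) ast_and(list(left, right)) else ast_or(list(left, right))
}

# Uniform random truth table, restricted to essential inputs and
# re-expressed as a minterm DNF.  Required regulators are kept essential
# by flipping one table entry when needed.
random_table_rule <- function(target, regs) {
  k <- length(regs)
  for (attempt in 1:20) {
    values <- sample(0:1, 2^k, replace = TRUE)
    ess <- essential_inputs(values, k)
    if (all(seq_len(k) %in% ess) || attempt == 20L) break
  }
  ess <- essential_inputs(values, k)
  if (length(ess) == 0L) {
    return(new_logic_rule(target, ast_const(values[1L])))
  }
  keep <- regs[ess]
  bits <- state_bits(seq_len(2^k) - 1, k)
  sub <- unique(data.frame(bits[, ess, drop = FALSE], v = values))
  terms <- list()
  for (ri in which(sub$v == 1L)) {
    lits <- lapply(seq_along(keep), function(j) {
      if (sub[ri, j] == 1L) ast_var(keep[j]) else ast_not(ast_var(keep[j]))
    })
    terms[[length(terms) + 1L]] <- if (length(lits) == 1L) lits[[1L]] else ast_and(lits)
  }
  expr <- if (length(terms) == 0L) ast_const(0L)
  else if (length(terms) == 1L) terms[[1L]] else ast_or(terms)
  new_logic_rule(target, expr)
}

essential_inputs <- function(values, k) {
  if (k == 0L) return(integer(0))
  bits <- state_bits(seq_len(2^k) - 1, k)
  ess <- integer(0)
  for (j in seq_len(k)) {
    partner <- ifelse(bits[, j] == 0L,
                      seq_len(2^k) + 2^(k - j),
                      seq_len(2^k) - 2^(k - j))
    if (any(values != values[partner])) ess <- c(ess, j)
  }
  ess
}
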