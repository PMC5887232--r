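#' @title Boolean network models
#' @description A `boolean_network` holds named nodes together with one
#' update rule per non-input node.  Rules are either logic rules (an
#' expression over `&`, `|`, `!`) or signed-threshold rules (next value
#' decided by the sign of a weighted sum of regulators).  Nodes without a
#' rule are input nodes: under synchronous updating they keep whatever
#' value they carry, so they act as constants once set.  Clamps fix a
#' node's value permanently and override its rule.
#' @name boolean_network
NULL

new_logic_rule <- function(target, expr) {
  structure(list(target = target, expr = expr, inputs = expr_vars(expr)),
            class = "logic_rule")
}

new_threshold_rule <- function(target, sources, weights, bias = 0L,
                               tie_policy = c("zero", "retain")) {
  tie_policy <- match.arg(tie_policy)
  weights <- as.integer(weights)
  if (any(weights == 0L)) stop("threshold rule for '", target, "' has a zero weight",
                               call. = FALSE)
  if (anyDuplicated(sources)) stop("duplicate regulator in threshold rule for '",
                                   target, "'", call. = FALSE)
  inputs <- sources
  if (tie_policy == "retain" && !(target %in% inputs)) inputs <- c(inputs, target)
  structure(list(target = target, sources = sources, weights = weights,
                 bias = as.integer(bias), tie_policy = tie_policy, inputs = inputs),
            class = "threshold_rule")
}

rule_inputs <- function(rule) rule$inputs

# Vectorised rule evaluation over a named list of integer vectors.
eval_rule <- function(rule, vals, nstates) {
  if (inherits(rule, "logic_rule")) {
    return(eval_ast(rule$expr, vals, nstates))
  }
  s <- rep.int(rule$bias, nstates)
  for (i in seq_along(rule$sources)) {
    s <- s + rule$weights[i] * vals[[rule$sources[i]]]
  }
  out <- integer(nstates)
  out[s > 0L] <- 1L
  if (rule$tie_policy == "retain") {
    tie <- s == 0L
    out[tie] <- vals[[rule$target]][tie]
  }
  out
}

new_boolean_network <- function(nodes, rules, clamps = integer(0)) {
  inputs <- setdiff(nodes, names(rules))
  structure(list(nodes = nodes, rules = rules, inputs = inputs,
                 clamps = clamps),
            class = "boolean_network")
}

#' Parse a logic-rule Boolean network model
#'
#' Reads a plain-text model in a BoolNet-style dialect: one rule per line,
#' either `"Target, expression"` or `"Target* = expression"`, with the
#' operators `&` (AND), `|` (OR), `!` (NOT) and parentheses.  Lines
#' starting with `#` and blank lines are ignored, as is an optional
#' `targets, factors` header.  Names referenced by some rule but never
#' given a rule of their own become input nodes.
#'
#' @param text Character vector of rule lines, a single string with
#'   embedded newlines, or the path of a file to read.
#' @return A `boolean_network` object.
#' @examples
#' net <- parse_logic_model(c("P, C & E", "C, !B & D & E"))
#' net$inputs
#' @export
parse_logic_model <- function(text) {
  if (length(text) == 1L && !grepl("\n", text) && file.exists(text)) {
    text <- readLines(text, warn = FALSE)
  }
  lines <- strsplit(paste(text, collapse = "\n"), "\n", fixed = TRUE)[[1L]]
  rules <- list()
  order_seen <- character(0)
  for (i in seq_along(lines)) {
    line <- trimws(lines[i])
    if (line == "" || startsWith(line, "#")) next
    if (grepl("^targets\\s*,\\s*factors$", tolower(line))) next
    if (grepl("^[^,*=]+\\*\\s*=", line)) {
      m <- regmatches(line, regexec("^([^,*=]+)\\*\\s*=\\s*(.+)$", line))[[1L]]
      target <- trimws(m[2L]); body <- m[3L]
    } else if (grepl(",", line, fixed = TRUE)) {
      cut <- regexpr(",", line, fixed = TRUE)
      target <- trimws(substr(line, 1L, cut - 1L))
      body <- substr(line, cut + 1L, nchar(line))
    } else {
      stop("line ", i, ": expected 'Target, expression' or 'Target* = expression': ",
           line, call. = FALSE)
    }
    if (target == "") stop("line ", i, ": empty target name", call. = FALSE)
    if (target %in% names(rules)) {
      stop("line ", i, ": duplicate rule for target '", target, "'", call. = FALSE)
    }
    expr <- tryCatch(parse_expression(body),
                     error = function(e) stop("line ", i, ": ", conditionMessage(e),
                                              call. = FALSE))
    rules[[target]] <- new_logic_rule(target, expr)
    order_seen <- c(order_seen, target, expr_vars(expr))
  }
  if (length(rules) == 0L) stop("no rules found in model text", call. = FALSE)
  # ruled nodes in file order first, then referenced-only input nodes
  nodes <- unique(c(names(rules), order_seen))
  new_boolean_network(nodes, rules)
}

#' Serialize a logic-rule network back to model text
#'
#' Writes one `"Target, expression"` line per ruled node in canonical form
#' (minimal parentheses, `&` binding tighter than `|`).  Parsing the
#' output reproduces the network.
#'
#' @param net A `boolean_network` with logic rules.
#' @param file Optional path; when given the lines are written there.
#' @return Invisibly, the character vector of lines.
#' @export
write_logic_model <- function(net, file = NULL) {
  stopifnot(inherits(net, "boolean_network"))
  lines <- vapply(net$rules, function(r) {
    if (!inherits(r, "logic_rule")) {
      stop("write_logic_model: rule for '", r$target, "' is not a logic rule",
           call. = FALSE)
    }
    paste0(r$target, ", ", format_ast(r$expr))
  }, character(1))
  lines <- unname(lines)
  if (!is.null(file)) writeLines(lines, file)
  invisible(lines)
}

#' Parse a signed-threshold Boolean network model
#'
#' Reads an edge table with columns `source`, `target`, `weight` (signed
#' nonzero integers).  Each target's next value is 1 when the weighted sum
#' of its regulators is positive, 0 when negative, and decided by
#' `tie_policy` at exactly zero: `"zero"` gives 0, `"retain"` keeps the
#' node's current value (which makes the node one of its own inputs).
#'
#' @param table A data frame with columns `source,target,weight`, or a
#'   CSV file path with that header.
#' @param tie_policy Tie rule for a weighted sum of exactly zero.
#' @return A `boolean_network` of threshold rules.
#' @export
parse_threshold_model <- function(table, tie_policy = c("zero", "retain")) {
  tie_policy <- match.arg(tie_policy)
  if (is.character(table)) {
    table <- utils::read.csv(table, stringsAsFactors = FALSE)
  }
  need <- c("source", "target", "weight")
  if (!all(need %in% names(table))) {
    stop("threshold table needs columns source,target,weight", call. = FALSE)
  }
  if (any(table$weight == 0)) stop("zero weight in threshold table", call. = FALSE)
  rules <- list()
  order_seen <- character(0)
  for (tg in unique(table$target)) {
    rows <- table[table$target == tg, , drop = FALSE]
    rules[[tg]] <- new_threshold_rule(tg, rows$source, rows$weight,
                                      tie_policy = tie_policy)
    order_seen <- c(order_seen, rows$source)
  }
  new_boolean_network(unique(c(names(rules), order_seen)), rules)
}

#' Write a threshold network as a source,target,weight table
#' @param net A `boolean_network` of threshold rules.
#' @param file Optional CSV path.
#' @return Invisibly, the data frame.
#' @export
write_threshold_model <- function(net, file = NULL) {
  rows <- do.call(rbind, lapply(net$rules, function(r) {
    data.frame(source = r$sources, target = r$target, weight = r$weights,
               stringsAsFactors = FALSE)
  }))
  rownames(rows) <- NULL
  if (!is.null(file)) utils::write.csv(rows, file, row.names = FALSE, quote = FALSE)
  invisible(rows)
}

#' Clamp nodes of a network to fixed values
#'
#' Returns a copy of the network in which the given nodes are permanently
#' fixed: their own rules are overridden for all time, which is the
#' standard model of pinning a node with an external input.  Clamping is
#' idempotent; re-clamping a node to the same value is a no-op, and
#' re-clamping to a different value is an error.
#'
#' @param net A `boolean_network`.
#' @param control Named 0/1 vector of node values, e.g. `c(C = 0)`.
#' @return The clamped `boolean_network`; the input object is unchanged.
#' @examples
#' net <- example_network()
#' controlled <- apply_control(net, c(C = 0))
#' @export
apply_control <- function(net, control) {
  stopifnot(inherits(net, "boolean_network"))
  control <- canonical_assignment(control)
  missing <- setdiff(names(control), net$nodes)
  if (length(missing) > 0L) {
    stop("control names unknown nodes: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  clamps <- net$clamps
  for (u in names(control)) {
    if (u %in% names(clamps) && clamps[[u]] != control[[u]]) {
      stop("conflicting clamp for '", u, "': already fixed at ", clamps[[u]],
           call. = FALSE)
    }
    clamps[u] <- control[[u]]
  }
  net$clamps <- clamps[order(match(names(clamps), net$nodes))]
  net
}

#' Advance a network state by one synchronous step
#'
#' Every unclamped ruled node takes the value of its update rule evaluated
#' on the current state; clamped nodes keep their clamp value; input nodes
#' keep their current value.
#'
#' @param net A `boolean_network`.
#' @param state Named 0/1 vector covering all nodes.
#' @return The successor state, in network node order.
#' @export
synchronous_step <- function(net, state) {
  stopifnot(inherits(net, "boolean_network"))
  if (!all(net$nodes %in% names(state))) {
    stop("state must assign every node", call. = FALSE)
  }
  state <- state[net$nodes]
  vals <- as.list(as.integer(state))
  names(vals) <- net$nodes
  nxt <- vapply(net$nodes, function(u) {
    if (u %in% names(net$clamps)) return(net$clamps[[u]])
    r <- net$rules[[u]]
    if (is.null(r)) return(vals[[u]])
    eval_rule(r, vals, 1L)
  }, integer(1))
  names(nxt) <- net$nodes
  nxt
}

# Effective regulators of a node: the rule's variable list, empty for
# input and clamped nodes.  Used by the layered network so that topology
# and dynamics always agree.
effective_regulators <- function(net, node) {
  if (node %in% names(net$clamps)) return(character(0))
  r <- net$rules[[node]]
  if (is.null(r)) return(character(0))
  setdiff(rule_inputs(r), names(net$clamps))
}

# Rule with the network's clamps folded in as constants.  Logic rules get
# constant substitution; threshold rules fold clamped regulators into the
# bias term.  Returns NULL for input/clamped nodes.
effective_rule <- function(net, node) {
  if (node %in% names(net$clamps)) return(NULL)
  r <- net$rules[[node]]
  if (is.null(r)) return(NULL)
  if (length(net$clamps) == 0L) return(r)
  fold_rule(r, net$clamps)
}

fold_rule <- function(rule, known) {
  if (inherits(rule, "logic_rule")) {
    return(new_logic_rule(rule$target, fold_ast(rule$expr, known)))
  }
  keep <- !(rule$sources %in% names(known))
  bias <- rule$bias +
    sum(rule$weights[!keep] * as.integer(known[rule$sources[!keep]]))
  if (rule$tie_policy == "retain" && rule$target %in% names(known)) {
    # a clamped node never reads itself; retain collapses to zero policy
    return(new_threshold_rule(rule$target, rule$sources[keep],
                              rule$weights[keep], bias, "zero"))
  }
  new_threshold_rule(rule$target, rule$sources[keep], rule$weights[keep],
                     bias, rule$tie_policy)
}

#' @export
print.boolean_network <- function(x, ...) {
  cat("Boolean network:", length(x$nodes), "nodes,",
      length(x$rules), "rules,", length(x$inputs), "input nodes\n")
  for (r in x$rules) {
    if (inherits(r, "logic_rule")) {
      cat("  ", r$target, "* = ", format_ast(r$expr), "\n", sep = "")
    } else {
      terms <- paste0(ifelse(r$weights > 0, "+", ""), r$weights, "*", r$sources)
      cat("  ", r$target, "* = [", paste(terms, collapse = " "),
          " > 0] (tie: ", r$tie_policy, ")\n", sep = "")
    }
  }
  if (length(x$inputs) > 0L) cat("  inputs:", paste(x$inputs, collapse = ", "), "\n")
  if (length(x$clamps) > 0L) {
    cat("  clamps:", paste0(names(x$clamps), "=", x$clamps, collapse = ", "), "\n")
  }
  invisible(x)
}

# ---- partial assignments ------------------------------------------------

# Named integer 0/1 vector with names sorted; the shared currency of
# control sets, phenotype specs and clamps.
canonical_assignment <- function(x) {
  if (length(x) == 0L) return(structure(integer(0), names = character(0)))
  if (is.null(names(x)) || any(names(x) == "")) {
    stop("assignment must be a named 0/1 vector", call. = FALSE)
  }
  nm <- names(x)
  x <- as.integer(x)
  names(x) <- nm
  # collapse duplicated names; conflicting duplicates are an error
  if (anyDuplicated(names(x))) {
    split_vals <- split(x, names(x))
    bad <- names(split_vals)[vapply(split_vals, function(v) length(unique(v)) > 1L,
                                    logical(1))]
    if (length(bad) > 0L) {
      stop("conflicting values for: ", paste(bad, collapse = ", "), call. = FALSE)
    }
    x <- vapply(split_vals, `[`, integer(1), 1L)
  }
  if (!all(x %in% c(0L, 1L))) stop("assignment values must be 0 or 1", call. = FALSE)
  x[order(names(x))]
}

assignment_key <- function(x) paste0(names(x), "=", x, collapse = ",")

format_assignment <- function(x) {
  if (length(x) == 0L) return("{}")
  paste0("{", paste0(names(x), "=", x, collapse = ", "), "}")
}

# TRUE when `a` is a sub-assignment of `b` (same values on all of a's nodes).
is_subassignment <- function(a, b) {
  if (length(a) > length(b)) return(FALSE)
  if (!all(names(a) %in% names(b))) return(FALSE)
  all(b[names(a)] == a)
}

# TRUE when some node is assigned opposite values in `a` and `b`.
assignments_conflict <- function(a, b) {
  common <- intersect(names(a), names(b))
  length(common) > 0L && any(a[common] != b[common])
}
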