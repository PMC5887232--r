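# Constant propagation: fold fixed input / mutation values through the
# update rules to a fixpoint, splitting the network into nodes with
# forced constant values and a simplified network over the remainder.

#' Propagate fixed values through a Boolean network
#'
#' Substitutes the given constants (inputs, mutations, or values already
#' fixed in the model) into every update rule and folds algebraically
#' (AND with 0 is 0, OR with 1 is 1, NOT of a constant; threshold rules
#' fold fixed regulators into a bias and are decided early when the
#' reachable sign range permits).  Any rule that collapses to a constant
#' fixes its target, and the process repeats until no further rule
#' becomes constant.  Constant folding is confluent, so the result does
#' not depend on substitution order.
#'
#' Nodes named in `given` are treated as overriding clamps (their own
#' rules are discarded, the mutation model).  When a discarded rule
#' itself folds to the opposite constant the model is self-inconsistent;
#' with `conflict = "error"` (default) this aborts with the derivation
#' chain, with `conflict = "override"` the given value silently wins.
#'
#' @param net A `boolean_network`.
#' @param given Named 0/1 vector of fixed values.
#' @param conflict `"error"` or `"override"`.
#' @return A `simplification` object: `fixed_values` (named 0/1 vector
#'   over all forced nodes, `given` included) and `simplified` (a
#'   `boolean_network` over the remaining nodes, whose rules reference no
#'   fixed node).
#' @examples
#' net <- parse_logic_model(c("MEK1_2, !(PPP2CA | AP1)", "AP1, JUN"))
#' propagate_constants(net, c(PPP2CA = 0))
#' @export
propagate_constants <- function(net, given = integer(0),
                                conflict = c("error", "override")) {
  stopifnot(inherits(net, "boolean_network"))
  conflict <- match.arg(conflict)
  given <- canonical_assignment(given)
  missing <- setdiff(names(given), net$nodes)
  if (length(missing) > 0L) {
    stop("given names unknown nodes: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (length(net$clamps) > 0L) {
    both <- intersect(names(given), names(net$clamps))
    bad <- both[given[both] != net$clamps[both]]
    if (length(bad) > 0L) {
      stop("given conflicts with existing clamps: ", paste(bad, collapse = ", "),
           call. = FALSE)
    }
    given <- canonical_assignment(c(given, net$clamps))
  }

  fixed <- given
  derivation <- stats::setNames(rep("given", length(given)), names(given))
  work <- net$rules
  work[names(fixed)] <- NULL
  repeat {
    changed <- FALSE
    for (u in names(work)) {
      folded <- fold_rule(work[[u]], fixed)
      work[[u]] <- folded
      cval <- rule_constant_value(folded)
      if (!is.na(cval)) {
        fixed[u] <- cval
        derivation[u] <- paste0(u, " = ", cval, " from rule ",
                                format_rule(net$rules[[u]]), " under {",
                                paste0(names(fixed), "=", fixed, collapse = ", "),
                                "}")
        work[[u]] <- NULL
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  fixed <- canonical_assignment(fixed)

  # self-consistency of overridden rules
  if (conflict == "error") {
    for (u in names(given)) {
      r <- net$rules[[u]]
      if (is.null(r)) next
      cval <- rule_constant_value(fold_rule(r, fixed))
      if (!is.na(cval) && cval != fixed[[u]]) {
        chain <- derivation[intersect(names(derivation), rule_inputs(r))]
        stop("contradiction: '", u, "' is given as ", fixed[[u]],
             " but its rule folds to ", cval, "\n  chain: ",
             paste(chain, collapse = "\n         "), call. = FALSE)
      }
    }
  }

  remaining <- setdiff(net$nodes, names(fixed))
  simplified <- new_boolean_network(remaining, work)
  structure(list(fixed_values = fixed, simplified = simplified),
            class = "simplification")
}

# NA when the rule is not (algebraically) constant.
rule_constant_value <- function(rule) {
  if (inherits(rule, "logic_rule")) {
    if (rule$expr$type == "const") return(rule$expr$value)
    return(NA_integer_)
  }
  lo <- rule$bias + sum(pmin(rule$weights, 0L))
  hi <- rule$bias + sum(pmax(rule$weights, 0L))
  if (lo > 0L) return(1L)
  # under the zero policy the value is 1 only for a strictly positive sum
  if (rule$tie_policy == "zero" && hi <= 0L) return(0L)
  if (hi < 0L) return(0L)
  NA_integer_
}

format_rule <- function(rule) {
  if (inherits(rule, "logic_rule")) {
    paste0(rule$target, "* = ", format_ast(rule$expr))
  } else {
    terms <- paste0(ifelse(rule$weights > 0, "+", ""), rule$weights, "*", rule$sources)
    paste0(rule$target, "* = [", paste(terms, collapse = " "), " > 0]")
  }
}

#' @export
print.simplification <- function(x, ...) {
  cat("Simplification:", length(x$fixed_values), "fixed nodes,",
      length(x$simplified$nodes), "remaining nodes\n")
  if (length(x$fixed_values) > 0L) {
    cat("  fixed:", paste0(names(x$fixed_values), "=", x$fixed_values,
                           collapse = ", "), "\n")
  }
  invisible(x)
}
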