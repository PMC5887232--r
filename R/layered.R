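# The layered network: hierarchical shells of direct and indirect
# regulators of the phenotype nodes.  Layer 0 is the phenotype set;
# layer k+1 collects the regulators of layer-k nodes not yet placed.
# Because each node's regulator set is read off its update rule, the
# construction is deterministic and unique, and the layer index of a
# node equals the length of its shortest regulatory path to a phenotype
# node.

#' Build the layered network of a phenotype specification
#'
#' @param net A `boolean_network`.
#' @param phenotype Phenotype node names, or a named 0/1 vector whose
#'   names are used.
#' @return A `layered_network`: `layers` (list of sorted node-name sets,
#'   layer 0 first), `layer_of` (named integer map for layered nodes) and
#'   `non_influential` (nodes in no layer; perturbing them can never
#'   change the phenotype values).
#' @examples
#' build_layered_network(example_network(), c(P = 0))
#' @export
build_layered_network <- function(net, phenotype) {
  stopifnot(inherits(net, "boolean_network"))
  pheno <- phenotype_nodes(phenotype)
  missing <- setdiff(pheno, net$nodes)
  if (length(missing) > 0L) {
    stop("phenotype node(s) absent from network: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  regs <- lapply(net$nodes, function(u) effective_regulators(net, u))
  names(regs) <- net$nodes
  layers <- list(sort(pheno))
  placed <- pheno
  repeat {
    frontier <- layers[[length(layers)]]
    cand <- unique(unlist(regs[frontier], use.names = FALSE))
    new <- sort(setdiff(cand, placed))
    if (length(new) == 0L) break
    layers[[length(layers) + 1L]] <- new
    placed <- c(placed, new)
  }
  layer_of <- integer(0)
  for (k in seq_along(layers)) {
    layer_of[layers[[k]]] <- k - 1L
  }
  structure(list(layers = layers, layer_of = layer_of,
                 nodes = net$nodes,
                 non_influential = setdiff(net$nodes, placed)),
            class = "layered_network")
}

#' Split nodes into phenotype-influential and non-influential sets
#'
#' A node is influential exactly when it appears in some layer of the
#' layered network, i.e. has a directed regulatory path to a phenotype
#' node.  Perturbations of non-influential nodes can never change the
#' phenotype values, so they are excluded as control candidates.
#'
#' @inheritParams build_layered_network
#' @return List with `layered` (influential node names, by layer order)
#'   and `non_influential`.
#' @export
influential_partition <- function(net, phenotype) {
  lay <- build_layered_network(net, phenotype)
  list(layered = unlist(lay$layers, use.names = FALSE),
       non_influential = lay$non_influential)
}

phenotype_nodes <- function(phenotype) {
  if (!is.null(names(phenotype)) && all(names(phenotype) != "")) {
    return(unique(names(phenotype)))
  }
  unique(as.character(phenotype))
}

#' @export
print.layered_network <- function(x, ...) {
  cat("Layered network:", sum(lengths(x$layers)), "layered nodes in",
      length(x$layers), "layers\n")
  for (k in seq_along(x$layers)) {
    cat("  layer ", k - 1L, ": ", paste(x$layers[[k]], collapse = ", "),
        "\n", sep = "")
  }
  if (length(x$non_influential) > 0L) {
    cat("  non-influential:", paste(x$non_influential, collapse = ", "), "\n")
  }
  invisible(x)
}
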