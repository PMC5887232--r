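# JSON and DOT serialization.  All JSON is produced with fixed key
# orders and no timestamps, so identical runs are byte-identical.

assignment_to_list <- function(a) {
  if (length(a) == 0L) return(stats::setNames(list(), character(0)))
  as.list(stats::setNames(as.integer(a), names(a)))
}

pck_version <- function() as.character(utils::packageVersion("pckernel"))

tree_is_leaf <- function(tree, id) {
  s <- tree$sets[[id]]
  if (s$removed || s$deleted || !s$expanded) return(FALSE)
  kids <- Filter(function(t) {
    !t$deleted && !t$removed && identical(t$parent, s$id)
  }, tree$sets)
  length(kids) == 0L
}

#' Serialize a converging tree to JSON
#'
#' Removed sets are retained with their removal reason (they correspond
#' to the dotted sets of the method's diagrams); restructured-away sets
#' are not serialized.
#'
#' @param tree A `converging_tree`.
#' @param file Optional output path.
#' @param metadata Optional named list merged into the `meta` block.
#' @return The JSON string, invisibly when written to a file.
#' @export
tree_to_json <- function(tree, file = NULL, metadata = NULL) {
  stopifnot(inherits(tree, "converging_tree"))
  alive <- Filter(function(s) !s$deleted, tree$sets)
  nodes <- lapply(alive, function(s) {
    list(id = s$id,
         level = s$level,
         assignment = assignment_to_list(s$assignment),
         parent_id = if (is.na(s$parent)) NULL else s$parent,
         leaf = tree_is_leaf(tree, s$id),
         removed = s$removed,
         removal_reason = s$reason)
  })
  payload <- list(meta = c(list(tool = "pckernel", version = pck_version()),
                           metadata),
                  status = tree$status,
                  phenotype = assignment_to_list(tree$phenotype),
                  sets = nodes)
  emit_json(payload, file)
}

#' Serialize a phenotype control kernel to JSON
#' @param pck A `pck` object.
#' @param file Optional output path.
#' @param metadata Optional named list merged into the `meta` block.
#' @return The JSON string, invisibly when written to a file.
#' @export
pck_to_json <- function(pck, file = NULL, metadata = NULL) {
  stopifnot(inherits(pck, "pck"))
  payload <- list(meta = c(list(tool = "pckernel", version = pck_version()),
                           metadata),
                  status = pck$status,
                  phenotype = assignment_to_list(pck$phenotype),
                  n_control_sets = length(pck$control_sets),
                  control_sets = lapply(seq_along(pck$control_sets), function(i) {
                    list(level = pck$levels[i],
                         assignment = assignment_to_list(pck$control_sets[[i]]))
                  }))
  emit_json(payload, file)
}

#' Serialize an attractor set to JSON
#' @param atts An `attractor_set`.
#' @param file Optional output path.
#' @param metadata Optional named list merged into the `meta` block.
#' @return The JSON string, invisibly when written to a file.
#' @export
attractors_to_json <- function(atts, file = NULL, metadata = NULL) {
  stopifnot(inherits(atts, "attractor_set"))
  payload <- list(meta = c(list(tool = "pckernel", version = pck_version(),
                                mode = atts$method, seed = atts$seed,
                                n_init = atts$n_init), metadata),
                  n_attractors = length(atts$attractors),
                  attractors = lapply(atts$attractors, function(a) {
                    list(kind = a$kind,
                         length = nrow(a$states),
                         states = lapply(seq_len(nrow(a$states)), function(ri) {
                           as.list(a$states[ri, , drop = TRUE])
                         }))
                  }))
  emit_json(payload, file)
}

#' Serialize a layered network to JSON
#' @param lay A `layered_network`.
#' @param file Optional output path.
#' @param metadata Optional named list merged into the `meta` block.
#' @return The JSON string, invisibly when written to a file.
#' @export
layered_to_json <- function(lay, file = NULL, metadata = NULL) {
  stopifnot(inherits(lay, "layered_network"))
  payload <- list(meta = c(list(tool = "pckernel", version = pck_version()),
                           metadata),
                  n_layers = length(lay$layers),
                  n_layered_nodes = sum(lengths(lay$layers)),
                  layers = stats::setNames(lay$layers,
                                           as.character(seq_along(lay$layers) - 1L)),
                  non_influential = lay$non_influential)
  emit_json(payload, file)
}

emit_json <- function(payload, file) {
  txt <- jsonlite::toJSON(payload, auto_unbox = TRUE, null = "null",
                          pretty = TRUE, digits = NA)
  if (!is.null(file)) {
    writeLines(txt, file)
    return(invisible(as.character(txt)))
  }
  as.character(txt)
}

#' Export a converging tree in Graphviz DOT format
#'
#' Removed sets are drawn dotted with their removal reason, matching the
#' method's tree diagrams.
#'
#' @param tree A `converging_tree`.
#' @param file Optional output path.
#' @return The DOT text, invisibly when written to a file.
#' @export
tree_to_dot <- function(tree, file = NULL) {
  stopifnot(inherits(tree, "converging_tree"))
  alive <- Filter(function(s) !s$deleted, tree$sets)
  lines <- c("digraph converging_tree {", "  rankdir=TB;")
  for (s in alive) {
    lab <- gsub("\"", "\\\\\"", format_assignment(s$assignment))
    style <- if (s$removed) {
      paste0(", style=dotted, color=gray50, xlabel=\"", s$reason, "\"")
    } else ""
    lines <- c(lines, paste0("  n", s$id, " [label=\"", lab, "\"", style, "];"))
  }
  for (s in alive) {
    if (!is.na(s$parent)) {
      lines <- c(lines, paste0("  n", s$parent, " -> n", s$id,
                               if (s$removed) " [style=dotted]" else "", ";"))
    }
  }
  lines <- c(lines, "}")
  txt <- paste(lines, collapse = "\n")
  if (!is.null(file)) {
    writeLines(txt, file)
    return(invisible(txt))
  }
  txt
}

#' Export a layered network in Graphviz DOT format with layer ranks
#' @param net The `boolean_network` the layering was computed on.
#' @param lay A `layered_network` of `net`.
#' @param file Optional output path.
#' @return The DOT text, invisibly when written to a file.
#' @export
layered_to_dot <- function(net, lay, file = NULL) {
  stopifnot(inherits(lay, "layered_network"))
  lines <- c("digraph layered_network {", "  rankdir=BT;")
  for (k in seq_along(lay$layers)) {
    members <- paste0("\"", lay$layers[[k]], "\"", collapse = "; ")
    lines <- c(lines, paste0("  { rank=same; ", members, "; }"))
  }
  for (u in net$nodes) {
    for (v in effective_regulators(net, u)) {
      downhill <- (u %in% names(lay$layer_of)) && (v %in% names(lay$layer_of)) &&
        lay$layer_of[[v]] == lay$layer_of[[u]] + 1L
      lines <- c(lines, paste0("  \"", v, "\" -> \"", u, "\"",
                               if (!downhill) " [style=dashed, color=red]" else "",
                               ";"))
    }
  }
  lines <- c(lines, "}")
  txt <- paste(lines, collapse = "\n")
  if (!is.null(file)) {
    writeLines(txt, file)
    return(invisible(txt))
  }
  txt
}
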