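# Synchronous attractor analysis.
#
# States are encoded as integers over the *free* (unclamped) nodes, with
# the first free node in network order as the most significant bit, so
# numeric comparison of encodings matches lexicographic comparison of
# state vectors.

free_nodes <- function(net) setdiff(net$nodes, names(net$clamps))

# Bit columns for all 2^nf free states (or for a supplied encoding vector).
state_bits <- function(codes, nf) {
  bits <- matrix(0L, nrow = length(codes), ncol = nf)
  rem <- codes
  for (j in seq_len(nf)) {
    w <- 2^(nf - j)
    b <- rem >= w
    bits[, j] <- as.integer(b)
    rem <- rem - w * b
  }
  bits
}

encode_bits <- function(bits) {
  nf <- ncol(bits)
  as.numeric(bits %*% 2^(nf - seq_len(nf)))
}

# Named list of per-node value vectors for a batch of free-state codes.
state_values <- function(net, codes) {
  free <- free_nodes(net)
  n <- length(codes)
  bits <- state_bits(codes, length(free))
  vals <- vector("list", length(net$nodes))
  names(vals) <- net$nodes
  for (j in seq_along(free)) vals[[free[j]]] <- bits[, j]
  for (u in names(net$clamps)) vals[[u]] <- rep.int(net$clamps[[u]], n)
  vals
}

# Successor encodings for a batch of free-state codes.
next_codes <- function(net, codes) {
  free <- free_nodes(net)
  vals <- state_values(net, codes)
  n <- length(codes)
  out <- numeric(n)
  for (j in seq_along(free)) {
    u <- free[j]
    r <- net$rules[[u]]
    v <- if (is.null(r)) vals[[u]] else eval_rule(r, vals, n)
    out <- out + v * 2^(length(free) - j)
  }
  out
}

# Decode a cycle of free-state codes into a full state matrix
# (rows = cycle states in transition order, cols = all nodes).
decode_cycle <- function(net, codes) {
  vals <- state_values(net, codes)
  m <- do.call(cbind, vals)
  rownames(m) <- NULL
  m
}

canonical_cycle <- function(codes) {
  k <- which.min(codes)
  if (k > 1L) codes <- c(codes[k:length(codes)], codes[seq_len(k - 1L)])
  codes
}

new_attractor <- function(net, codes) {
  codes <- canonical_cycle(codes)
  structure(list(states = decode_cycle(net, codes),
                 codes = codes,
                 kind = if (length(codes) == 1L) "point" else "cyclic"),
            class = "attractor")
}

#' Find the attractors of the synchronous dynamics
#'
#' Exhaustive mode enumerates the full state space over the free
#' (unclamped) nodes and returns every attractor.  Sampled mode follows
#' trajectories from `n_init` seeded random initial states and returns
#' the attractors they reach, deduplicated up to cyclic rotation; it is
#' the mode of choice when the free-node count makes enumeration
#' infeasible.  Input nodes without a clamp would silently multiply the
#' state space by held constants, so they must be fixed (via
#' [apply_control()]) before attractors are computed.
#'
#' @param net A `boolean_network` whose input nodes are all clamped.
#' @param method `"exhaustive"` or `"sampled"`.
#' @param n_init Number of sampled initial states (sampled mode).
#' @param seed Integer seed; required in sampled mode and recorded in the
#'   result.
#' @param max_free Refusal bound for exhaustive enumeration.
#' @return An `attractor_set`: a list of `attractor` objects (each a
#'   cycle of full states, rotated so the lexicographically smallest
#'   state comes first) with the search metadata attached.
#' @examples
#' find_attractors(parse_logic_model("P, !P"))
#' @export
find_attractors <- function(net, method = c("exhaustive", "sampled"),
                            n_init = 1000L, seed = NULL, max_free = 22L) {
  stopifnot(inherits(net, "boolean_network"))
  method <- match.arg(method)
  loose_inputs <- setdiff(net$inputs, names(net$clamps))
  if (length(loose_inputs) > 0L) {
    stop("input nodes must be fixed before dynamics are computed: ",
         paste(loose_inputs, collapse = ", "), call. = FALSE)
  }
  free <- free_nodes(net)
  nf <- length(free)
  atts <- if (method == "exhaustive") {
    if (nf > max_free) {
      stop("exhaustive attractor search refused: ", nf,
           " free nodes exceeds the bound of ", max_free, call. = FALSE)
    }
    find_attractors_exhaustive(net, nf)
  } else {
    if (is.null(seed)) stop("sampled attractor search needs an explicit seed",
                            call. = FALSE)
    find_attractors_sampled(net, nf, n_init, seed)
  }
  atts <- atts[order(vapply(atts, function(a) a$codes[1L], numeric(1)),
                     vapply(atts, function(a) length(a$codes), numeric(1)))]
  structure(list(attractors = atts, method = method,
                 n_init = if (method == "sampled") n_init else NULL,
                 seed = if (method == "sampled") seed else NULL,
                 n_free = nf),
            class = "attractor_set")
}

find_attractors_exhaustive <- function(net, nf) {
  m <- 2^nf
  codes <- seq_len(m) - 1
  nxt <- next_codes(net, codes) + 1  # 1-based indices
  color <- integer(m)  # 0 unseen, 1 on current path, 2 finished
  atts <- list()
  for (s in seq_len(m)) {
    if (color[s] != 0L) next
    path <- integer(0)
    v <- s
    while (color[v] == 0L) {
      color[v] <- 1L
      path <- c(path, v)
      v <- nxt[v]
    }
    if (color[v] == 1L) {  # closed a new cycle on the current path
      at <- match(v, path)
      cyc <- path[at:length(path)]
      atts[[length(atts) + 1L]] <- new_attractor(net, cyc - 1)
    }
    color[path] <- 2L
  }
  atts
}

find_attractors_sampled <- function(net, nf, n_init, seed) {
  starts <- with_seed(seed, {
    if (nf <= 25L) {
      floor(stats::runif(n_init) * 2^nf)
    } else {
      # build codes bitwise to keep full-precision uniformity
      bits <- matrix(as.integer(stats::runif(n_init * nf) < 0.5), ncol = nf)
      encode_bits(bits)
    }
  })
  # Floyd cycle detection, vectorised across trajectories.
  slow <- starts
  fast <- next_codes(net, starts)
  active <- rep(TRUE, length(starts))
  guard <- 0L
  while (any(active)) {
    meet <- active & (slow == fast)
    active[meet] <- FALSE
    if (!any(active)) break
    slow[active] <- next_codes(net, slow[active])
    fast[active] <- next_codes(net, next_codes(net, fast[active]))
    guard <- guard + 1L
    if (guard > 2^min(nf, 30L) + 10L) {
      stop("cycle detection failed to converge", call. = FALSE)
    }
  }
  atts <- list()
  seen <- character(0)
  for (code in unique(slow)) {
    cyc <- code
    v <- next_codes(net, code)
    while (v != code) {
      cyc <- c(cyc, v)
      v <- next_codes(net, v)
    }
    cyc <- canonical_cycle(cyc)
    key <- paste(cyc, collapse = " ")
    if (!(key %in% seen)) {
      seen <- c(seen, key)
      atts[[length(atts) + 1L]] <- new_attractor(net, cyc)
    }
  }
  atts
}

#' @export
print.attractor_set <- function(x, ...) {
  cat("Attractor set (", x$method, " mode, ", length(x$attractors),
      " attractor", if (length(x$attractors) != 1L) "s", ")\n", sep = "")
  for (i in seq_along(x$attractors)) {
    a <- x$attractors[[i]]
    cat("  [", i, "] ", a$kind, ", length ", nrow(a$states), ": ", sep = "")
    cat(paste(apply(a$states, 1L, paste, collapse = ""), collapse = " -> "), "\n")
  }
  invisible(x)
}

# Run an expression under a temporary RNG state.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}
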