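# Minimal forcing assignments of single equations and of systems.

test_that("the example network's equation solutions are exact", {
  net <- example_network()
  expect_same_assignment_sets(forcing_solutions(net$rules$P, 0),
                              list(c(C = 0L), c(E = 0L)))
  expect_same_assignment_sets(forcing_solutions(net$rules$C, 0),
                              list(c(B = 1L), c(D = 0L), c(E = 0L)))
  expect_same_assignment_sets(forcing_solutions(net$rules$E, 0),
                              list(c(D = 0L, F = 0L)))
  # identity rule, target value 1
  x <- parse_logic_model("Y, X")$rules$Y
  expect_same_assignment_sets(forcing_solutions(x, 1), list(c(X = 1L)))
})

test_that("tautologies and contradictions are flagged, not errored", {
  r <- parse_logic_model("T, A | !A")$rules$T
  never0 <- forcing_solutions(r, 0)
  expect_length(never0, 0)
  expect_true(attr(never0, "unsatisfiable"))
  always1 <- forcing_solutions(r, 1)
  expect_length(always1, 1)
  expect_length(always1[[1]], 0)  # the empty assignment forces a tautology
  expect_false(attr(always1, "unsatisfiable"))
})

test_that("forcing solutions equal the brute-force prime-implicant oracle", {
  n_rules <- 0L
  for (seed in 1:60) {
    net <- random_network(7, max_indegree = 4,
                          family = c("nested", "table", "threshold")[1 + seed %% 3],
                          seed = 2000 + seed)
    for (node in net$nodes) {
      for (v in 0:1) {
        got <- forcing_solutions(net$rules[[node]], v)
        want <- oracle_forcing(net, node, v)
        expect_same_assignment_sets(got, want)
        n_rules <- n_rules + 1L
      }
    }
  }
  expect_gte(n_rules, 500L)
})

test_that("solution order is deterministic by (size, names, values)", {
  r <- parse_logic_model("T, (!B) & D & E")$rules$T
  sols <- forcing_solutions(r, 0)
  expect_equal(assignment_keys(sols), c("B=1", "D=0", "E=0"))
})

test_that("system solutions take the product, drop conflicts, keep minimal", {
  net <- parse_logic_model(c("X, A & B", "Y, A | C"))
  sols <- system_solutions(c(X = 0, Y = 0), net)
  # upstream causes ({A=0},{B=0}) x ({A=0,C=0}) combine with the trivial
  # self-perturbations of each coordinate; supersets are filtered out
  expect_same_assignment_sets(sols,
                              list(c(A = 0L, C = 0L), c(A = 0L, Y = 0L),
                                   c(B = 0L, Y = 0L), c(X = 0L, Y = 0L)))
  # the purely-upstream route is the minimal non-self survivor
  upstream <- Filter(function(a) !any(names(a) %in% c("X", "Y")), sols)
  expect_same_assignment_sets(upstream, list(c(A = 0L, C = 0L)))

  # conflicting upstream tuples ({A=0} x {A=1}) are dropped entirely;
  # only self-assisted combinations remain
  net2 <- parse_logic_model(c("X, A", "Y, !A"))
  sols2 <- system_solutions(c(X = 0, Y = 0), net2)
  expect_length(Filter(function(a) !any(c("X", "Y") %in% names(a)), sols2), 0)
  for (a in sols2) expect_true(any(c("X", "Y") %in% names(a)))

  # a parent over an input node yields no children (leaf)
  net3 <- parse_logic_model("P, A & B")
  expect_length(system_solutions(c(A = 1), net3), 0)
})

test_that("singleton parents exclude their own node from candidates", {
  net <- parse_logic_model(c("K, K | X", "X, K"))
  sols <- system_solutions(c(K = 0), net)
  expect_length(sols, 0)  # only solution {(K,X)=(0,0)} re-assigns K
  net2 <- parse_logic_model(c("K, K & X", "X, K"))
  expect_same_assignment_sets(system_solutions(c(K = 0), net2),
                              list(c(X = 0L)))
})

test_that("system solutions force every parent equation on all completions", {
  for (seed in 1:30) {
    net <- random_network(8, seed = 3000 + seed)
    parent_nodes <- unique(net$nodes[c(1 + seed %% 5, 4 + seed %% 4)])
    parent <- stats::setNames((seed + seq_along(parent_nodes)) %% 2L,
                              parent_nodes)
    sols <- system_solutions(parent, net)
    for (a in sols) {
      for (u in names(parent)) {
        # each coordinate is either held by its own clamp or forced by
        # the rule on every completion of the unassigned inputs
        if (u %in% names(a)) {
          expect_equal(a[[u]], parent[[u]])
          next
        }
        vars <- net$rules[[u]]$inputs
        full <- as.matrix(expand.grid(rep(list(0:1), length(vars))))
        colnames(full) <- vars
        rows <- rep(TRUE, nrow(full))
        for (v in intersect(vars, names(a))) rows <- rows & (full[, v] == a[[v]])
        outs <- oracle_rule_outputs(net, u, full)
        expect_true(all(outs[rows] == parent[[u]]))
      }
    }
  }
})

test_that("the in-degree bound is enforced", {
  big <- parse_logic_model(paste0("T, ", paste0("X", 1:18, collapse = " & ")))
  expect_error(forcing_solutions(big$rules$T, 0, max_indegree = 16),
               "exceeds the truth-table bound")
})
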