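# Parsing, serialization, synchronous dynamics and attractors.

test_that("logic model parsing handles both line styles and input nodes", {
  net1 <- parse_logic_model(c("P, C & E", "A* = F"))
  expect_s3_class(net1, "boolean_network")
  expect_setequal(net1$inputs, c("C", "E", "F"))
  expect_equal(net1$rules$P$inputs, c("C", "E"))
  expect_equal(net1$rules$A$inputs, "F")

  # self-loop rule: a node is its own sole input
  net2 <- parse_logic_model("X, X")
  expect_equal(net2$rules$X$inputs, "X")
  expect_length(net2$inputs, 0)
})

test_that("parse errors carry line numbers and reject duplicates/operators", {
  expect_error(parse_logic_model(c("A, B", "A, C")), "line 2.*duplicate")
  expect_error(parse_logic_model(c("# ok", "", "A, B + C")),
               "line 3.*undeclared operator")
  expect_error(parse_logic_model("A, B & ("), "line 1")
  expect_error(parse_logic_model("just_a_word"), "expected")
})

test_that("serialization round-trips the packaged example model", {
  net <- example_network()
  lines <- write_logic_model(net)
  again <- parse_logic_model(lines)
  expect_equal(write_logic_model(again), lines)
  expect_equal(again$nodes, net$nodes)
  # canonical text is stable under a second round trip of arbitrary input
  tricky <- parse_logic_model("Z, !(A | B) & (C | !D)")
  expect_equal(write_logic_model(parse_logic_model(write_logic_model(tricky))),
               write_logic_model(tricky))
})

test_that("synchronous_step follows the example rules and fixes attractor points", {
  net <- example_network()
  s <- stats::setNames(rep(0L, 7), net$nodes)
  s[c("C", "E")] <- 1L
  expect_equal(synchronous_step(net, s)[["P"]], 1L)
  s["C"] <- 0L
  expect_equal(synchronous_step(net, s)[["P"]], 0L)  # AND with 0
  fp <- stats::setNames(c(1L, 0L, 1L, 1L, 1L, 1L, 1L), net$nodes)
  expect_equal(synchronous_step(net, fp), fp)
})

test_that("synchronous_step is deterministic over many random net/state pairs", {
  for (seed in 1:20) {
    net <- random_network(8, family = if (seed %% 2) "nested" else "threshold",
                          seed = seed)
    states <- matrix(stats::rbinom(50 * 8, 1, 0.5), ncol = 8)
    for (ri in seq_len(nrow(states))) {
      s <- stats::setNames(states[ri, ], net$nodes)
      expect_identical(synchronous_step(net, s), synchronous_step(net, s))
    }
  }
})

test_that("threshold parsing, tie policies and the two-row example", {
  df <- data.frame(source = "A", target = "B", weight = 1)
  net <- parse_threshold_model(df)
  s <- c(A = 1L, B = 0L)
  expect_equal(synchronous_step(net, s)[["B"]], 1L)
  expect_equal(synchronous_step(net, c(A = 0L, B = 1L))[["B"]], 0L)

  df2 <- data.frame(source = c("A", "B"), target = "C", weight = c(1, -1))
  net2 <- parse_threshold_model(df2)
  # sum exactly zero, policy "zero" -> 0
  expect_equal(synchronous_step(net2, c(A = 1L, B = 1L, C = 1L))[["C"]], 0L)
  net2r <- parse_threshold_model(df2, tie_policy = "retain")
  expect_equal(synchronous_step(net2r, c(A = 1L, B = 1L, C = 1L))[["C"]], 1L)

  expect_error(parse_threshold_model(data.frame(source = "A", target = "B",
                                                weight = 0)), "zero weight")
  expect_error(parse_threshold_model(df, tie_policy = "coin"))
})

test_that("threshold CSV round-trips through write_threshold_model", {
  net <- random_network(7, family = "threshold", seed = 11)
  path <- withr::local_tempfile(fileext = ".csv")
  write_threshold_model(net, path)
  again <- parse_threshold_model(path)
  expect_equal(write_threshold_model(again), write_threshold_model(net))
})

test_that("apply_control clamps permanently, merges idempotently, rejects conflicts", {
  net <- example_network()
  c0 <- apply_control(net, c(C = 0))
  s <- stats::setNames(rep(1L, 7), net$nodes)
  expect_equal(synchronous_step(c0, s)[["C"]], 0L)
  # original untouched, empty control is identity
  expect_length(net$clamps, 0)
  expect_equal(apply_control(net, integer(0))$clamps, net$clamps)
  # idempotent duplicate merge
  expect_equal(apply_control(net, c(A = 0, A = 0))$clamps, c(A = 0L))
  expect_error(apply_control(c0, c(C = 1)), "conflicting clamp")
  expect_error(apply_control(net, c(ZZ = 1)), "unknown nodes")
})

test_that("negation oscillator yields one cyclic attractor of length 2", {
  net <- parse_logic_model("P, !P")
  atts <- find_attractors(net)
  expect_length(atts$attractors, 1)
  expect_equal(atts$attractors[[1]]$kind, "cyclic")
  expect_equal(nrow(atts$attractors[[1]]$states), 2)
})

test_that("every attractor is closed under the synchronous transition", {
  for (seed in c(3, 7, 21)) {
    net <- random_network(9, family = "nested", seed = seed)
    atts <- find_attractors(net)
    for (a in atts$attractors) {
      for (ri in seq_len(nrow(a$states))) {
        nxt <- synchronous_step(net, a$states[ri, ])
        succ_row <- if (ri == nrow(a$states)) 1L else ri + 1L
        expect_equal(unname(nxt), unname(a$states[succ_row, ]))
      }
    }
  }
})

test_that("exhaustive attractors match the state-transition-graph oracle", {
  for (seed in c(2, 5, 13, 28)) {
    net <- random_network(8, family = if (seed %% 2) "nested" else "table",
                          seed = seed)
    atts <- find_attractors(net)
    got <- lapply(atts$attractors, function(a) sort(a$codes))
    expect_equal(got[order(vapply(got, `[`, numeric(1), 1L))],
                 oracle_attractor_states(net))
  }
})

test_that("deep sampling agrees with exhaustive enumeration on small nets", {
  for (seed in c(4, 9)) {
    net <- random_network(8, family = "nested", seed = seed)
    ex <- find_attractors(net)
    sm <- find_attractors(net, method = "sampled", n_init = 4096, seed = 99)
    key <- function(atts) sort(vapply(atts$attractors, function(a) {
      paste(a$codes, collapse = " ")
    }, character(1)))
    expect_equal(key(sm), key(ex))
  }
})

test_that("exhaustive search refuses above the free-node bound and loose inputs", {
  net <- random_network(8, seed = 1)
  expect_error(find_attractors(net, max_free = 5), "exceeds the bound")
  withinput <- parse_logic_model("P, A & B")
  expect_error(find_attractors(withinput), "input nodes must be fixed")
  expect_error(find_attractors(net, method = "sampled"), "explicit seed")
})
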