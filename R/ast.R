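# Logic-expression ASTs for Boolean update rules.
#
# Grammar (precedence low to high):  expr := term ('|' term)* ;
# term := factor ('&' factor)* ; factor := '!' factor | '(' expr ')' |
# name | '0' | '1'.  Node names may contain any character except the
# operator/grouping characters, commas and whitespace, so identifiers such
# as "MEK1_2" or "CHK1/2" are legal.

ast_var <- function(name) list(type = "var", name = name)
ast_const <- function(value) list(type = "const", value = as.integer(value))
ast_not <- function(arg) list(type = "not", arg = arg)
ast_and <- function(args) list(type = "and", args = args)
ast_or <- function(args) list(type = "or", args = args)

tokenize_expr <- function(text) {
  tokens <- list()
  i <- 1L
  n <- nchar(text)
  while (i <= n) {
    ch <- substr(text, i, i)
    if (grepl("^\\s$", ch)) {
      i <- i + 1L
    } else if (ch %in% c("&", "|", "!", "(", ")")) {
      tokens[[length(tokens) + 1L]] <- list(kind = ch)
      i <- i + 1L
    } else if (ch == ",") {
      stop("unexpected ',' inside expression: ", text, call. = FALSE)
    } else {
      j <- i
      while (j <= n && !grepl("^[\\s&|!(),]$", substr(text, j, j), perl = TRUE)) {
        j <- j + 1L
      }
      word <- substr(text, i, j - 1L)
      if (grepl("[+*=<>~^-]", word)) {
        stop("undeclared operator in '", word, "'; only &, |, ! are supported",
             call. = FALSE)
      }
      tokens[[length(tokens) + 1L]] <- list(kind = "name", value = word)
      i <- j
    }
  }
  tokens
}

parse_expression <- function(text) {
  tokens <- tokenize_expr(text)
  if (length(tokens) == 0L) stop("empty expression", call. = FALSE)
  pos <- 1L

  peek <- function() if (pos <= length(tokens)) tokens[[pos]]$kind else NA_character_
  advance <- function() {
    tok <- tokens[[pos]]
    pos <<- pos + 1L
    tok
  }

  parse_or <- function() {
    args <- list(parse_and())
    while (identical(peek(), "|")) {
      advance()
      args[[length(args) + 1L]] <- parse_and()
    }
    if (length(args) == 1L) args[[1L]] else ast_or(args)
  }
  parse_and <- function() {
    args <- list(parse_factor())
    while (identical(peek(), "&")) {
      advance()
      args[[length(args) + 1L]] <- parse_factor()
    }
    if (length(args) == 1L) args[[1L]] else ast_and(args)
  }
  parse_factor <- function() {
    kind <- peek()
    if (is.na(kind)) stop("unexpected end of expression: ", text, call. = FALSE)
    if (kind == "!") {
      advance()
      return(ast_not(parse_factor()))
    }
    if (kind == "(") {
      advance()
      e <- parse_or()
      if (!identical(peek(), ")")) stop("missing ')' in: ", text, call. = FALSE)
      advance()
      return(e)
    }
    if (kind == "name") {
      tok <- advance()
      if (tok$value %in% c("0", "1")) return(ast_const(tok$value))
      return(ast_var(tok$value))
    }
    stop("unexpected '", kind, "' in: ", text, call. = FALSE)
  }

  out <- parse_or()
  if (pos <= length(tokens)) {
    stop("trailing tokens after expression: ", text, call. = FALSE)
  }
  out
}

# Variables of an expression, in order of first appearance.
expr_vars <- function(e) {
  switch(e$type,
    var = e$name,
    const = character(0),
    not = expr_vars(e$arg),
    unique(unlist(lapply(e$args, expr_vars), use.names = FALSE)))
}

# Vectorised evaluation; `vals` is a named list of equal-length integer
# vectors, `nstates` the common length (needed for constants).
eval_ast <- function(e, vals, nstates) {
  switch(e$type,
    var = {
      v <- vals[[e$name]]
      if (is.null(v)) stop("no value supplied for node '", e$name, "'", call. = FALSE)
      v
    },
    const = rep.int(e$value, nstates),
    not = 1L - eval_ast(e$arg, vals, nstates),
    and = {
      acc <- eval_ast(e$args[[1L]], vals, nstates)
      for (a in e$args[-1L]) acc <- acc * eval_ast(a, vals, nstates)
      acc
    },
    or = {
      acc <- eval_ast(e$args[[1L]], vals, nstates)
      for (a in e$args[-1L]) {
        acc <- acc + eval_ast(a, vals, nstates)
      }
      as.integer(acc > 0L)
    })
}

# Substitute known constants (named 0/1 vector) and fold: AND with 0 -> 0,
# OR with 1 -> 1, NOT of constant, and single-argument collapse.
fold_ast <- function(e, known) {
  switch(e$type,
    var = {
      if (e$name %in% names(known)) ast_const(known[[e$name]]) else e
    },
    const = e,
    not = {
      a <- fold_ast(e$arg, known)
      if (a$type == "const") ast_const(1L - a$value) else ast_not(a)
    },
    and = {
      args <- lapply(e$args, fold_ast, known = known)
      kept <- list()
      for (a in args) {
        if (a$type == "const") {
          if (a$value == 0L) return(ast_const(0L))
        } else {
          kept[[length(kept) + 1L]] <- a
        }
      }
      if (length(kept) == 0L) return(ast_const(1L))
      if (length(kept) == 1L) return(kept[[1L]])
      ast_and(kept)
    },
    or = {
      args <- lapply(e$args, fold_ast, known = known)
      kept <- list()
      for (a in args) {
        if (a$type == "const") {
          if (a$value == 1L) return(ast_const(1L))
        } else {
          kept[[length(kept) + 1L]] <- a
        }
      }
      if (length(kept) == 0L) return(ast_const(0L))
      if (length(kept) == 1L) return(kept[[1L]])
      ast_or(kept)
    })
}

# Canonical text form: '&' binds tighter than '|'; '!' applied to a
# compound gets parentheses.
format_ast <- function(e, parent = "or") {
  out <- switch(e$type,
    var = e$name,
    const = as.character(e$value),
    not = {
      inner <- format_ast(e$arg, parent = "atom")
      if (e$arg$type %in% c("and", "or")) paste0("!(", inner, ")") else paste0("!", inner)
    },
    and = paste(vapply(e$args, format_ast, character(1), parent = "and"),
                collapse = " & "),
    or = paste(vapply(e$args, format_ast, character(1), parent = "or"),
               collapse = " | "))
  if (e$type == "or" && parent == "and") paste0("(", out, ")") else out
}
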