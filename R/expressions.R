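# Rate-expression grammar: Boolean operators (!, &, |), the ternary
# `cond ? a : b`, arithmetic (+ - * /), numeric literals, $-prefixed
# parameters, and node identifiers (valued 0/1 in arithmetic context).
# Update rules additionally allow p(<boolean expression>), the
# population-averaged probability of a state predicate.
#
# Expressions are kept as ASTs (nested lists with a `kind` field); the same
# AST feeds the R evaluator (reference path and oracle), the canonical
# deparser, and the bytecode compiler for the C++ kernel.

BP_TOKEN_RE <- paste0(
  "^(?:",
  "(?<ws>\\s+)|",
  "(?<num>(?:[0-9]+\\.?[0-9]*|\\.[0-9]+)(?:[eE][+-]?[0-9]+)?)|",
  "(?<param>\\$[A-Za-z_][A-Za-z0-9_]*)|",
  "(?<ident>[A-Za-z_][A-Za-z0-9_]*)|",
  "(?<op>\\?|:|\\(|\\)|!|&&|&|\\|\\||\\||\\+|-|\\*|/)",
  ")"
)

bp_tokenize <- function(text) {
  tokens <- list()
  pos <- 1L
  n <- nchar(text)
  col <- 1L
  while (pos <= n) {
    rest <- substr(text, pos, n)
    m <- regexpr(BP_TOKEN_RE, rest, perl = TRUE)
    if (m == -1L) {
      stop(sprintf("parse error: unexpected character '%s' at position %d in \"%s\"",
                   substr(rest, 1, 1), col, text), call. = FALSE)
    }
    starts <- attr(m, "capture.start")[1, ]
    lens <- attr(m, "capture.length")[1, ]
    hit <- which(lens > 0 & starts > 0)[1]
    type <- names(starts)[hit]
    value <- substr(rest, starts[hit], starts[hit] + lens[hit] - 1L)
    if (type != "ws") {
      # normalize && / || to single-character forms
      if (value == "&&") value <- "&"
      if (value == "||") value <- "|"
      tokens[[length(tokens) + 1L]] <- list(type = type, value = value, col = col)
    }
    taken <- attr(m, "match.length")
    pos <- pos + taken
    col <- col + taken
  }
  tokens
}

# --- recursive-descent parser ------------------------------------------------
# precedence (low to high): ternary, |, &, + -, * /, unary (! -), primary

bp_parse_expr <- function(text, allow_prob = FALSE) {
  tokens <- bp_tokenize(text)
  st <- new.env(parent = emptyenv())
  st$tokens <- tokens
  st$i <- 1L
  st$text <- text
  st$allow_prob <- allow_prob
  ast <- bp_p_ternary(st)
  if (st$i <= length(st$tokens)) {
    tk <- st$tokens[[st$i]]
    stop(sprintf("parse error: trailing input '%s' at position %d in \"%s\"",
                 tk$value, tk$col, text), call. = FALSE)
  }
  ast
}

bp_peek <- function(st) if (st$i <= length(st$tokens)) st$tokens[[st$i]] else NULL
bp_advance <- function(st) { tk <- st$tokens[[st$i]]; st$i <- st$i + 1L; tk }
bp_expect <- function(st, value) {
  tk <- bp_peek(st)
  if (is.null(tk) || tk$value != value) {
    stop(sprintf("parse error: expected '%s' %s in \"%s\"", value,
                 if (is.null(tk)) "but input ended" else sprintf("at position %d", tk$col),
                 st$text), call. = FALSE)
  }
  bp_advance(st)
}

bp_p_ternary <- function(st) {
  cond <- bp_p_or(st)
  tk <- bp_peek(st)
  if (!is.null(tk) && tk$value == "?") {
    bp_advance(st)
    yes <- bp_p_ternary(st)
    bp_expect(st, ":")
    no <- bp_p_ternary(st)
    return(list(kind = "tern", cond = cond, yes = yes, no = no))
  }
  cond
}

bp_p_or <- function(st) {
  left <- bp_p_and(st)
  repeat {
    tk <- bp_peek(st)
    if (is.null(tk) || tk$value != "|") return(left)
    bp_advance(st)
    left <- list(kind = "or", l = left, r = bp_p_and(st))
  }
}

bp_p_and <- function(st) {
  left <- bp_p_add(st)
  repeat {
    tk <- bp_peek(st)
    if (is.null(tk) || tk$value != "&") return(left)
    bp_advance(st)
    left <- list(kind = "and", l = left, r = bp_p_add(st))
  }
}

bp_p_add <- function(st) {
  left <- bp_p_mul(st)
  repeat {
    tk <- bp_peek(st)
    if (is.null(tk) || !(tk$value %in% c("+", "-"))) return(left)
    bp_advance(st)
    right <- bp_p_mul(st)
    left <- list(kind = if (tk$value == "+") "add" else "sub", l = left, r = right)
  }
}

bp_p_mul <- function(st) {
  left <- bp_p_unary(st)
  repeat {
    tk <- bp_peek(st)
    if (is.null(tk) || !(tk$value %in% c("*", "/"))) return(left)
    bp_advance(st)
    right <- bp_p_unary(st)
    left <- list(kind = if (tk$value == "*") "mul" else "div", l = left, r = right)
  }
}

bp_p_unary <- function(st) {
  tk <- bp_peek(st)
  if (is.null(tk)) stop(sprintf("parse error: unexpected end of input in \"%s\"", st$text),
                        call. = FALSE)
  if (tk$value == "!") { bp_advance(st); return(list(kind = "not", x = bp_p_unary(st))) }
  if (tk$value == "-") { bp_advance(st); return(list(kind = "neg", x = bp_p_unary(st))) }
  bp_p_primary(st)
}

bp_p_primary <- function(st) {
  tk <- bp_peek(st)
  if (is.null(tk)) stop(sprintf("parse error: unexpected end of input in \"%s\"", st$text),
                        call. = FALSE)
  if (tk$value == "(") {
    bp_advance(st)
    inner <- bp_p_ternary(st)
    bp_expect(st, ")")
    return(inner)
  }
  if (tk$type == "num") { bp_advance(st); return(list(kind = "num", value = as.numeric(tk$value))) }
  if (tk$type == "param") { bp_advance(st); return(list(kind = "param", name = substring(tk$value, 2))) }
  if (tk$type == "ident") {
    bp_advance(st)
    nxt <- bp_peek(st)
    if (tk$value == "p" && st$allow_prob && !is.null(nxt) && nxt$value == "(") {
      bp_advance(st)
      inner <- bp_p_ternary(st)
      bp_expect(st, ")")
      return(list(kind = "prob", x = inner))
    }
    return(list(kind = "node", name = tk$value))
  }
  stop(sprintf("parse error: unexpected token '%s' at position %d in \"%s\"",
               tk$value, tk$col, st$text), call. = FALSE)
}

# --- symbol collection -------------------------------------------------------

#' @keywords internal
bp_expr_symbols <- function(ast) {
  nodes <- character(0)
  params <- character(0)
  walk <- function(a) {
    switch(a$kind,
      num = NULL,
      param = params <<- c(params, a$name),
      node = nodes <<- c(nodes, a$name),
      not = , neg = , prob = walk(a$x),
      tern = { walk(a$cond); walk(a$yes); walk(a$no) },
      { walk(a$l); walk(a$r) }
    )
    invisible(NULL)
  }
  walk(ast)
  list(nodes = unique(nodes), params = unique(params))
}

# --- evaluation (reference path) ---------------------------------------------

# `state` is a named numeric vector (or matrix column environment) of 0/1 node
# values; `params` a named numeric vector. Values may be vectors of common
# length, so state-predicate evaluation over a particle matrix is vectorized.
bp_eval_expr <- function(ast, state, params, prob_fn = NULL) {
  ev <- function(a) {
    switch(a$kind,
      num = a$value,
      param = {
        v <- params[[a$name]]
        if (is.null(v)) stop(sprintf("undeclared parameter '$%s'", a$name), call. = FALSE)
        v
      },
      node = {
        if (is.matrix(state)) {
          if (!a$name %in% colnames(state)) stop(sprintf("undeclared node '%s'", a$name), call. = FALSE)
          state[, a$name]
        } else {
          v <- state[[a$name]]
          if (is.null(v)) stop(sprintf("undeclared node '%s'", a$name), call. = FALSE)
          v
        }
      },
      not = as.numeric(ev(a$x) == 0),
      neg = -ev(a$x),
      and = as.numeric(ev(a$l) != 0 & ev(a$r) != 0),
      or = as.numeric(ev(a$l) != 0 | ev(a$r) != 0),
      add = ev(a$l) + ev(a$r),
      sub = ev(a$l) - ev(a$r),
      mul = ev(a$l) * ev(a$r),
      div = ev(a$l) / ev(a$r),
      tern = {
        c0 <- ev(a$cond)
        y <- ev(a$yes)
        n <- ev(a$no)
        out <- ifelse(c0 != 0, y, n)
        if (length(c0) == 1L) out[[1]] else out
      },
      prob = {
        if (is.null(prob_fn)) stop("p(...) is only allowed in population update rules", call. = FALSE)
        prob_fn(a$x)
      },
      stop(sprintf("unknown AST kind '%s'", a$kind), call. = FALSE)
    )
  }
  ev(ast)
}

# --- canonical deparser ------------------------------------------------------

bp_deparse_expr <- function(ast) {
  # precedence levels used to decide parenthesization
  prec <- function(a) switch(a$kind,
    tern = 1, or = 2, and = 3, add = 4, sub = 4, mul = 5, div = 5,
    not = 6, neg = 6, 7)
  dp <- function(a) {
    wrap <- function(child, p) {
      s <- dp(child)
      if (prec(child) < p) paste0("(", s, ")") else s
    }
    switch(a$kind,
      num = format(a$value, digits = 15, scientific = FALSE, trim = TRUE),
      param = paste0("$", a$name),
      node = a$name,
      not = paste0("!", wrap(a$x, 6)),
      neg = paste0("-", wrap(a$x, 6)),
      and = paste0(wrap(a$l, 3), " & ", wrap(a$r, 4)),
      or = paste0(wrap(a$l, 2), " | ", wrap(a$r, 3)),
      add = paste0(wrap(a$l, 4), " + ", wrap(a$r, 5)),
      sub = paste0(wrap(a$l, 4), " - ", wrap(a$r, 5)),
      mul = paste0(wrap(a$l, 5), " * ", wrap(a$r, 6)),
      div = paste0(wrap(a$l, 5), " / ", wrap(a$r, 6)),
      tern = paste0(wrap(a$cond, 2), " ? ", wrap(a$yes, 2), " : ", wrap(a$no, 1)),
      prob = paste0("p(", dp(a$x), ")")
    )
  }
  dp(ast)
}

# --- bytecode compiler for the C++ kernel ------------------------------------
# opcodes: 0 CONST  1 PARAM  2 NODE  3 NOT  4 AND  5 OR  6 ADD  7 SUB
#          8 MUL    9 DIV   10 NEG  11 TERN (pops no, yes, cond)

bp_compile_expr <- function(ast, node_index, param_index) {
  ops <- integer(0)
  args <- integer(0)
  consts <- numeric(0)
  emit <- function(op, arg = 0L) {
    ops <<- c(ops, op)
    args <<- c(args, arg)
  }
  walk <- function(a) {
    switch(a$kind,
      num = { consts <<- c(consts, a$value); emit(0L, length(consts) - 1L) },
      param = {
        idx <- param_index[[a$name]]
        if (is.null(idx)) stop(sprintf("undeclared parameter '$%s'", a$name), call. = FALSE)
        emit(1L, idx - 1L)
      },
      node = {
        idx <- node_index[[a$name]]
        if (is.null(idx)) stop(sprintf("undeclared node '%s'", a$name), call. = FALSE)
        emit(2L, idx - 1L)
      },
      not = { walk(a$x); emit(3L) },
      neg = { walk(a$x); emit(10L) },
      and = { walk(a$l); walk(a$r); emit(4L) },
      or = { walk(a$l); walk(a$r); emit(5L) },
      add = { walk(a$l); walk(a$r); emit(6L) },
      sub = { walk(a$l); walk(a$r); emit(7L) },
      mul = { walk(a$l); walk(a$r); emit(8L) },
      div = { walk(a$l); walk(a$r); emit(9L) },
      tern = { walk(a$cond); walk(a$yes); walk(a$no); emit(11L) },
      prob = stop("p(...) cannot appear in a transition-rate expression", call. = FALSE)
    )
    invisible(NULL)
  }
  walk(ast)
  list(ops = ops, args = args, consts = consts)
}

# Accept either an already-parsed AST or a string.
bp_as_ast <- function(x, allow_prob = FALSE) {
  if (is.character(x)) bp_parse_expr(x, allow_prob = allow_prob)
  else if (is.numeric(x) && length(x) == 1L) list(kind = "num", value = as.numeric(x))
  else x
}
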