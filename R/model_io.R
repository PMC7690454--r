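# Three-file model dialect.
#
# bnd — node logic and transition rates:
#     node CALR {
#       rate_up = DyingTumorCell ? $u_CALR : 0;
#       rate_down = $d_CALR;
#     }
#
# cfg — parameter values, initial condition, simulation settings:
#     $u_CALR = 0.25;
#     init 0.8 : TumorCell = 1, ChemoT = 1;
#     init 0.1 : DC = 1, CALR = *;     // '*' = wildcard, mass spread evenly
#     set time_step = 2;
#
# upp — population features:
#     death Death;
#     division Division;
#     update $ATP_pop = p(ATP);
#
# '//' starts a comment. Nodes not mentioned in an init pattern are 0.

#' Parse a model from bnd/cfg/upp texts
#'
#' @param bnd_text,cfg_text Character scalars (or character vectors of lines)
#'   with the node definitions and the configuration.
#' @param upp_text Optional population file; when absent the model has no
#'   Death/Division nodes and no update rules.
#' @return A list with `network` ([bp_network()]), `initial`
#'   ([bp_initial_condition()]) and `settings` (named numeric vector).
#' @export
parse_model <- function(bnd_text, cfg_text, upp_text = NULL) {
  bnd <- bp_parse_bnd(bnd_text)
  cfg <- bp_parse_cfg(cfg_text)
  upp <- if (is.null(upp_text)) list(death = NULL, division = NULL, rules = list())
         else bp_parse_upp(upp_text)

  nodes <- lapply(bnd, function(b) bp_node(b$name, b$rate_up, b$rate_down))
  net <- bp_network(nodes, params = cfg$params, death = upp$death,
                    division = upp$division, update_rules = upp$rules)
  init <- bp_initial_condition(cfg$init)
  for (a in cfg$init) {
    bad <- setdiff(names(a$pattern), names(net$nodes))
    if (length(bad))
      stop(sprintf("initial condition references undeclared node '%s'", bad[1]),
           call. = FALSE)
  }
  list(network = net, initial = init, settings = cfg$settings)
}

bp_split_lines <- function(text) {
  if (length(text) > 1L) text <- paste(text, collapse = "\n")
  lines <- strsplit(text, "\n", fixed = TRUE)[[1]]
  sub("//.*$", "", lines)
}

bp_parse_bnd <- function(text) {
  lines <- bp_split_lines(text)
  out <- list()
  i <- 1L
  n <- length(lines)
  while (i <= n) {
    ln <- trimws(lines[i])
    if (ln == "") { i <- i + 1L; next }
    m <- regmatches(ln, regexec("^node\\s+([A-Za-z_][A-Za-z0-9_]*)\\s*\\{\\s*$", ln))[[1]]
    if (!length(m))
      stop(sprintf("bnd parse error at line %d: expected 'node <name> {', got \"%s\"",
                   i, ln), call. = FALSE)
    nm <- m[2]
    spec <- list(name = nm, rate_up = NULL, rate_down = NULL)
    i <- i + 1L
    repeat {
      if (i > n) stop(sprintf("bnd parse error: unterminated block for node '%s'", nm),
                      call. = FALSE)
      ln <- trimws(lines[i])
      if (ln == "") { i <- i + 1L; next }
      if (ln == "}") { i <- i + 1L; break }
      m2 <- regmatches(ln, regexec("^(rate_up|rate_down)\\s*=\\s*(.*);\\s*$", ln))[[1]]
      if (!length(m2))
        stop(sprintf("bnd parse error at line %d (node '%s'): \"%s\"", i, nm, ln),
             call. = FALSE)
      ast <- tryCatch(bp_parse_expr(m2[3]),
                      error = function(e) stop(sprintf("bnd line %d: %s", i,
                                                       conditionMessage(e)), call. = FALSE))
      spec[[m2[2]]] <- ast
      i <- i + 1L
    }
    if (is.null(spec$rate_up)) spec$rate_up <- list(kind = "num", value = 0)
    if (is.null(spec$rate_down)) spec$rate_down <- list(kind = "num", value = 0)
    out[[nm]] <- spec
  }
  if (!length(out)) stop("bnd parse error: no node definitions found", call. = FALSE)
  out
}

bp_parse_cfg <- function(text) {
  lines <- bp_split_lines(text)
  params <- numeric(0)
  init <- list()
  settings <- numeric(0)
  for (i in seq_along(lines)) {
    ln <- trimws(lines[i])
    if (ln == "") next
    if (grepl("^\\$", ln)) {
      m <- regmatches(ln, regexec("^\\$([A-Za-z_][A-Za-z0-9_]*)\\s*=\\s*([-0-9.eE+]+)\\s*;\\s*$", ln))[[1]]
      if (!length(m))
        stop(sprintf("cfg parse error at line %d: \"%s\"", i, ln), call. = FALSE)
      v <- as.numeric(m[3])
      if (is.na(v)) stop(sprintf("cfg line %d: invalid number", i), call. = FALSE)
      if (v < 0) stop(sprintf("cfg line %d: parameter '$%s' is negative", i, m[2]),
                      call. = FALSE)
      params[m[2]] <- v
    } else if (grepl("^init\\b", ln)) {
      m <- regmatches(ln, regexec("^init\\s+([0-9.eE+-]+)\\s*:\\s*(.*);\\s*$", ln))[[1]]
      if (!length(m))
        stop(sprintf("cfg parse error at line %d: \"%s\"", i, ln), call. = FALSE)
      prob <- as.numeric(m[2])
      pat_txt <- trimws(m[3])
      pattern <- integer(0)
      if (pat_txt != "" && pat_txt != "-") {
        parts <- trimws(strsplit(pat_txt, ",", fixed = TRUE)[[1]])
        pattern <- stats::setNames(rep(NA_integer_, length(parts)), rep("", length(parts)))
        for (k in seq_along(parts)) {
          pm <- regmatches(parts[k], regexec("^([A-Za-z_][A-Za-z0-9_]*)\\s*=\\s*([01*])$", parts[k]))[[1]]
          if (!length(pm))
            stop(sprintf("cfg line %d: bad pattern component \"%s\"", i, parts[k]),
                 call. = FALSE)
          names(pattern)[k] <- pm[2]
          pattern[k] <- if (pm[3] == "*") NA_integer_ else as.integer(pm[3])
        }
      }
      init[[length(init) + 1L]] <- list(prob = prob, pattern = pattern)
    } else if (grepl("^set\\b", ln)) {
      m <- regmatches(ln, regexec("^set\\s+([A-Za-z_][A-Za-z0-9_]*)\\s*=\\s*([-0-9.eE+]+)\\s*;\\s*$", ln))[[1]]
      if (!length(m))
        stop(sprintf("cfg parse error at line %d: \"%s\"", i, ln), call. = FALSE)
      settings[m[2]] <- as.numeric(m[3])
    } else {
      stop(sprintf("cfg parse error at line %d: \"%s\"", i, ln), call. = FALSE)
    }
  }
  if (!length(init))
    init <- list(list(prob = 1, pattern = integer(0)))
  list(params = params, init = init, settings = settings)
}

bp_parse_upp <- function(text) {
  lines <- bp_split_lines(text)
  death <- NULL
  division <- NULL
  rules <- list()
  for (i in seq_along(lines)) {
    ln <- trimws(lines[i])
    if (ln == "") next
    if (grepl("^death\\b", ln)) {
      m <- regmatches(ln, regexec("^death\\s+([A-Za-z_][A-Za-z0-9_]*)\\s*;\\s*$", ln))[[1]]
      if (!length(m)) stop(sprintf("upp parse error at line %d: \"%s\"", i, ln), call. = FALSE)
      death <- m[2]
    } else if (grepl("^division\\b", ln)) {
      m <- regmatches(ln, regexec("^division\\s+([A-Za-z_][A-Za-z0-9_]*)\\s*;\\s*$", ln))[[1]]
      if (!length(m)) stop(sprintf("upp parse error at line %d: \"%s\"", i, ln), call. = FALSE)
      division <- m[2]
    } else if (grepl("^update\\b", ln)) {
      m <- regmatches(ln, regexec("^update\\s+\\$([A-Za-z_][A-Za-z0-9_]*)\\s*=\\s*(.*);\\s*$", ln))[[1]]
      if (!length(m)) stop(sprintf("upp parse error at line %d: \"%s\"", i, ln), call. = FALSE)
      rules[[m[2]]] <- tryCatch(bp_parse_expr(m[3], allow_prob = TRUE),
                                error = function(e) stop(sprintf("upp line %d: %s", i,
                                                                 conditionMessage(e)),
                                                         call. = FALSE))
    } else {
      stop(sprintf("upp parse error at line %d: \"%s\"", i, ln), call. = FALSE)
    }
  }
  list(death = death, division = division, rules = rules)
}

#' Write a model to bnd/cfg/upp texts
#'
#' The writer is canonical: nodes are written in alphabetical order,
#' parameters and update rules sorted by name, so the output is a
#' deterministic function of the model's content.
#' `parse_model(write_model(x))` is semantically identical to `x`.
#'
#' @param net A [bp_network()].
#' @param initial A [bp_initial_condition()].
#' @param settings Named numeric vector of simulation settings.
#' @return A list with `bnd`, `cfg` and (if the model has population
#'   features) `upp` character scalars.
#' @export
write_model <- function(net, initial = NULL, settings = numeric(0)) {
  ord <- order(names(net$nodes))
  bnd <- character(0)
  for (nd in net$nodes[ord]) {
    bnd <- c(bnd, sprintf("node %s {", nd$name),
             sprintf("  rate_up = %s;", bp_deparse_expr(nd$rate_up)),
             sprintf("  rate_down = %s;", bp_deparse_expr(nd$rate_down)),
             "}", "")
  }
  cfg <- character(0)
  for (pn in sort(names(net$params)))
    cfg <- c(cfg, sprintf("$%s = %s;", pn,
                          format(net$params[[pn]], digits = 15, scientific = FALSE)))
  if (!is.null(initial)) {
    for (a in initial$atoms) {
      pat <- a$pattern
      body <- if (length(pat)) {
        o <- order(names(pat))
        paste(sprintf("%s = %s", names(pat)[o],
                      ifelse(is.na(pat[o]), "*", as.character(pat[o]))),
              collapse = ", ")
      } else "-"
      cfg <- c(cfg, sprintf("init %s : %s;",
                            format(a$prob, digits = 15, scientific = FALSE), body))
    }
  }
  for (sn in sort(names(settings)))
    cfg <- c(cfg, sprintf("set %s = %s;", sn,
                          format(settings[[sn]], digits = 15, scientific = FALSE)))
  out <- list(bnd = paste(bnd, collapse = "\n"),
              cfg = paste(cfg, collapse = "\n"))
  if (!is.null(net$death_node) || !is.null(net$division_node) ||
      length(net$update_rules)) {
    upp <- character(0)
    if (!is.null(net$death_node)) upp <- c(upp, sprintf("death %s;", net$death_node))
    if (!is.null(net$division_node)) upp <- c(upp, sprintf("division %s;", net$division_node))
    for (rn in sort(names(net$update_rules)))
      upp <- c(upp, sprintf("update $%s = %s;", rn,
                            bp_deparse_expr(net$update_rules[[rn]])))
    out$upp <- paste(upp, collapse = "\n")
  }
  out
}

#' Export a model as a single JSON document
#'
#' @inheritParams write_model
#' @return A JSON string (nodes with expression strings, parameters, update
#'   rules, initial condition, settings).
#' @export
model_to_json <- function(net, initial = NULL, settings = numeric(0)) {
  nodes <- lapply(net$nodes, function(nd)
    list(rate_up = bp_deparse_expr(nd$rate_up),
         rate_down = bp_deparse_expr(nd$rate_down)))
  init <- if (!is.null(initial)) lapply(initial$atoms, function(a)
    list(prob = a$prob,
         pattern = as.list(ifelse(is.na(a$pattern), "*", as.character(a$pattern))) |>
           stats::setNames(names(a$pattern)))) else NULL
  doc <- list(nodes = nodes,
              parameters = as.list(net$params),
              death_node = net$death_node,
              division_node = net$division_node,
              update_rules = lapply(net$update_rules, bp_deparse_expr),
              initial_condition = init,
              settings = as.list(settings))
  jsonlite::toJSON(doc, auto_unbox = TRUE, pretty = TRUE, null = "null", digits = NA)
}

#' Read a model from bnd/cfg/upp files on disk
#' @param bnd,cfg Paths to the bnd and cfg files.
#' @param upp Optional path to the upp file.
#' @return As [parse_model()].
#' @export
read_model <- function(bnd, cfg, upp = NULL) {
  rd <- function(p) paste(readLines(p, warn = FALSE), collapse = "\n")
  parse_model(rd(bnd), rd(cfg), if (!is.null(upp)) rd(upp))
}
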