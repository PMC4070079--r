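# Plain-text network files in a BIF-style dialect:
#
#   // optional comments
#   network <name> { }
#   variable A {
#     type discrete [ 2 ] { no, yes };
#   }
#   probability ( A ) {
#     table 0.7, 0.3;
#   }
#   probability ( B | A ) {
#     ( no ) 0.9, 0.1;
#     ( yes ) 0.2, 0.8;
#   }
#
# The parser accepts arbitrary whitespace and reports the line number of the
# offending token.  Three distinct condition classes are signalled:
#   bnstrength_parse_error      -- malformed syntax
#   bnstrength_undeclared_error -- probability block over undeclared variables
#   bnstrength_arity_error      -- CPT rows/levels inconsistent with declaration

io_error <- function(class, msg, line = NA_integer_) {
  if (!is.na(line))
    msg <- sprintf("line %d: %s", line, msg)
  stop(structure(class = c(class, "error", "condition"),
                 list(message = msg, call = NULL)))
}

tokenize_network_file <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("//.*$", "", lines)
  pat <- "[{}()\\[\\],;|]|[^\\s{}()\\[\\],;|]+"
  toks <- character(0L)
  tlines <- integer(0L)
  for (i in seq_along(lines)) {
    m <- gregexpr(pat, lines[i], perl = TRUE)[[1L]]
    if (m[1L] == -1L) next
    tk <- regmatches(lines[i], list(m))[[1L]]
    toks <- c(toks, tk)
    tlines <- c(tlines, rep(i, length(tk)))
  }
  # an environment, so parser helpers can advance the cursor in place
  list2env(list(tok = toks, line = tlines, pos = 1L))
}

tk_peek <- function(st) if (st$pos > length(st$tok)) NULL else st$tok[st$pos]
tk_line <- function(st) {
  if (st$pos > length(st$tok)) {
    if (length(st$line)) st$line[length(st$line)] else 1L
  } else st$line[st$pos]
}
tk_next <- function(st) {
  if (st$pos > length(st$tok))
    io_error("bnstrength_parse_error", "unexpected end of file", tk_line(st))
  tok <- st$tok[st$pos]
  st$pos <- st$pos + 1L
  tok
}
tk_expect <- function(st, what) {
  tok <- tk_peek(st)
  if (is.null(tok))
    io_error("bnstrength_parse_error",
             sprintf("expected '%s', got end of file", what), tk_line(st))
  if (tok != what)
    io_error("bnstrength_parse_error",
             sprintf("expected '%s', got '%s'", what, tok), tk_line(st))
  st$pos <- st$pos + 1L
  tok
}

parse_number_list <- function(state, terminator = ";") {
  out <- numeric(0L)
  repeat {
    tok <- tk_next(state)
    val <- suppressWarnings(as.numeric(tok))
    if (is.na(val))
      io_error("bnstrength_parse_error",
               sprintf("expected a probability, got '%s'", tok), tk_line(state))
    out <- c(out, val)
    tok <- tk_next(state)
    if (tok == terminator) break
    if (tok != ",")
      io_error("bnstrength_parse_error",
               sprintf("expected ',' or '%s', got '%s'", terminator, tok),
               tk_line(state))
  }
  out
}

parse_name_list <- function(state, terminator = "}") {
  out <- character(0L)
  repeat {
    tok <- tk_next(state)
    if (tok == terminator && length(out)) break
    if (tok %in% c(",", ";", "{", "}", "(", ")"))
      io_error("bnstrength_parse_error",
               sprintf("expected a name, got '%s'", tok), tk_line(state))
    out <- c(out, tok)
    tok <- tk_next(state)
    if (tok == terminator) break
    if (tok != ",")
      io_error("bnstrength_parse_error",
               sprintf("expected ',' or '%s', got '%s'", terminator, tok),
               tk_line(state))
  }
  out
}

#' Read a discrete Bayesian network from a text file
#'
#' Reads the BIF-style dialect written by [write_network()] (see the format
#' sketch in the package sources): a `network` header, one `variable` block
#' per node declaring its discrete levels, and one `probability` block per
#' node giving either a `table` line (no parents) or one row of child
#' probabilities per parenthesised parent configuration.  `//` comments and
#' arbitrary whitespace are accepted.  Parse errors report line numbers and
#' carry one of three condition classes distinguishing malformed syntax,
#' undeclared variables and CPT arity mismatches.
#'
#' @param path file path.
#' @return A valid `dbn` object.
#' @export
read_network <- function(path) {
  if (!file.exists(path))
    io_error("bnstrength_parse_error", sprintf("file '%s' not found", path))
  state <- tokenize_network_file(path)
  if (length(state$tok) == 0L)
    io_error("bnstrength_parse_error", "empty network file", 1L)

  variables <- list()
  cpts <- list()
  parents <- list()

  tk_expect(state, "network")
  tk_next(state)                       # network name (unused)
  tk_expect(state, "{")
  while (!is.null(tk_peek(state)) && tk_peek(state) != "}")
    tk_next(state)                     # ignore properties
  tk_expect(state, "}")

  while (!is.null(tk_peek(state))) {
    kw <- tk_next(state)
    if (kw == "variable") {
      vname <- tk_next(state)
      tk_expect(state, "{")
      tk_expect(state, "type")
      tk_expect(state, "discrete")
      tk_expect(state, "[")
      k <- suppressWarnings(as.integer(tk_next(state)))
      if (is.na(k) || k < 2L)
        io_error("bnstrength_parse_error", "level count must be an integer >= 2",
                 tk_line(state))
      tk_expect(state, "]")
      tk_expect(state, "{")
      lv <- parse_name_list(state, terminator = "}")
      tk_expect(state, ";")
      tk_expect(state, "}")
      if (length(lv) != k)
        io_error("bnstrength_arity_error",
                 sprintf("variable '%s': %d levels declared but %d listed",
                         vname, k, length(lv)), tk_line(state))
      variables[[vname]] <- lv
    } else if (kw == "probability") {
      tk_expect(state, "(")
      child <- tk_next(state)
      pa <- character(0L)
      tok <- tk_next(state)
      if (tok == "|") {
        repeat {
          pa <- c(pa, tk_next(state))
          tok <- tk_next(state)
          if (tok == ")") break
          if (tok != ",")
            io_error("bnstrength_parse_error",
                     sprintf("expected ',' or ')', got '%s'", tok),
                     tk_line(state))
        }
      } else if (tok != ")") {
        io_error("bnstrength_parse_error",
                 sprintf("expected '|' or ')', got '%s'", tok), tk_line(state))
      }
      line0 <- tk_line(state)
      for (v in c(child, pa))
        if (!v %in% names(variables))
          io_error("bnstrength_undeclared_error",
                   sprintf("probability block references undeclared variable '%s'",
                           v), line0)
      r <- length(variables[[child]])
      tk_expect(state, "{")
      if (length(pa) == 0L) {
        tk_expect(state, "table")
        probs <- parse_number_list(state)
        if (length(probs) != r)
          io_error("bnstrength_arity_error",
                   sprintf("node '%s': %d probabilities for %d levels",
                           child, length(probs), r), tk_line(state))
        cpts[[child]] <- array(probs, dim = r,
                               dimnames = list(variables[[child]]))
        tk_expect(state, "}")
      } else {
        pdims <- vapply(pa, function(p) length(variables[[p]]), integer(1L))
        q <- prod(pdims)
        cpt <- array(NA_real_, dim = c(r, pdims),
                     dimnames = c(list(variables[[child]]),
                                  variables[pa]))
        m <- matrix(NA_real_, nrow = r, ncol = q)
        seen <- logical(q)
        while (!is.null(tk_peek(state)) && tk_peek(state) == "(") {
          rowline <- tk_line(state)
          tk_expect(state, "(")
          conf <- parse_name_list(state, terminator = ")")
          if (length(conf) != length(pa))
            io_error("bnstrength_arity_error",
                     sprintf("node '%s': parent configuration has %d values, expected %d",
                             child, length(conf), length(pa)), rowline)
          ij <- integer(length(pa))
          for (j in seq_along(pa)) {
            ij[j] <- match(conf[j], variables[[pa[j]]])
            if (is.na(ij[j]))
              io_error("bnstrength_arity_error",
                       sprintf("node '%s': '%s' is not a level of parent '%s'",
                               child, conf[j], pa[j]), rowline)
          }
          col <- 1L + sum((ij - 1L) * cumprod(c(1L, pdims))[seq_along(pa)])
          probs <- parse_number_list(state)
          if (length(probs) != r)
            io_error("bnstrength_arity_error",
                     sprintf("node '%s': %d probabilities for %d levels",
                             child, length(probs), r), rowline)
          if (seen[col])
            io_error("bnstrength_arity_error",
                     sprintf("node '%s': duplicated parent configuration", child),
                     rowline)
          seen[col] <- TRUE
          m[, col] <- probs
        }
        tk_expect(state, "}")
        if (!all(seen))
          io_error("bnstrength_arity_error",
                   sprintf("node '%s': %d of %d parent configurations missing",
                           child, sum(!seen), q), line0)
        cpt[] <- m
        cpts[[child]] <- cpt
      }
      parents[[child]] <- pa
    } else {
      io_error("bnstrength_parse_error",
               sprintf("expected 'variable' or 'probability', got '%s'", kw),
               tk_line(state))
    }
  }

  missing_cpt <- setdiff(names(variables), names(cpts))
  if (length(missing_cpt))
    io_error("bnstrength_parse_error",
             sprintf("no probability block for variable(s): %s",
                     paste(missing_cpt, collapse = ", ")))
  edges <- do.call(rbind, lapply(names(parents), function(v) {
    if (length(parents[[v]])) cbind(parents[[v]], v) else NULL
  }))
  net <- discrete_bn(variables, edges, cpts = NULL, check = FALSE)
  # install CPTs with the parent order of the file, permuted to the node's
  # canonical (declaration-order) parent order
  for (v in names(variables)) {
    file_pa <- parents[[v]]
    cpt <- cpts[[v]]
    if (length(file_pa) > 1L) {
      perm <- c(1L, 1L + match(net[[v]]$parents, file_pa))
      cpt <- aperm(cpt, perm)
    }
    net[[v]]$cpt <- cpt
  }
  assert_valid_network(net)
}

#' Write a discrete Bayesian network to a text file
#'
#' Writes the BIF-style dialect read by [read_network()].  Writing then
#' reading reproduces the network exactly up to CPT round-off below `1e-9`.
#'
#' @param net a valid `dbn` object.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_network <- function(net, path) {
  assert_valid_network(net)
  bad <- grepl("[][}{)(,;|[:space:]]|//", unlist(c(names(net),
                                                   lapply(net, `[[`, "levels"))))
  if (any(bad))
    stop("node or level names contain characters reserved by the file format",
         call. = FALSE)
  out <- c("// discrete Bayesian network", "network net {", "}")
  for (v in names(net)) {
    lv <- net[[v]]$levels
    out <- c(out,
             sprintf("variable %s {", v),
             sprintf("  type discrete [ %d ] { %s };", length(lv),
                     paste(lv, collapse = ", ")),
             "}")
  }
  for (v in names(net)) {
    lv <- net[[v]]$levels
    pa <- net[[v]]$parents
    cpt <- net[[v]]$cpt
    fmt <- function(p) paste(sprintf("%.12g", p), collapse = ", ")
    if (length(pa) == 0L) {
      out <- c(out, sprintf("probability ( %s ) {", v),
               sprintf("  table %s;", fmt(as.numeric(cpt))), "}")
    } else {
      pdims <- vapply(pa, function(p) length(net[[p]]$levels), integer(1L))
      q <- prod(pdims)
      m <- matrix(as.numeric(cpt), nrow = length(lv), ncol = q)
      confs <- expand.grid(lapply(pa, function(p) net[[p]]$levels),
                           stringsAsFactors = FALSE)
      rows <- vapply(seq_len(q), function(j)
        sprintf("  ( %s ) %s;", paste(unlist(confs[j, ]), collapse = ", "),
                fmt(m[, j])), character(1L))
      out <- c(out, sprintf("probability ( %s | %s ) {", v,
                            paste(pa, collapse = ", ")), rows, "}")
    }
  }
  writeLines(out, path)
  invisible(path)
}
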