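#' Graph endpoint
#'
#' A named, queryable RDF graph — the stand-in for a SPARQL endpoint exposing
#' one virtualized store.  `available = FALSE` simulates an unreachable
#' endpoint so the error contract (unavailability vs. empty results) is
#' testable.
#'
#' @param name endpoint name, unique within a federation.
#' @param triples triples data.frame (see [apply_mapping()]).
#' @param available logical fault-injection flag.
#' @return object of class `graph_endpoint`.
#' @export
graph_endpoint <- function(name, triples, available = TRUE) {
  abort_if(!is_string(name) || !nzchar(name), "endpoint name must be a string")
  abort_if(!is.data.frame(triples) ||
             !all(c("subject", "predicate", "object") %in% names(triples)),
           "triples must have subject/predicate/object columns")
  structure(list(name = name, triples = triples,
                 available = isTRUE(available)),
            class = "graph_endpoint")
}

is_var <- function(x) is.character(x) & startsWith(x, "?")

#' Triple pattern
#'
#' Each position is a constant (IRI or literal string) or a variable written
#' `"?name"`.
#'
#' @param s,p,o subject, predicate, object positions.
#' @return list of class `triple_pattern`.
#' @export
triple_pattern <- function(s, p, o) {
  structure(list(s = s, p = p, o = o), class = "triple_pattern")
}

pattern_vars <- function(pattern) {
  v <- unlist(pattern[c("s", "p", "o")])
  sub("^\\?", "", v[is_var(v)])
}

#' Service clause
#'
#' A graph pattern (list of [triple_pattern()]s) evaluated against one named
#' endpoint, plus local equality/inequality filters over this clause's
#' variables — the SERVICE stanza of a federated query.
#'
#' @param endpoint endpoint name.
#' @param patterns list of triple patterns.
#' @param filters list of `list(lhs = "?x", op = "=="|"!=", rhs = "?y"|const)`.
#' @return object of class `service_clause`.
#' @export
service_clause <- function(endpoint, patterns, filters = list()) {
  abort_if(!is_string(endpoint), "endpoint must be a name string")
  abort_if(length(patterns) == 0, "a service clause needs >= 1 pattern")
  patterns <- lapply(patterns, function(p) {
    if (inherits(p, "triple_pattern")) p else do.call(triple_pattern, as.list(p))
  })
  vars <- unique(unlist(lapply(patterns, pattern_vars)))
  for (f in filters) {
    fv <- c(if (is_var(f$lhs)) sub("^\\?", "", f$lhs),
            if (is_var(f$rhs)) sub("^\\?", "", f$rhs))
    bad <- setdiff(fv, vars)
    abort_if(length(bad) > 0,
             "filter variable(s) not bound in clause: ",
             paste(bad, collapse = ", "))
  }
  structure(list(endpoint = endpoint, patterns = patterns, filters = filters),
            class = "service_clause")
}

clause_vars <- function(clause) {
  unique(unlist(lapply(clause$patterns, pattern_vars)))
}

#' Federated query
#'
#' Two or more service clauses joined by cross-clause equality filters, plus
#' selection filters (variable = constant) and a projection.  Variable names
#' must be disjoint across clauses; cross-clause joins are expressed only
#' through `join_filters` (each SERVICE stanza has its own variable scope).
#'
#' @param clauses list of [service_clause()]s (>= 1).
#' @param join_filters list of `list(lhs = "?x", rhs = "?y")` with the two
#'   variables coming from different clauses; values are compared after key
#'   canonicalization (`"0123"` joins `123`).
#' @param selection_filters list of `list(lhs = "?x", op, rhs = constant)`.
#' @param projection character vector of variables (with or without `?`).
#' @return object of class `federated_query`.
#' @export
federated_query <- function(clauses, join_filters = list(),
                            selection_filters = list(), projection) {
  abort_if(length(clauses) == 0, "need >= 1 clause")
  for (cl in clauses) abort_if(!inherits(cl, "service_clause"),
                               "clauses must be service_clause objects")
  var_sets <- lapply(clauses, clause_vars)
  all_vars <- unlist(var_sets)
  abort_if(any(duplicated(all_vars)),
           "variable name(s) shared across clauses: ",
           paste(unique(all_vars[duplicated(all_vars)]), collapse = ", "),
           " (join clauses via join_filters)")
  clause_of <- function(v) which(vapply(var_sets, function(s) v %in% s, logical(1)))[1]
  for (jf in join_filters) {
    l <- sub("^\\?", "", jf$lhs); r <- sub("^\\?", "", jf$rhs)
    abort_if(!l %in% all_vars || !r %in% all_vars,
             "join filter references unbound variable")
    abort_if(length(clauses) > 1 && identical(clause_of(l), clause_of(r)),
             "join filters must reference variables from two distinct clauses")
  }
  projection <- sub("^\\?", "", projection)
  bad <- setdiff(projection, all_vars)
  abort_if(length(bad) > 0,
           "projection of never-bound variable(s): ", paste(bad, collapse = ", "))
  structure(list(clauses = clauses, join_filters = join_filters,
                 selection_filters = selection_filters,
                 projection = projection),
            class = "federated_query")
}

## ---- BGP evaluation --------------------------------------------------------

# Match one triple pattern against a triples table -> bindings data.frame.
match_pattern <- function(triples, pattern) {
  cols <- c(s = "subject", p = "predicate", o = "object")
  keep <- rep(TRUE, nrow(triples))
  for (pos in names(cols)) {
    term <- pattern[[pos]]
    if (!is_var(term)) keep <- keep & (triples[[cols[[pos]]]] == term)
  }
  hits <- triples[keep, , drop = FALSE]
  terms <- vapply(names(cols), function(pos) pattern[[pos]], character(1))
  var_pos <- names(terms)[is_var(terms)]
  var_names <- sub("^\\?", "", terms[var_pos])
  # a variable repeated within one pattern forces equal values
  for (v in unique(var_names[duplicated(var_names)])) {
    pcs <- cols[var_pos[var_names == v]]
    same <- Reduce(`&`, lapply(pcs[-1], function(cc)
      hits[[cc]] == hits[[pcs[[1]]]]))
    hits <- hits[same, , drop = FALSE]
  }
  out <- data.frame(row.names = seq_len(nrow(hits)))
  for (k in seq_along(var_pos)) {
    if (!var_names[k] %in% names(out))
      out[[var_names[k]]] <- hits[[cols[[var_pos[k]]]]]
  }
  out
}

# natural join of two bindings frames on their shared variables (exact match)
natural_join <- function(a, b) {
  if (nrow(a) == 0 || nrow(b) == 0) {
    out <- a[integer(0), , drop = FALSE]
    for (v in setdiff(names(b), names(a))) out[[v]] <- character(0)
    return(out)
  }
  common <- intersect(names(a), names(b))
  if (length(common) == 0) {
    ia <- rep(seq_len(nrow(a)), each = nrow(b))
    ib <- rep(seq_len(nrow(b)), times = nrow(a))
    return(cbind(a[ia, , drop = FALSE],
                 b[ib, , drop = FALSE], row.names = NULL))
  }
  key_a <- do.call(paste, c(a[common], sep = "\r"))
  key_b <- do.call(paste, c(b[common], sep = "\r"))
  idx <- split(seq_len(nrow(b)), key_b)
  matches <- idx[key_a]
  n_each <- vapply(matches, function(m) if (is.null(m)) 0L else length(m),
                   integer(1))
  ia <- rep(seq_len(nrow(a)), times = n_each)
  ib <- unlist(matches[n_each > 0], use.names = FALSE)
  cbind(a[ia, , drop = FALSE],
        b[ib, setdiff(names(b), common), drop = FALSE], row.names = NULL)
}

# Evaluate a basic graph pattern with filters.  Patterns are joined left to
# right; an equality filter between two still-unconnected frames is used as a
# hash-join condition instead of a cross product, and any filter whose
# variables are all bound is applied as early as possible.  Remaining filters
# are applied (and validated) at the end.
eval_bgp <- function(triples, patterns, filters) {
  bindings <- NULL
  pending <- filters
  filter_vars <- function(f) {
    c(if (is_var(f$lhs)) sub("^\\?", "", f$lhs),
      if (is.character(f$rhs) && length(f$rhs) == 1 && is_var(f$rhs))
        sub("^\\?", "", f$rhs))
  }
  for (pattern in patterns) {
    b <- match_pattern(triples, pattern)
    if (is.null(bindings)) {
      bindings <- b
    } else {
      shared <- intersect(names(bindings), names(b))
      joined <- FALSE
      if (length(shared) == 0 && length(pending) > 0) {
        jf_idx <- which(vapply(pending, function(f) {
          v <- filter_vars(f)
          (f$op %||% "==") == "==" && length(v) == 2 &&
            ((v[1] %in% names(bindings) && v[2] %in% names(b)) ||
               (v[2] %in% names(bindings) && v[1] %in% names(b)))
        }, logical(1)))
        if (length(jf_idx) > 0) {
          bindings <- join_bindings(bindings, b, pending[jf_idx])
          pending <- pending[-jf_idx]
          joined <- TRUE
        }
      }
      if (!joined) bindings <- natural_join(bindings, b)
    }
    if (length(pending) > 0) {
      ready <- which(vapply(pending, function(f)
        all(filter_vars(f) %in% names(bindings)), logical(1)))
      if (length(ready) > 0) {
        bindings <- apply_binding_filters(bindings, pending[ready])
        pending <- pending[-ready]
      }
    }
  }
  # anything left must still be checkable (errors on unbound variables)
  apply_binding_filters(bindings, pending)
}

apply_binding_filters <- function(bindings, filters) {
  for (f in filters) {
    op <- f$op %||% "=="
    lhs <- if (is_var(f$lhs)) bindings[[sub("^\\?", "", f$lhs)]] else f$lhs
    rhs <- if (is_var(f$rhs)) bindings[[sub("^\\?", "", f$rhs)]] else f$rhs
    abort_if(is.null(lhs) || is.null(rhs), "filter references unbound variable")
    cmp <- canonical_key(lhs) == canonical_key(rhs)
    keep <- if (op == "==") cmp else if (op == "!=") !cmp else
      stop("unsupported filter operator: ", op, call. = FALSE)
    bindings <- bindings[keep, , drop = FALSE]
  }
  rownames(bindings) <- NULL
  bindings
}

#' Evaluate one service clause against its endpoint
#'
#' Returns every variable binding satisfying the clause's patterns and local
#' filters over the endpoint's graph, with multiset semantics.  An
#' unavailable endpoint raises an error distinct from an empty result.
#'
#' @param endpoints named list of [graph_endpoint()]s.
#' @param clause a [service_clause()].
#' @return bindings data.frame, one column per clause variable.
#' @export
execute_service <- function(endpoints, clause) {
  ep <- endpoints[[clause$endpoint]]
  abort_if(is.null(ep), "unknown endpoint: ", clause$endpoint)
  abort_if(!ep$available,
           "endpoint '", clause$endpoint,
           "' is unavailable (service error, not an empty result)")
  out <- eval_bgp(ep$triples, clause$patterns, clause$filters)
  rownames(out) <- NULL
  out
}

#' Join two binding sets on explicit equality filters
#'
#' Hash equality-join over the stated variable pairs; key values are
#' canonicalized first so that numeric and string representations of the
#' same key compare equal (the two stores type their patient keys
#' differently).  With no filters the result is the cross product.
#'
#' @param a,b bindings data.frames.
#' @param join_filters list of `list(lhs = "?x", rhs = "?y")`.
#' @return bindings data.frame over the union of variables.
#' @export
join_bindings <- function(a, b, join_filters = list()) {
  for (jf in join_filters) {
    l <- sub("^\\?", "", jf$lhs); r <- sub("^\\?", "", jf$rhs)
    abort_if(!(l %in% names(a) || l %in% names(b)) ||
               !(r %in% names(a) || r %in% names(b)),
             "join filter names unbound variable: ", l, " = ", r)
  }
  if (nrow(a) == 0 || nrow(b) == 0) {
    out <- a[integer(0), , drop = FALSE]
    for (v in setdiff(names(b), names(a))) out[[v]] <- character(0)
    return(out)
  }
  # canonical key columns for filters whose sides live in different frames
  lkeys <- character(0); rkeys <- character(0)
  for (jf in join_filters) {
    l <- sub("^\\?", "", jf$lhs); r <- sub("^\\?", "", jf$rhs)
    if (l %in% names(b) && r %in% names(a)) { tmp <- l; l <- r; r <- tmp }
    if (l %in% names(a) && r %in% names(b)) {
      lkeys <- c(lkeys, l); rkeys <- c(rkeys, r)
    }
  }
  if (length(lkeys) == 0) {
    ia <- rep(seq_len(nrow(a)), each = nrow(b))
    ib <- rep(seq_len(nrow(b)), times = nrow(a))
    out <- cbind(a[ia, , drop = FALSE], b[ib, , drop = FALSE],
                 row.names = NULL)
  } else {
    key_a <- do.call(paste, c(lapply(lkeys, function(k) canonical_key(a[[k]])),
                              sep = "\r"))
    key_b <- do.call(paste, c(lapply(rkeys, function(k) canonical_key(b[[k]])),
                              sep = "\r"))
    idx <- split(seq_len(nrow(b)), key_b)
    matches <- idx[key_a]
    n_each <- vapply(matches, function(m) if (is.null(m)) 0L else length(m),
                     integer(1))
    ia <- rep(seq_len(nrow(a)), times = n_each)
    ib <- unlist(matches[n_each > 0], use.names = FALSE)
    out <- cbind(a[ia, , drop = FALSE], b[ib, , drop = FALSE],
                 row.names = NULL)
  }
  # filters fully inside one frame act as selections on the joined result
  leftover <- Filter(function(jf) {
    l <- sub("^\\?", "", jf$lhs); r <- sub("^\\?", "", jf$rhs)
    !any(lkeys == l & rkeys == r) && !any(lkeys == r & rkeys == l)
  }, join_filters)
  apply_binding_filters(out, lapply(leftover, function(jf)
    list(lhs = jf$lhs, op = "==", rhs = jf$rhs)))
}

#' Run a federated query
#'
#' Evaluates every SERVICE clause against its endpoint, joins the per-clause
#' binding sets on the cross-clause equality filters, applies the selection
#' filters, and projects.  The result equals (as a multiset) evaluating the
#' same conjunctive pattern over the union of all endpoint graphs
#' ([run_monolithic()]), which is the federation-transparency contract.
#'
#' @param query a [federated_query()].
#' @param endpoints named list of [graph_endpoint()]s.
#' @return bindings data.frame with the projected variables.
#' @export
run_federated <- function(query, endpoints) {
  abort_if(!inherits(query, "federated_query"), "query must be a federated_query")
  results <- lapply(query$clauses, function(cl) execute_service(endpoints, cl))
  combined <- results[[1]]
  pending <- query$join_filters
  if (length(results) > 1) {
    for (i in 2:length(results)) {
      vars_next <- names(results[[i]])
      app_idx <- which(vapply(pending, function(jf) {
        l <- sub("^\\?", "", jf$lhs); r <- sub("^\\?", "", jf$rhs)
        (l %in% names(combined) && r %in% vars_next) ||
          (r %in% names(combined) && l %in% vars_next)
      }, logical(1)))
      combined <- join_bindings(combined, results[[i]], pending[app_idx])
      if (length(app_idx) > 0) pending <- pending[-app_idx]
    }
  }
  # any joins not yet applied (e.g. both sides arrived via later clauses)
  combined <- apply_binding_filters(combined, lapply(pending, function(jf)
    list(lhs = jf$lhs, op = "==", rhs = jf$rhs)))
  combined <- apply_binding_filters(combined, query$selection_filters)
  miss <- setdiff(query$projection, names(combined))
  abort_if(length(miss) > 0,
           "projection of never-bound variable(s): ", paste(miss, collapse = ", "))
  out <- combined[, query$projection, drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Evaluate a federated query over the merged store
#'
#' The transparency oracle: all clause patterns are evaluated as one
#' conjunctive pattern over the union of every endpoint's triples, then all
#' local, join and selection filters are applied and the projection taken.
#' For filter+join queries (no negation) this must equal [run_federated()].
#'
#' @inheritParams run_federated
#' @return bindings data.frame with the projected variables.
#' @export
run_monolithic <- function(query, endpoints) {
  abort_if(!inherits(query, "federated_query"), "query must be a federated_query")
  union_triples <- do.call(rbind, lapply(endpoints, function(ep)
    ep$triples[, c("subject", "predicate", "object"), drop = FALSE]))
  patterns <- unlist(lapply(query$clauses, `[[`, "patterns"),
                     recursive = FALSE)
  filters <- c(unlist(lapply(query$clauses, `[[`, "filters"),
               recursive = FALSE),
               lapply(query$join_filters, function(jf)
                 list(lhs = jf$lhs, op = "==", rhs = jf$rhs)),
               query$selection_filters)
  bindings <- eval_bgp(union_triples, patterns, filters)
  out <- bindings[, query$projection, drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Human-readable evaluation plan
#'
#' @param query a [federated_query()].
#' @return character vector of plan lines (also printed invisibly-friendly).
#' @export
plan_summary <- function(query) {
  lines <- c(sprintf("federated query: %d clause(s), project [%s]",
                     length(query$clauses),
                     paste(query$projection, collapse = ", ")))
  for (i in seq_along(query$clauses)) {
    cl <- query$clauses[[i]]
    lines <- c(lines, sprintf("  %d. SERVICE %s: %d pattern(s), %d local filter(s)",
                              i, cl$endpoint, length(cl$patterns),
                              length(cl$filters)))
  }
  for (jf in query$join_filters) {
    lines <- c(lines, sprintf("  join: %s = %s", jf$lhs, jf$rhs))
  }
  for (sf in query$selection_filters) {
    lines <- c(lines, sprintf("  select: %s %s %s", sf$lhs, sf$op %||% "==",
                              deparse(sf$rhs)))
  }
  lines
}

## ---- concrete syntax -------------------------------------------------------

tokenize_filter <- function(expr, line_no) {
  m <- regmatches(expr, regexec(
    "^\\(\\s*(\\?[A-Za-z_][A-Za-z0-9_]*)\\s*(=|!=)\\s*(.+?)\\s*\\)$", expr))[[1]]
  abort_if(length(m) == 0, "line ", line_no, ": malformed FILTER: ", expr)
  rhs_tok <- m[4]
  rhs <- if (startsWith(rhs_tok, "?")) rhs_tok else parse_term(rhs_tok)$value
  list(lhs = m[2], op = if (m[3] == "=") "==" else "!=", rhs = rhs)
}

parse_pattern_line <- function(body, line_no) {
  toks <- character(0)
  s <- trimws(body)
  while (nzchar(s)) {
    if (startsWith(s, "?")) {
      m <- regexpr("^\\?[A-Za-z_][A-Za-z0-9_]*", s)
      toks <- c(toks, regmatches(s, m))
      s <- trimws(substr(s, attr(m, "match.length") + 1, nchar(s)))
    } else if (startsWith(s, "<")) {
      m <- regexpr("^<[^>]*>", s)
      abort_if(m == -1, "line ", line_no, ": unterminated IRI in pattern")
      toks <- c(toks, regmatches(s, m))
      s <- trimws(substr(s, attr(m, "match.length") + 1, nchar(s)))
    } else if (startsWith(s, "\"")) {
      m <- regexpr('^"(?:[^"\\\\]|\\\\.)*"(?:\\^\\^<[^>]*>)?', s)
      abort_if(m == -1, "line ", line_no, ": unterminated literal in pattern")
      toks <- c(toks, regmatches(s, m))
      s <- trimws(substr(s, attr(m, "match.length") + 1, nchar(s)))
    } else {
      stop("line ", line_no, ": malformed pattern near: ", s, call. = FALSE)
    }
  }
  abort_if(length(toks) != 3, "line ", line_no, ": pattern needs 3 terms")
  term_of <- function(tok) if (startsWith(tok, "?")) tok else parse_term(tok)$value
  triple_pattern(term_of(toks[1]), term_of(toks[2]), term_of(toks[3]))
}

#' Parse the minimal federated-query concrete syntax
#'
#' A small SPARQL-like dialect covering exactly what the federation evaluator
#' supports: a `SELECT` projection, one or more `SERVICE <name> { ... }`
#' blocks of triple patterns (`.`-terminated) and local `FILTER(?x = ?y)`
#' lines, then top-level `FILTER` lines for cross-clause joins
#' (variable = variable) and selections (variable = constant).
#'
#' @param text character vector of query lines, or a path to a query file.
#' @return a [federated_query()].
#' @export
parse_query <- function(text) {
  if (length(text) == 1 && file.exists(text)) text <- readLines(text)
  lines <- trimws(text)
  projection <- NULL
  clauses <- list()
  join_filters <- list()
  selection_filters <- list()
  i <- 1L
  while (i <= length(lines)) {
    ln <- lines[i]
    if (!nzchar(ln) || startsWith(ln, "#")) { i <- i + 1L; next }
    if (grepl("^SELECT\\b", ln, ignore.case = TRUE)) {
      vars <- regmatches(ln, gregexpr("\\?[A-Za-z_][A-Za-z0-9_]*", ln))[[1]]
      abort_if(length(vars) == 0, "line ", i, ": SELECT lists no variables")
      projection <- sub("^\\?", "", vars)
      i <- i + 1L
    } else if (grepl("^SERVICE\\b", ln, ignore.case = TRUE)) {
      m <- regmatches(ln, regexec("^SERVICE\\s+(\\S+)\\s*\\{\\s*$", ln,
                                  ignore.case = TRUE))[[1]]
      abort_if(length(m) == 0,
               "line ", i, ": expected 'SERVICE <name> {'")
      ep_name <- gsub("^<|>$", "", m[2])
      patterns <- list(); filters <- list()
      i <- i + 1L
      repeat {
        abort_if(i > length(lines), "unterminated SERVICE block (missing '}')")
        bl <- lines[i]
        if (bl == "}") { i <- i + 1L; break }
        if (!nzchar(bl) || startsWith(bl, "#")) { i <- i + 1L; next }
        if (grepl("^FILTER", bl, ignore.case = TRUE)) {
          filters[[length(filters) + 1L]] <-
            tokenize_filter(sub("^FILTER\\s*", "", bl, ignore.case = TRUE), i)
        } else {
          abort_if(!grepl("\\.$", bl),
                   "line ", i, ": pattern must end with '.'")
          patterns[[length(patterns) + 1L]] <-
            parse_pattern_line(sub("\\s*\\.$", "", bl), i)
        }
        i <- i + 1L
      }
      clauses[[length(clauses) + 1L]] <-
        service_clause(ep_name, patterns, filters)
    } else if (grepl("^FILTER", ln, ignore.case = TRUE)) {
      f <- tokenize_filter(sub("^FILTER\\s*", "", ln, ignore.case = TRUE), i)
      if (is.character(f$rhs) && startsWith(f$rhs, "?")) {
        join_filters[[length(join_filters) + 1L]] <- f
      } else {
        selection_filters[[length(selection_filters) + 1L]] <- f
      }
      i <- i + 1L
    } else {
      stop("line ", i, ": cannot parse: ", ln, call. = FALSE)
    }
  }
  abort_if(is.null(projection), "query has no SELECT line")
  federated_query(clauses, join_filters, selection_filters, projection)
}

#' Export a binding set
#'
#' @param bindings bindings data.frame.
#' @param path output path.
#' @param format `"csv"` or `"json"`.
#' @export
write_bindings <- function(bindings, path, format = c("csv", "json")) {
  format <- match.arg(format)
  if (format == "csv") {
    utils::write.csv(bindings, path, row.names = FALSE)
  } else {
    jsonlite::write_json(bindings, path, dataframe = "rows")
  }
  invisible(path)
}
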