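#' Relational table schema
#'
#' Declares the structure a direct mapping is derived from: the table name,
#' typed columns, primary key and foreign keys.  Column datatypes are the
#' three the virtualized stores use: `integer`, `text`, `date`.
#'
#' @param table_name table name (used in subject/class IRIs).
#' @param columns named character vector, `c(colName = "integer", ...)`;
#'   order is the column order and fixes triple emission order.
#' @param primary_key character vector of key column names (non-empty,
#'   subset of columns).
#' @param foreign_keys list of `list(column =, ref_table =, ref_column =)`.
#' @return object of class `table_schema`.
#' @examples
#' gt <- table_schema("genotypes",
#'   c(patientId = "text", rsID = "text", genotype = "text"),
#'   primary_key = c("patientId", "rsID"))
#' @export
table_schema <- function(table_name, columns, primary_key,
                         foreign_keys = list()) {
  abort_if(!is_string(table_name) || !nzchar(table_name),
           "table_name must be a non-empty string")
  abort_if(is.null(names(columns)) || any(!nzchar(names(columns))),
           "columns must be a named character vector")
  abort_if(!all(columns %in% c("integer", "text", "date")),
           "column datatypes must be integer, text or date")
  abort_if(length(primary_key) == 0, "primary_key must be non-empty")
  abort_if(!all(primary_key %in% names(columns)),
           "primary_key columns must be declared columns")
  for (fk in foreign_keys) {
    abort_if(!all(c("column", "ref_table", "ref_column") %in% names(fk)),
             "each foreign key needs column, ref_table, ref_column")
    abort_if(!fk$column %in% names(columns),
             "foreign-key column ", fk$column, " not a declared column")
  }
  structure(list(table_name = table_name, columns = columns,
                 primary_key = primary_key, foreign_keys = foreign_keys),
            class = "table_schema")
}

RDF_TYPE <- "http://www.w3.org/1999/02/22-rdf-syntax-ns#type"
XSD <- "http://www.w3.org/2001/XMLSchema#"

iri_encode <- function(x) {
  vapply(as.character(x), utils::URLencode, character(1), reserved = TRUE,
         USE.NAMES = FALSE)
}

subject_iri <- function(base_iri, table, pk_values) {
  # pk_values: list of equal-length vectors, one per key column.  "-" is
  # escaped inside components so the composite-key separator is unambiguous
  # (subject IRIs stay injective over primary-key tuples).
  enc <- lapply(pk_values, function(v)
    gsub("-", "%2D", iri_encode(v), fixed = TRUE))
  key <- do.call(paste, c(enc, sep = "-"))
  paste0(base_iri, "/", table, "/", key)
}

datatype_iri <- function(datatype) {
  switch(datatype,
         integer = paste0(XSD, "integer"),
         date = paste0(XSD, "date"),
         text = NA_character_,
         NA_character_)
}

#' Derive the direct mapping of a relational table
#'
#' Implements the direct-mapping rule used for RDF virtualization: every row
#' gets a subject IRI built from its primary-key values
#' (`{base}/{table}/{pk1}[-{pk2}...]`, percent-encoded) and one `rdf:type`
#' statement typing it as `{base}/{table}`; every column that is neither a
#' primary- nor a foreign-key column becomes a literal-valued predicate
#' `{base}/{table}#{column}`; every foreign-key column becomes an
#' IRI-valued predicate pointing at the referenced table's subject IRI.
#'
#' @param schema a [table_schema()].
#' @param base_iri absolute base IRI, no trailing slash.
#' @return object of class `triple_mapping`.
#' @examples
#' sch <- table_schema("genotypes",
#'   c(patientId = "text", rsID = "text", genotype = "text"),
#'   primary_key = c("patientId", "rsID"))
#' m <- direct_map(sch, "http://example.org/gc")
#' @export
direct_map <- function(schema, base_iri) {
  abort_if(!inherits(schema, "table_schema"), "schema must be a table_schema")
  abort_if(!is_string(base_iri) || !grepl("^[A-Za-z][A-Za-z0-9+.-]*://", base_iri),
           "base_iri must be an absolute IRI")
  base_iri <- sub("/+$", "", base_iri)
  tbl <- schema$table_name
  fk_cols <- vapply(schema$foreign_keys, `[[`, character(1), "column")
  poms <- list()
  for (col in names(schema$columns)) {
    if (col %in% schema$primary_key && !(col %in% fk_cols)) next
    if (col %in% fk_cols) {
      fk <- schema$foreign_keys[[match(col, fk_cols)]]
      poms[[length(poms) + 1L]] <- list(
        column = col,
        predicate = paste0(base_iri, "/", tbl, "#", col),
        kind = "iri-ref",
        ref_table = fk$ref_table)
    } else {
      poms[[length(poms) + 1L]] <- list(
        column = col,
        predicate = paste0(base_iri, "/", tbl, "#", col),
        kind = "literal",
        datatype = datatype_iri(schema$columns[[col]]))
    }
  }
  structure(list(logical_table = tbl, base_iri = base_iri,
                 class_iri = paste0(base_iri, "/", tbl),
                 subject_key = schema$primary_key,
                 predicate_object_maps = poms, schema = schema),
            class = "triple_mapping")
}

#' @export
print.triple_mapping <- function(x, ...) {
  cat("Direct mapping for table", x$logical_table, "\n")
  cat("  subject: ", x$base_iri, "/", x$logical_table, "/{",
      paste(x$subject_key, collapse = "}-{"), "}\n", sep = "")
  cat("  class:  ", x$class_iri, "\n")
  for (pom in x$predicate_object_maps) {
    cat("  ", pom$column, " -> <", pom$predicate, "> [", pom$kind, "]\n",
        sep = "")
  }
  invisible(x)
}

empty_triples <- function() {
  data.frame(subject = character(0), predicate = character(0),
             object = character(0), kind = character(0),
             datatype = character(0), stringsAsFactors = FALSE)
}

#' Materialize the RDF triples of a table under a mapping
#'
#' Emits, for each row, one `rdf:type` triple, then (in schema column order)
#' one literal triple per populated non-key column and one IRI-reference
#' triple per populated foreign key.  NULL values (NA or empty string) emit
#' no triple.  A row with a missing primary-key value is rejected.
#'
#' @param mapping a [direct_map()] result (possibly after
#'   [override_mapping()]).
#' @param rows data.frame conforming to the mapping's logical table.
#' @return data.frame of triples with columns `subject`, `predicate`,
#'   `object`, `kind` (`"iri"` or `"literal"`), `datatype` (xsd IRI or NA).
#' @export
apply_mapping <- function(mapping, rows) {
  abort_if(!inherits(mapping, "triple_mapping"), "mapping must be a triple_mapping")
  abort_if(!is.data.frame(rows), "rows must be a data.frame")
  need <- names(mapping$schema$columns)
  miss <- setdiff(need, names(rows))
  abort_if(length(miss) > 0,
           "rows missing column(s): ", paste(miss, collapse = ", "))
  if (nrow(rows) == 0) return(empty_triples())

  pk_vals <- lapply(mapping$subject_key, function(k) rows[[k]])
  pk_missing <- Reduce(`|`, lapply(pk_vals, is_null_value))
  if (any(pk_missing)) {
    stop("row ", which(pk_missing)[1],
         ": missing primary-key value (",
         paste(mapping$subject_key, collapse = ", "), ")", call. = FALSE)
  }
  subj <- subject_iri(mapping$base_iri, mapping$logical_table, pk_vals)

  n <- nrow(rows)
  parts <- vector("list", 1L + length(mapping$predicate_object_maps))
  parts[[1]] <- data.frame(row = seq_len(n), rank = 0L, subject = subj,
                           predicate = RDF_TYPE, object = mapping$class_iri,
                           kind = "iri", datatype = NA_character_,
                           stringsAsFactors = FALSE)
  rank <- 0L
  for (pom in mapping$predicate_object_maps) {
    rank <- rank + 1L
    v <- rows[[pom$column]]
    keep <- !is_null_value(v)
    if (!any(keep)) next
    if (pom$kind == "literal") {
      obj <- as.character(v[keep])
      parts[[rank + 1L]] <- data.frame(
        row = which(keep), rank = rank, subject = subj[keep],
        predicate = pom$predicate, object = obj, kind = "literal",
        datatype = pom$datatype %||% NA_character_, stringsAsFactors = FALSE)
    } else {
      obj <- subject_iri(mapping$base_iri, pom$ref_table,
                         list(v[keep]))
      parts[[rank + 1L]] <- data.frame(
        row = which(keep), rank = rank, subject = subj[keep],
        predicate = pom$predicate, object = obj, kind = "iri",
        datatype = NA_character_, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, parts[!vapply(parts, is.null, logical(1))])
  out <- out[order(out$row, out$rank), c("subject", "predicate", "object",
                                         "kind", "datatype")]
  rownames(out) <- NULL
  out
}

#' Replace an auto-generated mapping term by an ontology term
#'
#' Customizes a direct mapping the way virtualization mapping files are
#' edited by hand: the auto-generated class IRI or a column's predicate IRI
#' is replaced by a term from a standardized ontology.  Triple counts are
#' unchanged; only IRIs differ.
#'
#' @param mapping a `triple_mapping`.
#' @param target `"class"` to replace the class IRI, or a column name to
#'   replace that column's predicate.
#' @param term absolute ontology IRI to substitute.
#' @return a new `triple_mapping`.
#' @export
override_mapping <- function(mapping, target, term) {
  abort_if(!inherits(mapping, "triple_mapping"), "mapping must be a triple_mapping")
  abort_if(!is_string(term) || !grepl("^[A-Za-z][A-Za-z0-9+.-]*:", term),
           "term must be an absolute IRI")
  cols <- vapply(mapping$predicate_object_maps, `[[`, character(1), "column")
  if (identical(target, "class")) {
    mapping$class_iri <- term
    return(mapping)
  }
  idx <- match(target, cols)
  abort_if(is.na(idx),
           "unknown override target '", target, "'; valid targets: class, ",
           paste(cols, collapse = ", "))
  mapping$predicate_object_maps[[idx]]$predicate <- term
  mapping
}

## ---- serialization ---------------------------------------------------------

escape_literal <- function(x) {
  x <- gsub("\\", "\\\\", x, fixed = TRUE)
  x <- gsub("\"", "\\\"", x, fixed = TRUE)
  x <- gsub("\n", "\\n", x, fixed = TRUE)
  x <- gsub("\r", "\\r", x, fixed = TRUE)
  gsub("\t", "\\t", x, fixed = TRUE)
}

unescape_literal <- function(x) {
  out <- character(length(x))
  for (i in seq_along(x)) {
    s <- x[i]
    res <- character(0)
    while (nchar(s) > 0) {
      m <- regexpr("\\\\[\\\\\"nrt]", s)
      if (m == -1) { res <- c(res, s); break }
      if (m > 1) res <- c(res, substr(s, 1, m - 1))
      esc <- substr(s, m + 1, m + 1)
      res <- c(res, switch(esc, "n" = "\n", "r" = "\r", "t" = "\t",
                           "\"" = "\"", "\\" = "\\"))
      s <- substr(s, m + 2, nchar(s))
    }
    out[i] <- paste(res, collapse = "")
  }
  out
}

format_object <- function(object, kind, datatype) {
  ifelse(kind == "iri", paste0("<", object, ">"),
         ifelse(is.na(datatype),
                paste0("\"", escape_literal(object), "\""),
                paste0("\"", escape_literal(object), "\"^^<", datatype, ">")))
}

#' Serialize triples to N-Triples or Turtle
#'
#' N-Triples output is sorted lexicographically line-by-line so identical
#' triple multisets serialize to identical documents (reproducible diffs).
#' Turtle output groups statements by subject with `;` continuation and uses
#' full IRIs throughout.
#'
#' @param triples triples data.frame (see [apply_mapping()]).
#' @param format `"ntriples"` or `"turtle"`.
#' @param file optional path; when given, lines are written there.
#' @return character vector of document lines, invisibly when `file` is set.
#' @export
serialize_triples <- function(triples, format = c("ntriples", "turtle"),
                              file = NULL) {
  format <- match.arg(format)
  abort_if(!is.data.frame(triples) ||
             !all(c("subject", "predicate", "object", "kind") %in% names(triples)),
           "triples must have subject/predicate/object/kind columns")
  dt <- if ("datatype" %in% names(triples)) triples$datatype else
    rep(NA_character_, nrow(triples))
  if (format == "ntriples") {
    if (nrow(triples) == 0) {
      lines <- character(0)
    } else {
      lines <- paste0("<", triples$subject, "> <", triples$predicate, "> ",
                      format_object(triples$object, triples$kind, dt), " .")
      lines <- sort(lines, method = "radix")
    }
  } else {
    if (nrow(triples) == 0) {
      lines <- character(0)
    } else {
      obj <- format_object(triples$object, triples$kind, dt)
      ord <- order(triples$subject, triples$predicate, obj, method = "radix")
      s <- triples$subject[ord]; p <- triples$predicate[ord]; o <- obj[ord]
      lines <- character(0)
      i <- 1L
      while (i <= length(s)) {
        j <- i
        while (j < length(s) && s[j + 1L] == s[i]) j <- j + 1L
        stmts <- paste0("    <", p[i:j], "> ", o[i:j])
        block <- c(paste0("<", s[i], ">"),
                   paste0(stmts, c(rep(" ;", j - i), " .")))
        lines <- c(lines, block, "")
        i <- j + 1L
      }
      if (length(lines) > 0 && lines[length(lines)] == "")
        lines <- lines[-length(lines)]
    }
  }
  if (!is.null(file)) {
    writeLines(lines, file)
    return(invisible(lines))
  }
  lines
}

parse_term <- function(tok) {
  if (startsWith(tok, "<")) {
    list(value = sub("^<(.*)>$", "\\1", tok), kind = "iri",
         datatype = NA_character_)
  } else if (startsWith(tok, "\"")) {
    m <- regmatches(tok, regexec('^"((?:[^"\\\\]|\\\\.)*)"(?:\\^\\^<([^>]*)>)?$',
                                 tok))[[1]]
    abort_if(length(m) == 0, "malformed literal: ", tok)
    list(value = unescape_literal(m[2]), kind = "literal",
         datatype = if (nzchar(m[3])) m[3] else NA_character_)
  } else {
    stop("malformed RDF term: ", tok, call. = FALSE)
  }
}

split_statement_terms <- function(body) {
  # split an N-Triples statement body into three terms, respecting quotes
  terms <- character(0)
  s <- trimws(body)
  while (nzchar(s)) {
    if (startsWith(s, "<")) {
      end <- regexpr(">", s, fixed = TRUE)
      abort_if(end == -1, "unterminated IRI in: ", body)
      terms <- c(terms, substr(s, 1, end))
      s <- trimws(substr(s, end + 1, nchar(s)))
    } else if (startsWith(s, "\"")) {
      chars <- strsplit(s, "")[[1]]
      i <- 2L
      while (i <= length(chars)) {
        if (chars[i] == "\\") { i <- i + 2L; next }
        if (chars[i] == "\"") break
        i <- i + 1L
      }
      abort_if(i > length(chars), "unterminated literal in: ", body)
      end <- i
      rest <- substr(s, end + 1, nchar(s))
      if (startsWith(rest, "^^")) {
        dt_end <- regexpr(">", rest, fixed = TRUE)
        abort_if(dt_end == -1, "unterminated datatype IRI in: ", body)
        end <- end + dt_end
      }
      terms <- c(terms, substr(s, 1, end))
      s <- trimws(substr(s, end + 1, nchar(s)))
    } else {
      stop("malformed term near: ", s, call. = FALSE)
    }
  }
  terms
}

#' Parse N-Triples / subset Turtle back into a triples table
#'
#' `parse_ntriples()` accepts any N-Triples document restricted to IRIs and
#' (optionally typed) literals; `parse_turtle()` accepts the
#' subject-grouped subset that [serialize_triples()] emits.
#'
#' @param lines character vector of document lines, or a file path of length
#'   one pointing at an existing file.
#' @return triples data.frame (`subject`, `predicate`, `object`, `kind`,
#'   `datatype`).
#' @export
parse_ntriples <- function(lines) {
  if (length(lines) == 1 && file.exists(lines)) lines <- readLines(lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(lines) == 0) return(empty_triples())
  out <- lapply(seq_along(lines), function(i) {
    ln <- lines[i]
    abort_if(!grepl("\\.$", ln), "line ", i, ": statement must end with '.'")
    body <- sub("\\s*\\.$", "", ln)
    terms <- split_statement_terms(body)
    abort_if(length(terms) != 3, "line ", i, ": expected 3 terms")
    s <- parse_term(terms[1]); p <- parse_term(terms[2]); o <- parse_term(terms[3])
    abort_if(s$kind != "iri" || p$kind != "iri",
             "line ", i, ": subject and predicate must be IRIs")
    data.frame(subject = s$value, predicate = p$value, object = o$value,
               kind = o$kind, datatype = o$datatype, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' @rdname parse_ntriples
#' @export
parse_turtle <- function(lines) {
  if (length(lines) == 1 && file.exists(lines)) lines <- readLines(lines)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) return(empty_triples())
  subject <- NULL
  rows <- list()
  for (i in seq_along(lines)) {
    ln <- trimws(lines[i])
    if (startsWith(ln, "@prefix")) next
    if (grepl("^<[^>]*>$", ln)) { subject <- sub("^<(.*)>$", "\\1", ln); next }
    abort_if(is.null(subject), "line ", i, ": statement before any subject")
    terminator <- if (grepl(";$", ln)) ";" else if (grepl("\\.$", ln)) "." else
      stop("line ", i, ": statement must end with ';' or '.'", call. = FALSE)
    body <- sub("\\s*[;.]$", "", ln)
    terms <- split_statement_terms(body)
    abort_if(length(terms) != 2, "line ", i, ": expected predicate and object")
    p <- parse_term(terms[1]); o <- parse_term(terms[2])
    rows[[length(rows) + 1L]] <- data.frame(
      subject = subject, predicate = p$value, object = o$value,
      kind = o$kind, datatype = o$datatype, stringsAsFactors = FALSE)
    if (terminator == ".") subject <- subject  # subject stays until replaced
  }
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}

## ---- mapping file I/O ------------------------------------------------------

#' Read / write mapping files
#'
#' A YAML dialect mirroring R2RML's structure (logical table, subject
#' template, one predicate-object map per column) so that auto-generated
#' mappings can be inspected and hand-edited, then reloaded.
#'
#' @param mapping a `triple_mapping`.
#' @param path file path.
#' @return [read_mapping_yaml()] returns a `triple_mapping`.
#' @export
write_mapping_yaml <- function(mapping, path) {
  abort_if(!inherits(mapping, "triple_mapping"), "mapping must be a triple_mapping")
  doc <- list(
    logicalTable = mapping$logical_table,
    baseIri = mapping$base_iri,
    subjectMap = list(template = paste0(mapping$base_iri, "/",
                                        mapping$logical_table, "/{",
                                        paste(mapping$subject_key,
                                              collapse = "}-{"), "}"),
                      keyColumns = as.list(mapping$subject_key),
                      classIri = mapping$class_iri),
    predicateObjectMaps = lapply(mapping$predicate_object_maps, function(pom) {
      out <- list(column = pom$column, predicate = pom$predicate,
                  objectKind = pom$kind)
      if (pom$kind == "literal") out$datatype <- pom$datatype else
        out$refTable <- pom$ref_table
      out
    }),
    schema = list(columns = as.list(mapping$schema$columns),
                  primaryKey = as.list(mapping$schema$primary_key),
                  foreignKeys = mapping$schema$foreign_keys)
  )
  yaml::write_yaml(doc, path)
  invisible(path)
}

#' @rdname write_mapping_yaml
#' @export
read_mapping_yaml <- function(path) {
  doc <- yaml::read_yaml(path)
  schema <- table_schema(doc$logicalTable,
                         unlist(doc$schema$columns),
                         unlist(doc$schema$primaryKey),
                         doc$schema$foreignKeys %||% list())
  mapping <- direct_map(schema, doc$baseIri)
  mapping$class_iri <- doc$subjectMap$classIri
  for (pom in doc$predicateObjectMaps) {
    cols <- vapply(mapping$predicate_object_maps, `[[`, character(1), "column")
    idx <- match(pom$column, cols)
    abort_if(is.na(idx), "mapping file names unknown column: ", pom$column)
    mapping$predicate_object_maps[[idx]]$predicate <- pom$predicate
  }
  mapping
}
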