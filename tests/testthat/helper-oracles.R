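# Independent oracles and fixture builders used across the suite.
# Everything here is deliberately brute-force: loops and closed forms that
# re-derive what the implementation computes by a different route.

# Two-sided Fisher exact p by full enumeration over all tables with the
# observed margins, using plain choose() arithmetic.
oracle_fisher_p <- function(a, b, c, d) {
  m <- a + b; n <- c + d; k <- a + c
  if (m == 0 || n == 0 || k == 0 || k == m + n) return(1)
  ks <- max(0, k - n):min(k, m)
  probs <- choose(m, ks) * choose(n, k - ks) / choose(m + n, k)
  obs <- choose(m, a) * choose(n, c) / choose(m + n, k)
  min(1, sum(probs[probs <= obs * (1 + 1e-7)]))
}

# Nested-loop equality join with key canonicalization (leading zeros,
# numeric-vs-string) -- the reference for join_bindings.
oracle_join <- function(a, b, lvar, rvar) {
  canon <- function(x) {
    x <- as.character(x)
    num <- grepl("^[0-9]+$", x)
    x[num] <- as.character(as.numeric(x[num]))
    x
  }
  rows <- list()
  for (i in seq_len(nrow(a))) {
    for (j in seq_len(nrow(b))) {
      if (canon(a[[lvar]][i]) == canon(b[[rvar]][j])) {
        rows[[length(rows) + 1L]] <- cbind(a[i, , drop = FALSE],
                                           b[j, , drop = FALSE])
      }
    }
  }
  if (length(rows) == 0) {
    out <- a[integer(0), , drop = FALSE]
    for (v in setdiff(names(b), names(a))) out[[v]] <- character(0)
    return(out)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# Row-by-row triple counter: 1 rdf:type + one triple per populated non-key
# non-fk column + one per populated foreign key.
oracle_triple_count <- function(schema, rows) {
  fk_cols <- vapply(schema$foreign_keys, `[[`, character(1), "column")
  plain <- setdiff(names(schema$columns), union(schema$primary_key, fk_cols))
  total <- 0L
  populated <- function(v) !is.na(v) && !(is.character(v) && v == "")
  for (i in seq_len(nrow(rows))) {
    c_i <- sum(vapply(plain, function(col) populated(rows[[col]][i]),
                      logical(1)))
    f_i <- sum(vapply(fk_cols, function(col) populated(rows[[col]][i]),
                      logical(1)))
    total <- total + 1L + c_i + f_i
  }
  total
}

# Multiset equality of two bindings frames: same columns, same rows up to
# order.
expect_same_multiset <- function(a, b) {
  expect_setequal(names(a), names(b))
  b <- b[, names(a), drop = FALSE]
  key_a <- do.call(paste, c(lapply(a, as.character), sep = "\r"))
  key_b <- do.call(paste, c(lapply(b, as.character), sep = "\r"))
  expect_equal(sort(key_a), sort(key_b))
}

# Random triples over a small vocabulary.  Each emulated store gets its own
# IRI namespace (`ns`), as the virtualized stores do: that disjointness is
# what makes federated evaluation equivalent to querying the merged graph.
random_triples <- function(n, ns = "a", n_subj = 20, n_pred = 5, n_obj = 15) {
  df <- data.frame(
    subject = sprintf("http://x.org/%s/s/%d", ns, sample.int(n_subj, n, TRUE)),
    predicate = sprintf("http://x.org/%s/p/%d", ns, sample.int(n_pred, n, TRUE)),
    object = sprintf("v%d", sample.int(n_obj, n, TRUE)),
    stringsAsFactors = FALSE)
  df <- unique(df)
  df$kind <- "literal"
  df$datatype <- NA_character_
  df
}

# A random two-endpoint federation plus a random two-clause query with one
# cross-clause join and optionally a selection filter; variables are
# disjoint across clauses by construction.
random_federation_case <- function(max_triples = 500) {
  n1 <- sample.int(max_triples, 1)
  n2 <- sample.int(max_triples, 1)
  eps <- list(a = graph_endpoint("a", random_triples(n1, ns = "a")),
              b = graph_endpoint("b", random_triples(n2, ns = "b")))
  p1 <- sample(sprintf("http://x.org/a/p/%d", 1:5), 1)
  p2 <- sample(sprintf("http://x.org/b/p/%d", 1:5), 1)
  cl1 <- service_clause("a", list(triple_pattern("?s1", p1, "?o1")))
  cl2 <- service_clause("b", list(triple_pattern("?s2", p2, "?o2")))
  sel <- if (stats::runif(1) < 0.5) {
    list(list(lhs = "?o1", op = "==", rhs = sprintf("v%d", sample.int(15, 1))))
  } else list()
  query <- federated_query(
    clauses = list(cl1, cl2),
    join_filters = list(list(lhs = "?o1", rhs = "?o2")),
    selection_filters = sel,
    projection = c("s1", "s2", "o1"))
  list(query = query, endpoints = eps)
}

# Tiny hand-buildable bundle: k subjects, one SNP, chosen genotypes, one
# diagnosis per subject -- used for the demonstration-query fixture.
toy_bundle <- function(genotypes_by_subject, snp = "rs2476601",
                       code = "250.00") {
  n <- length(genotypes_by_subject)
  demo <- data.frame(internalKey = 100 + seq_len(n),
                     clinicNumber = 500 + seq_len(n),
                     age = 60L, sex = "F", subgroup = "TOY",
                     record_len = 10L, stringsAsFactors = FALSE)
  link <- data.frame(clinicNumber = demo$clinicNumber,
                     patientId = as.character(demo$clinicNumber),
                     stringsAsFactors = FALSE)
  gt <- data.frame(patientId = link$patientId, rsID = snp,
                   genotype = genotypes_by_subject, stringsAsFactors = FALSE)
  dx <- data.frame(eventId = seq_len(n), internalKey = demo$internalKey,
                   icd9_code = code, dx_date = "2001-01-01",
                   stringsAsFactors = FALSE)
  map <- default_category_map()[, c("code", "category_id", "label")]
  structure(list(demographics = demo, diagnoses = dx, genotypes = gt,
                 linkage = link, category_map = map,
                 panel = default_snp_panel(), seed = 0L),
            class = "fixture_bundle")
}
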