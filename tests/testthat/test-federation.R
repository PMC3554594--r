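mk_triples <- function(...) {
  rows <- list(...)
  df <- do.call(rbind, lapply(rows, function(r)
    data.frame(subject = r[1], predicate = r[2], object = r[3],
               stringsAsFactors = FALSE)))
  df$kind <- "literal"; df$datatype <- NA_character_
  df
}

GT_P <- "http://x.org/p/genotype"
ID_P <- "http://x.org/p/id"

test_that("service execution matches patterns and local filters", {
  ep <- graph_endpoint("g", mk_triples(
    c("http://x.org/s/1", GT_P, "A:A"),
    c("http://x.org/s/2", GT_P, "A:G"),
    c("http://x.org/s/2", ID_P, "p2")))
  eps <- list(g = ep)
  cl <- service_clause("g", list(triple_pattern("?p", GT_P, "?g")))
  b <- execute_service(eps, cl)
  expect_equal(nrow(b), 2)
  expect_setequal(names(b), c("p", "g"))
  # unsatisfiable local filter: empty result, no error
  cl2 <- service_clause("g", list(triple_pattern("?p", GT_P, "?g")),
                        filters = list(list(lhs = "?g", op = "==",
                                            rhs = "Z:Z")))
  expect_equal(nrow(execute_service(eps, cl2)), 0)
})

test_that("a local key-join filter reduces the product to key-equal rows", {
  set.seed(8)
  tr <- rbind(
    data.frame(subject = sprintf("http://x.org/a/%d", 1:30),
               predicate = ID_P, object = as.character(sample.int(10, 30, TRUE)),
               stringsAsFactors = FALSE),
    data.frame(subject = sprintf("http://x.org/b/%d", 1:30),
               predicate = GT_P, object = as.character(sample.int(10, 30, TRUE)),
               stringsAsFactors = FALSE))
  tr$kind <- "literal"; tr$datatype <- NA_character_
  eps <- list(g = graph_endpoint("g", tr))
  cl <- service_clause("g", list(triple_pattern("?x", ID_P, "?k1"),
                                 triple_pattern("?y", GT_P, "?k2")),
                       filters = list(list(lhs = "?k1", op = "==",
                                           rhs = "?k2")))
  got <- execute_service(eps, cl)
  a <- data.frame(x = tr$subject[1:30], k1 = tr$object[1:30],
                  stringsAsFactors = FALSE)
  b <- data.frame(y = tr$subject[31:60], k2 = tr$object[31:60],
                  stringsAsFactors = FALSE)
  expect_same_multiset(got, oracle_join(a, b, "k1", "k2"))
})

test_that("endpoint errors distinguish unknown, unavailable and empty", {
  eps <- list(g = graph_endpoint("g", mk_triples(c("s", "p", "o"))),
              dead = graph_endpoint("dead", mk_triples(c("s", "p", "o")),
                                    available = FALSE))
  cl_missing <- service_clause("nope", list(triple_pattern("?s", "p", "?o")))
  expect_error(execute_service(eps, cl_missing), "unknown endpoint")
  cl_dead <- service_clause("dead", list(triple_pattern("?s", "p", "?o")))
  expect_error(execute_service(eps, cl_dead), "unavailable")
  cl_empty <- service_clause("g", list(triple_pattern("?s", "zzz", "?o")))
  expect_equal(nrow(execute_service(eps, cl_empty)), 0)
})

test_that("join_bindings matches the nested-loop oracle", {
  a <- data.frame(x = c("1", "2"), stringsAsFactors = FALSE)
  b <- data.frame(y = c("2", "3"), stringsAsFactors = FALSE)
  got <- join_bindings(a, b, list(list(lhs = "?x", rhs = "?y")))
  expect_equal(nrow(got), 1)
  expect_equal(got$x, "2")
  expect_equal(got$y, "2")
  # absorbing element
  expect_equal(nrow(join_bindings(a, b[integer(0), , drop = FALSE],
                                  list(list(lhs = "?x", rhs = "?y")))), 0)
  # key canonicalization: "0123" joins 123
  a2 <- data.frame(x = c("0123", "7"), stringsAsFactors = FALSE)
  b2 <- data.frame(y = c("123", "07"), stringsAsFactors = FALSE)
  got2 <- join_bindings(a2, b2, list(list(lhs = "?x", rhs = "?y")))
  expect_equal(nrow(got2), 2)
  # randomized case vs oracle
  set.seed(77)
  ra <- data.frame(x = as.character(sample.int(40, 200, TRUE)),
                   u = as.character(seq_len(200)), stringsAsFactors = FALSE)
  rb <- data.frame(y = as.character(sample.int(40, 200, TRUE)),
                   v = as.character(seq_len(200)), stringsAsFactors = FALSE)
  expect_same_multiset(join_bindings(ra, rb, list(list(lhs = "?x", rhs = "?y"))),
                       oracle_join(ra, rb, "x", "y"))
  expect_error(join_bindings(ra, rb, list(list(lhs = "?zz", rhs = "?y"))),
               "unbound")
})

test_that("the demonstration query shape retrieves exactly the planted carriers", {
  gts <- c(rep("A:A", 7), rep("A:G", 2), "G:G")
  bundle <- toy_bundle(gts)
  # two diagnosis rows for the first subject so its bindings multiply
  bundle$diagnoses <- rbind(bundle$diagnoses,
                            data.frame(eventId = 11L, internalKey = 101L,
                                       icd9_code = "401.9",
                                       dx_date = "2002-02-02"))
  eps <- virtualize_bundle(bundle)
  q <- biobank_query("rs2476601", "A:A")
  got <- run_federated(q, eps)
  expect_length(unique(got$pid), 7)
  expect_true(all(got$genotype == "A:A"))
  # subject 101 carries both of its diagnosis rows
  expect_equal(sort(got$code[got$pid == "501"]), c("250.00", "401.9"))
  # selection for a SNP absent from the panel: empty, no error
  none <- run_federated(biobank_query("rs4915077", "A:A"), eps)
  expect_equal(nrow(none), 0)
})

test_that("single-clause federation degenerates to execute_service", {
  bundle <- toy_bundle(c("A:A", "G:G"))
  eps <- virtualize_bundle(bundle)
  q <- genotype_retrieval_query()
  via_fed <- run_federated(q, eps)
  via_service <- execute_service(eps, q$clauses[[1]])
  expect_same_multiset(via_fed,
                       via_service[, c("pid", "rsID", "genotype")])
})

test_that("federation is transparent wrt the merged store on random fixtures", {
  set.seed(99)
  for (rep in 1:30) {
    case <- random_federation_case(max_triples = 300)
    fed <- run_federated(case$query, case$endpoints)
    mono <- run_monolithic(case$query, case$endpoints)
    expect_same_multiset(fed, mono)
  }
})

test_that("clause order does not change the result multiset", {
  set.seed(13)
  for (rep in 1:10) {
    case <- random_federation_case(max_triples = 200)
    q <- case$query
    q_swapped <- federated_query(rev(q$clauses), q$join_filters,
                                 q$selection_filters, q$projection)
    expect_same_multiset(run_federated(q, case$endpoints),
                         run_federated(q_swapped, case$endpoints))
  }
})

test_that("adding triples never removes result rows (monotonicity)", {
  set.seed(21)
  for (rep in 1:10) {
    case <- random_federation_case(max_triples = 150)
    before <- run_federated(case$query, case$endpoints)
    bigger <- case$endpoints
    extra <- random_triples(50)
    bigger$a <- graph_endpoint("a", unique(rbind(bigger$a$triples, extra)))
    after <- run_federated(case$query, bigger)
    key_before <- do.call(paste, c(before, sep = "\r"))
    key_after <- do.call(paste, c(after[, names(before), drop = FALSE],
                                  sep = "\r"))
    tab_b <- table(key_before); tab_a <- table(key_after)
    expect_true(all(names(tab_b) %in% names(tab_a)))
    expect_true(all(tab_a[names(tab_b)] >= tab_b))
  }
})

test_that("projection of a never-bound variable errors", {
  expect_error(
    federated_query(
      clauses = list(service_clause("g", list(triple_pattern("?s", "p", "?o")))),
      projection = "zzz"),
    "never-bound")
})

test_that("plan summaries are deterministic and descriptive", {
  q1 <- genotype_retrieval_query()
  expect_identical(plan_summary(q1), plan_summary(q1))
  expect_match(plan_summary(q1)[1], "1 clause")
  q2 <- biobank_query()
  lines <- plan_summary(q2)
  expect_equal(sum(grepl("^  join:", lines)), 1)
  expect_equal(sum(grepl("^  select:", lines)), 2)
})

test_that("the concrete query syntax parses to the built-in query", {
  bundle <- toy_bundle(c("A:A", "A:A", "G:G"))
  eps <- virtualize_bundle(bundle)
  bg <- "http://example.org/biobank"
  bc <- "http://example.org/clinical"
  text <- c(
    "SELECT ?pid ?rsID ?genotype ?code",
    "SERVICE genotype {",
    sprintf("  ?g <%s/genotypes#rsID> ?rsID .", bg),
    sprintf("  ?g <%s/genotypes#genotype> ?genotype .", bg),
    sprintf("  ?g <%s/genotypes#patientId> ?gpid .", bg),
    sprintf("  ?s <%s/subjects#patientId> ?pid .", bg),
    "  FILTER(?pid = ?gpid)",
    "}",
    "SERVICE clinical {",
    sprintf("  ?d <%s/diagnoses#internalKey> ?demo .", bc),
    sprintf("  ?d <%s/diagnoses#icd9_code> ?code .", bc),
    sprintf("  ?demo <%s/demographics#clinicNumber> ?cn .", bc),
    "}",
    "FILTER(?pid = ?cn)",
    "FILTER(?rsID = \"rs2476601\")",
    "FILTER(?genotype = \"A:A\")")
  q <- parse_query(text)
  expect_same_multiset(run_federated(q, eps),
                       run_federated(biobank_query("rs2476601", "A:A"), eps))
  # malformed input names the offending line
  expect_error(parse_query(c("SELECT ?x", "SERVICE g {", "garbage", "}")),
               "line 3")
})
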