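base <- "http://example.org/store"

gt_schema <- table_schema(
  "genotypes",
  c(patientId = "text", rsID = "text", genotype = "text"),
  primary_key = c("patientId", "rsID"))

dx_schema <- table_schema(
  "diagnoses",
  c(eventId = "integer", internalKey = "integer", icd9_code = "text",
    dx_date = "date"),
  primary_key = "eventId",
  foreign_keys = list(list(column = "internalKey", ref_table = "demographics",
                           ref_column = "internalKey")))

test_that("direct mapping is forced by the rule and deterministic", {
  m <- direct_map(gt_schema, base)
  kinds <- vapply(m$predicate_object_maps, `[[`, character(1), "kind")
  expect_equal(m$class_iri, paste0(base, "/genotypes"))
  expect_equal(sum(kinds == "literal"), 1)   # only the genotype column
  expect_equal(sum(kinds == "iri-ref"), 0)
  m_dx <- direct_map(dx_schema, base)
  kinds_dx <- vapply(m_dx$predicate_object_maps, `[[`, character(1), "kind")
  expect_equal(sum(kinds_dx == "iri-ref"), 1)  # exactly the declared fk
  expect_identical(direct_map(gt_schema, base), direct_map(gt_schema, base))
})

test_that("apply_mapping emits 1 + c + f triples per row and suppresses NULLs", {
  sch <- table_schema("t", c(id = "integer", x = "text", y = "text",
                             z = "integer", fk = "integer"),
                      primary_key = "id",
                      foreign_keys = list(list(column = "fk", ref_table = "u",
                                               ref_column = "id")))
  m <- direct_map(sch, base)
  full <- data.frame(id = 1L, x = "a", y = "b", z = 3L, fk = 9L)
  expect_equal(nrow(apply_mapping(m, full)), 5)  # type + 3 literals + 1 fk
  holes <- data.frame(id = 1L, x = "a", y = NA, z = 3L, fk = 9L)
  expect_equal(nrow(apply_mapping(m, holes)), 4)
  # emission order within a row: rdf:type first, then schema column order
  tr <- apply_mapping(m, full)
  expect_match(tr$predicate[1], "rdf-syntax-ns#type")
  expect_equal(sub(".*#", "", tr$predicate[-1]), c("x", "y", "z", "fk"))
})

test_that("the full demographics table yields the expected triple total", {
  sch <- table_schema("demographics",
                      c(internalKey = "integer", clinicNumber = "integer",
                        age = "integer", sex = "text", subgroup = "text"),
                      primary_key = "internalKey")
  ch <- generate_cohort(cohort_spec(seed = 4))
  demo <- ch$demographics[, names(sch$columns)]
  tr <- apply_mapping(direct_map(sch, base), demo)
  expect_equal(nrow(tr), 6307 * (1 + 4))  # 31,535
})

test_that("rows with missing primary keys are rejected with the row index", {
  m <- direct_map(gt_schema, base)
  rows <- data.frame(patientId = c("1", NA, "3"), rsID = "rs5219",
                     genotype = "A:A", stringsAsFactors = FALSE)
  expect_error(apply_mapping(m, rows), "row 2")
})

test_that("triple counts match the brute-force counter on random tables", {
  set.seed(42)
  for (rep in 1:25) {
    n_col <- sample(3:8, 1)
    cols <- stats::setNames(sample(c("integer", "text", "date"), n_col, TRUE),
                            paste0("c", seq_len(n_col)))
    pk <- names(cols)[1]
    fks <- if (n_col >= 4 && stats::runif(1) < 0.6) {
      list(list(column = names(cols)[2], ref_table = "other",
                ref_column = "id"))
    } else list()
    sch <- table_schema(paste0("t", rep), cols, pk, fks)
    n_row <- sample(1:40, 1)
    rows <- as.data.frame(lapply(cols, function(dt) {
      v <- as.character(sample.int(50, n_row, TRUE))
      v[stats::runif(n_row) < 0.2] <- NA  # random NULLs
      v
    }), stringsAsFactors = FALSE)
    rows[[pk]] <- as.character(seq_len(n_row))  # keys always populated
    tr <- apply_mapping(direct_map(sch, base), rows)
    expect_equal(nrow(tr), oracle_triple_count(sch, rows))
  }
})

test_that("subject IRIs are injective over primary-key tuples", {
  sch <- table_schema("t", c(k1 = "text", k2 = "text", v = "text"),
                      primary_key = c("k1", "k2"))
  m <- direct_map(sch, base)
  # adversarial tuples that would collide under naive concatenation
  rows <- data.frame(k1 = c("a-b", "a", "x/y", "x"),
                     k2 = c("c", "b-c", "z", "y/z"),
                     v = "w", stringsAsFactors = FALSE)
  tr <- apply_mapping(m, rows)
  subjects <- unique(tr$subject)
  expect_length(subjects, 4)
})

test_that("override substitutes terms without changing triple counts", {
  m <- direct_map(dx_schema, base)
  rows <- data.frame(eventId = 1:3, internalKey = 4:6,
                     icd9_code = "250.00", dx_date = "2001-01-01")
  before <- apply_mapping(m, rows)
  m2 <- override_mapping(m, "class", "http://purl.org/tmo/TMO_Disease")
  after <- apply_mapping(m2, rows)
  expect_equal(nrow(after), nrow(before))
  expect_equal(sort(after$subject), sort(before$subject))
  type_rows <- grepl("rdf-syntax-ns#type", after$predicate)
  expect_true(all(after$object[type_rows] == "http://purl.org/tmo/TMO_Disease"))
  # predicate override, idempotence, and the error contract
  m3 <- override_mapping(m, "icd9_code", "http://purl.org/obo/ICD9")
  expect_identical(override_mapping(m3, "icd9_code", "http://purl.org/obo/ICD9"),
                   m3)
  expect_error(override_mapping(m, "foo", "http://x.org/t"), "valid targets")
})

test_that("N-Triples serialization round-trips and escapes correctly", {
  expect_identical(serialize_triples(empty_df <- data.frame(
    subject = character(0), predicate = character(0), object = character(0),
    kind = character(0), datatype = character(0)), "ntriples"),
    character(0))
  tricky <- data.frame(
    subject = paste0(base, "/t/1"), predicate = paste0(base, "/t#x"),
    object = "say \"hi\"\tand\nbye \\ done", kind = "literal",
    datatype = NA_character_, stringsAsFactors = FALSE)
  lines <- serialize_triples(tricky, "ntriples")
  expect_match(lines, '\\\\"hi\\\\"')
  expect_false(grepl("\n", lines[1], fixed = TRUE))
  back <- parse_ntriples(lines)
  expect_equal(back$object, tricky$object)

  m <- direct_map(dx_schema, base)
  rows <- data.frame(eventId = 1:5, internalKey = c(4:7, NA),
                     icd9_code = c("250.00", NA, "401.9", "244.0", "272.4"),
                     dx_date = "2001-01-01")
  tr <- apply_mapping(m, rows)
  nt <- serialize_triples(tr, "ntriples")
  expect_identical(nt, sort(nt, method = "radix"))  # reproducible ordering
  expect_same_multiset(parse_ntriples(nt), tr)
})

test_that("Turtle serialization round-trips through its parser", {
  m <- direct_map(gt_schema, base)
  rows <- data.frame(patientId = c("5000001", "5000002"),
                     rsID = c("rs2476601", "rs5219"),
                     genotype = c("A:A", "C:T"), stringsAsFactors = FALSE)
  tr <- apply_mapping(m, rows)
  ttl <- serialize_triples(tr, "turtle")
  expect_same_multiset(parse_turtle(ttl), tr)
  expect_error(serialize_triples(tr, "rdfxml"), "arg")
})

test_that("mapping files round-trip through the YAML dialect", {
  m <- override_mapping(direct_map(dx_schema, base), "icd9_code",
                        "http://purl.org/obo/ICD9")
  path <- withr::local_tempfile(fileext = ".yaml")
  write_mapping_yaml(m, path)
  back <- read_mapping_yaml(path)
  rows <- data.frame(eventId = 1:3, internalKey = 4:6,
                     icd9_code = "250.00", dx_date = "2001-01-01")
  expect_identical(apply_mapping(back, rows), apply_mapping(m, rows))
})
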