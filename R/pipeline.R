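#' Pipeline run configuration
#'
#' Collects everything one end-to-end run needs: the master seed, the cohort
#' and effect specification, the scan panel, category map, phenotyping rule,
#' genetic model, multiplicity adjustment, cluster-retention threshold and
#' the demonstration query's SNP/genotype selection.  All components default
#' to the package's study defaults.
#'
#' @param seed master integer seed.
#' @param outdir output directory for pipeline stages.
#' @param spec a [cohort_spec()] (seed is overridden by `seed`).
#' @param effects list of [planted_effect()]s.
#' @param panel SNP panel data.frame.
#' @param map category map data.frame.
#' @param rule a [phenotype_rule()].
#' @param model scan model kind (see [phewas_scan()]).
#' @param adjust multiplicity adjustment.
#' @param min_subjects cluster-retention threshold.
#' @param snp,genotype selection of the built-in demonstration query.
#' @param maf per-SNP minor-allele frequencies.
#' @param background per-category baseline prevalences (NULL = map defaults).
#' @return object of class `run_config`.
#' @export
run_config <- function(seed = 1L, outdir = tempfile("fedphewas-"),
                       spec = cohort_spec(seed = seed), effects = list(),
                       panel = default_snp_panel(),
                       map = default_category_map(), rule = t2dm_rule(),
                       model = "dominant", adjust = "bh", min_subjects = 25,
                       snp = "rs2476601", genotype = "A:A",
                       maf = default_maf(panel), background = NULL) {
  spec$seed <- as.integer(seed)
  structure(list(seed = as.integer(seed), outdir = outdir, spec = spec,
                 effects = effects, panel = panel, map = map, rule = rule,
                 model = model, adjust = adjust, min_subjects = min_subjects,
                 snp = snp, genotype = genotype, maf = maf,
                 background = background),
            class = "run_config")
}

#' Load a run configuration from YAML
#'
#' Paths in the file (cohort spec, effects, panel, map, rule) are read
#' relative to the config file's directory and must exist at validation
#' time; omitted entries fall back to the package defaults.
#'
#' @param path YAML config path.
#' @return a [run_config()].
#' @export
load_run_config <- function(path) {
  abort_if(!file.exists(path), "no such config file: ", path)
  doc <- yaml::read_yaml(path)
  base <- dirname(path)
  resolve <- function(p) {
    if (is.null(p)) return(NULL)
    full <- if (file.exists(p)) p else file.path(base, p)
    abort_if(!file.exists(full), "config references missing path: ", p)
    full
  }
  spec <- if (!is.null(doc$cohort)) read_cohort_yaml(resolve(doc$cohort)) else
    cohort_spec(seed = doc$seed %||% 1L)
  effects <- if (!is.null(doc$effects)) read_effects_yaml(resolve(doc$effects)) else
    list()
  panel <- if (!is.null(doc$panel)) {
    snp_panel(utils::read.csv(resolve(doc$panel), stringsAsFactors = FALSE))
  } else default_snp_panel()
  map <- if (!is.null(doc$category_map)) {
    as.data.frame(load_category_map(resolve(doc$category_map)))
  } else default_category_map()
  rule <- if (!is.null(doc$rule)) read_phenotype_rule(resolve(doc$rule)) else
    t2dm_rule()
  run_config(seed = doc$seed %||% 1L,
             outdir = doc$outdir %||% tempfile("fedphewas-"),
             spec = spec, effects = effects, panel = panel, map = map,
             rule = rule, model = doc$model %||% "dominant",
             adjust = doc$adjust %||% "bh",
             min_subjects = doc$min_subjects %||% 25,
             snp = doc$snp %||% "rs2476601",
             genotype = doc$genotype %||% "A:A")
}

#' Read cohort / effect specifications from YAML
#'
#' @param path YAML file path.
#' @return [read_cohort_yaml()] a [cohort_spec()]; [read_effects_yaml()] a
#'   list of [planted_effect()]s.
#' @export
read_cohort_yaml <- function(path) {
  doc <- yaml::read_yaml(path)
  sg <- do.call(rbind, lapply(doc$subgroups, function(g)
    data.frame(label = g$label, n = g$n, mean_age = g$mean_age,
               sd_age = g$sd_age, female_frac = g$female_frac,
               record_len_mean = g$record_len_mean, stringsAsFactors = FALSE)))
  cohort_spec(sg, seed = doc$seed %||% 1L)
}

#' @rdname read_cohort_yaml
#' @export
read_effects_yaml <- function(path) {
  doc <- yaml::read_yaml(path)
  lapply(doc$effects %||% doc, function(e)
    planted_effect(e$snp_id, e$risk_allele, e$category_id, e$odds_ratio,
                   e$baseline_prev))
}

## ---- virtualization of the two stores --------------------------------------

#' Relational schemas of the emulated stores
#'
#' The clinical store holds `demographics` (primary key `internalKey`) and
#' `diagnoses` (surrogate key `eventId`, foreign key `internalKey`); the
#' genotype store holds the biobank registry `subjects` and the `genotypes`
#' calls.  The registry and call tables receive surrogate integer keys at
#' virtualization time so their natural keys (`patientId`, `rsID`) remain
#' queryable as literal values — the shape the federated demonstration
#' query's FILTERs require.
#'
#' @name store_schemas
#' @keywords internal
NULL

clinical_schemas <- function() {
  list(
    demographics = table_schema(
      "demographics",
      c(internalKey = "integer", clinicNumber = "integer", age = "integer",
        sex = "text", subgroup = "text", record_len = "integer"),
      primary_key = "internalKey"),
    diagnoses = table_schema(
      "diagnoses",
      c(eventId = "integer", internalKey = "integer", icd9_code = "text",
        dx_date = "date"),
      primary_key = "eventId",
      foreign_keys = list(list(column = "internalKey",
                               ref_table = "demographics",
                               ref_column = "internalKey")))
  )
}

genotype_schemas <- function() {
  list(
    subjects = table_schema(
      "subjects",
      c(subjectId = "integer", patientId = "text", clinicNumber = "integer"),
      primary_key = "subjectId"),
    genotypes = table_schema(
      "genotypes",
      c(gtId = "integer", patientId = "text", rsID = "text",
        genotype = "text"),
      primary_key = "gtId")
  )
}

#' Virtualize a fixture bundle into two graph endpoints
#'
#' Derives the direct mappings of the clinical and genotype store schemas,
#' materializes their triples, and wraps them as the `clinical` and
#' `genotype` endpoints of a federation — the desk-scale analogue of
#' exposing two store-backed virtual RDF graphs behind SPARQL endpoints.
#'
#' @param bundle a `fixture_bundle`.
#' @param base_clinical,base_genotype base IRIs of the two stores.
#' @return named list of two [graph_endpoint()]s plus the mappings used
#'   (attribute `mappings`).
#' @export
virtualize_bundle <- function(bundle,
                              base_clinical = "http://example.org/clinical",
                              base_genotype = "http://example.org/biobank") {
  cs <- clinical_schemas()
  gs <- genotype_schemas()
  demo <- bundle$demographics
  if (!"record_len" %in% names(demo)) demo$record_len <- NA_integer_
  dx <- bundle$diagnoses
  if (!"eventId" %in% names(dx)) dx$eventId <- seq_len(nrow(dx))
  subjects <- bundle$linkage
  subjects$subjectId <- seq_len(nrow(subjects))
  gt <- bundle$genotypes
  gt$gtId <- seq_len(nrow(gt))

  m_demo <- direct_map(cs$demographics, base_clinical)
  m_dx <- direct_map(cs$diagnoses, base_clinical)
  m_subj <- direct_map(gs$subjects, base_genotype)
  m_gt <- direct_map(gs$genotypes, base_genotype)

  clinical_triples <- rbind(apply_mapping(m_demo, demo),
                            apply_mapping(m_dx, dx))
  genotype_triples <- rbind(apply_mapping(m_subj, subjects),
                            apply_mapping(m_gt, gt))
  eps <- list(clinical = graph_endpoint("clinical", clinical_triples),
              genotype = graph_endpoint("genotype", genotype_triples))
  attr(eps, "mappings") <- list(demographics = m_demo, diagnoses = m_dx,
                                subjects = m_subj, genotypes = m_gt)
  eps
}

#' Built-in federated queries
#'
#' `biobank_query()` is the demonstration query shape: the genotype SERVICE
#' stanza retrieves each biobank subject's patient id together with their
#' SNP identifiers and genotype calls (two tables joined by a local FILTER
#' on the patient id); the clinical SERVICE stanza retrieves diagnosis codes
#' joined to demographics through the internal-key reference; a cross-clause
#' FILTER joins the stores on clinic number = patient id; two selection
#' FILTERs restrict to one SNP and one exact genotype string.
#' `genotype_retrieval_query()` and `diagnosis_retrieval_query()` are the
#' unrestricted retrievals the scan stage uses.
#'
#' @param snp rsID selected by the query (e.g. `"rs2476601"`).
#' @param genotype exact genotype literal (e.g. `"A:A"`).
#' @param base_clinical,base_genotype store base IRIs (must match
#'   [virtualize_bundle()]).
#' @return a [federated_query()].
#' @export
biobank_query <- function(snp = "rs2476601", genotype = "A:A",
                          base_clinical = "http://example.org/clinical",
                          base_genotype = "http://example.org/biobank") {
  bg <- sub("/+$", "", base_genotype)
  bc <- sub("/+$", "", base_clinical)
  gclause <- service_clause(
    "genotype",
    patterns = list(
      triple_pattern("?g", paste0(bg, "/genotypes#rsID"), "?rsID"),
      triple_pattern("?g", paste0(bg, "/genotypes#genotype"), "?genotype"),
      triple_pattern("?g", paste0(bg, "/genotypes#patientId"), "?gpid"),
      triple_pattern("?s", paste0(bg, "/subjects#patientId"), "?pid")),
    filters = list(list(lhs = "?pid", op = "==", rhs = "?gpid")))
  cclause <- service_clause(
    "clinical",
    patterns = list(
      triple_pattern("?d", paste0(bc, "/diagnoses#internalKey"), "?demo"),
      triple_pattern("?d", paste0(bc, "/diagnoses#icd9_code"), "?code"),
      triple_pattern("?demo", paste0(bc, "/demographics#clinicNumber"),
                     "?cn")))
  federated_query(
    clauses = list(gclause, cclause),
    join_filters = list(list(lhs = "?pid", rhs = "?cn")),
    selection_filters = list(list(lhs = "?rsID", op = "==", rhs = snp),
                             list(lhs = "?genotype", op = "==", rhs = genotype)),
    projection = c("pid", "rsID", "genotype", "code"))
}

#' @rdname biobank_query
#' @export
genotype_retrieval_query <- function(base_genotype = "http://example.org/biobank") {
  bg <- sub("/+$", "", base_genotype)
  federated_query(
    clauses = list(service_clause(
      "genotype",
      patterns = list(
        triple_pattern("?g", paste0(bg, "/genotypes#patientId"), "?pid"),
        triple_pattern("?g", paste0(bg, "/genotypes#rsID"), "?rsID"),
        triple_pattern("?g", paste0(bg, "/genotypes#genotype"), "?genotype")))),
    projection = c("pid", "rsID", "genotype"))
}

#' @rdname biobank_query
#' @export
diagnosis_retrieval_query <- function(base_clinical = "http://example.org/clinical",
                                      base_genotype = "http://example.org/biobank") {
  bg <- sub("/+$", "", base_genotype)
  bc <- sub("/+$", "", base_clinical)
  federated_query(
    clauses = list(
      service_clause("genotype", patterns = list(
        triple_pattern("?s", paste0(bg, "/subjects#patientId"), "?pid"))),
      service_clause("clinical", patterns = list(
        triple_pattern("?d", paste0(bc, "/diagnoses#internalKey"), "?demo"),
        triple_pattern("?d", paste0(bc, "/diagnoses#icd9_code"), "?code"),
        triple_pattern("?demo", paste0(bc, "/demographics#clinicNumber"),
                       "?cn")))),
    join_filters = list(list(lhs = "?pid", rhs = "?cn")),
    projection = c("pid", "code"))
}

## ---- pipeline commands -----------------------------------------------------

config_fingerprint <- function(config) {
  slim <- list(seed = config$seed, model = config$model,
               adjust = config$adjust, min_subjects = config$min_subjects,
               snp = config$snp, genotype = config$genotype,
               subgroups = config$spec$subgroups,
               effects = lapply(config$effects, unclass))
  fnv1a32(jsonlite::toJSON(slim, auto_unbox = TRUE, digits = NA))
}

write_manifest <- function(config, stage, files) {
  manifest <- list(stage = stage, seed = config$seed,
                   config_hash = config_fingerprint(config),
                   package_version = as.character(utils::packageVersion("fedphewas")),
                   files = as.list(files))
  path <- file.path(config$outdir, paste0(stage, "-manifest.json"))
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' Pipeline stage: generate the synthetic bundle
#'
#' @param config a [run_config()].
#' @return the `fixture_bundle`, invisibly; files are written under
#'   `config$outdir/bundle` with a stage manifest.
#' @export
cmd_generate <- function(config) {
  abort_if(!inherits(config, "run_config"), "config must be a run_config")
  bundle <- generate_bundle(spec = config$spec, panel = config$panel,
                            maf = config$maf, effects = config$effects,
                            map = config$map, background = config$background,
                            model = if (config$model == "genotypic-exact")
                              "dominant" else config$model)
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  paths <- write_fixture_bundle(bundle, file.path(config$outdir, "bundle"))
  write_manifest(config, "generate", paths)
  invisible(bundle)
}

#' Pipeline stage: virtualize and run the demonstration query
#'
#' Virtualizes both stores, runs the built-in federated query restricted to
#' `config$snp` / `config$genotype` (or a query file parsed by
#' [parse_query()]), and writes the bindings as CSV.
#'
#' @param config a [run_config()].
#' @param bundle optional in-memory bundle (else read from
#'   `config$outdir/bundle`).
#' @param query_file optional path to a query in the minimal concrete
#'   syntax.
#' @return the bindings data.frame, invisibly.
#' @export
cmd_query <- function(config, bundle = NULL, query_file = NULL) {
  abort_if(!inherits(config, "run_config"), "config must be a run_config")
  if (is.null(bundle)) bundle <- read_fixture_bundle(file.path(config$outdir, "bundle"))
  endpoints <- virtualize_bundle(bundle)
  query <- if (is.null(query_file)) {
    biobank_query(config$snp, config$genotype)
  } else {
    parse_query(query_file)
  }
  message(paste(plan_summary(query), collapse = "\n"))
  bindings <- run_federated(query, endpoints)
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  out <- file.path(config$outdir, "bindings.csv")
  write_bindings(bindings, out)
  write_manifest(config, "query", out)
  invisible(bindings)
}

#' Pipeline stage: end-to-end phenome scan
#'
#' Generates (or loads) the bundle, virtualizes both stores, retrieves the
#' genotype calls and the federated diagnosis bindings, classifies the
#' cohort under the phenotyping rule, clusters diagnoses into phenome
#' categories, applies the retention threshold, scans every panel SNP
#' against every retained cluster and writes the results table, the plot
#' export and a manifest.
#'
#' @param config a [run_config()].
#' @param bundle optional in-memory bundle (else generated from the config).
#' @return list with `bundle`, `status`, `clusters` (retained), `results`,
#'   invisibly.
#' @export
cmd_scan <- function(config, bundle = NULL) {
  abort_if(!inherits(config, "run_config"), "config must be a run_config")
  if (is.null(bundle)) bundle <- cmd_generate(config)
  endpoints <- virtualize_bundle(bundle)

  genotype_bindings <- run_federated(genotype_retrieval_query(), endpoints)
  names(genotype_bindings) <- c("patientId", "rsID", "genotype")
  dx_bindings <- run_federated(diagnosis_retrieval_query(), endpoints)
  names(dx_bindings) <- c("subject", "code")

  status <- classify_cohort(bundle$diagnoses, config$rule,
                            subjects = bundle$demographics$internalKey)
  clusters <- cluster_subjects(dx_bindings, category_map(bundle$category_map))
  retained <- filter_clusters(clusters, config$min_subjects)
  abort_if(length(retained) == 0,
           "no cluster reaches the retention threshold of ",
           config$min_subjects, " subjects")
  results <- phewas_scan(genotype_bindings, retained, panel = bundle$panel,
                         model = config$model, adjust = config$adjust)

  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  files <- c(results = file.path(config$outdir, "scan-results.tsv"),
             plotdata = file.path(config$outdir, "scan-plotdata.tsv"),
             clusters = file.path(config$outdir, "clusters.tsv"),
             status = file.path(config$outdir, "phenotype-status.csv"))
  write_phewas_results(results, files[["results"]])
  manhattan_export(results, files[["plotdata"]])
  write_cluster_report(retained, files[["clusters"]])
  utils::write.csv(status, files[["status"]], row.names = FALSE)
  write_manifest(config, "scan", files)
  invisible(list(bundle = bundle, status = status, clusters = retained,
                 results = results))
}
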