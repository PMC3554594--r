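#' Phenotyping rule
#'
#' A code-count surrogate for consortium EHR phenotyping algorithms: a
#' subject is a case when at least `min_case_events` diagnosis events match
#' a case code prefix and no exclusion prefix matches; a control when no
#' case or exclusion prefix matches at all (with `control_requires_zero`);
#' anything else is unknown.  Richer criteria (medications, labs, notes) are
#' outside this rule's vocabulary by design — the rule is externalized to
#' YAML so sites can configure what their data supports.
#'
#' @param disease_label free-text label.
#' @param case_codes character vector of ICD-9-CM code prefixes.
#' @param min_case_events minimum number of matching events for case status
#'   (>= 1).
#' @param exclusion_codes prefixes that veto case status.
#' @param control_requires_zero when TRUE (default) controls must have zero
#'   case-prefix and zero exclusion-prefix events; when FALSE every non-case
#'   is a control.
#' @return object of class `phenotype_rule`.
#' @export
phenotype_rule <- function(disease_label, case_codes, min_case_events = 2L,
                           exclusion_codes = character(0),
                           control_requires_zero = TRUE) {
  abort_if(length(case_codes) == 0 || !all(nzchar(case_codes)),
           "rule must list at least one non-empty case code prefix")
  abort_if(!is_count(min_case_events) || min_case_events < 1,
           "min_case_events must be >= 1")
  abort_if(length(intersect(case_codes, exclusion_codes)) > 0,
           "case and exclusion prefixes must be disjoint")
  structure(list(disease_label = disease_label,
                 case_codes = as.character(case_codes),
                 min_case_events = as.integer(min_case_events),
                 exclusion_codes = as.character(exclusion_codes),
                 control_requires_zero = isTRUE(control_requires_zero)),
            class = "phenotype_rule")
}

#' @rdname phenotype_rule
#' @export
t2dm_rule <- function() {
  phenotype_rule("type 2 diabetes mellitus", case_codes = "250",
                 min_case_events = 2L)
}

#' @rdname phenotype_rule
#' @export
hypothyroidism_rule <- function() {
  phenotype_rule("hypothyroidism", case_codes = "244", min_case_events = 2L)
}

matches_prefix <- function(codes, prefixes) {
  if (length(codes) == 0) return(logical(0))
  hit <- rep(FALSE, length(codes))
  for (p in prefixes) hit <- hit | startsWith(codes, p)
  hit
}

#' Classify one subject's diagnosis history
#'
#' @param codes character vector of the subject's ICD-9-CM codes (one entry
#'   per event; empty vector = no events).
#' @param rule a [phenotype_rule()].
#' @return `"case"`, `"control"` or `"unknown"`.
#' @examples
#' classify_subject(c("250.00", "250.02"), t2dm_rule())  # "case"
#' @export
classify_subject <- function(codes, rule) {
  abort_if(!inherits(rule, "phenotype_rule"), "rule must be a phenotype_rule")
  codes <- as.character(codes)
  n_case <- sum(matches_prefix(codes, rule$case_codes))
  n_excl <- sum(matches_prefix(codes, rule$exclusion_codes))
  if (n_case >= rule$min_case_events && n_excl == 0) return("case")
  if (rule$control_requires_zero) {
    if (n_case == 0 && n_excl == 0) return("control")
    return("unknown")
  }
  "control"
}

#' Classify a whole cohort
#'
#' Applies the rule per subject over a diagnosis table.  Subjects listed in
#' `subjects` but absent from the table classify on an empty history (i.e.
#' control under the default rule shape).
#'
#' @param diagnoses data.frame with subject-id and code columns (defaults:
#'   `internalKey`, `icd9_code`).
#' @param rule a [phenotype_rule()].
#' @param subjects optional vector of all subject ids to classify.
#' @param id_col,code_col column names in `diagnoses`.
#' @return data.frame `subject`, `status`; case/control/unknown counts are
#'   reported via `message()`.
#' @export
classify_cohort <- function(diagnoses, rule, subjects = NULL,
                            id_col = "internalKey", code_col = "icd9_code") {
  abort_if(!all(c(id_col, code_col) %in% names(diagnoses)),
           "diagnoses must have columns ", id_col, " and ", code_col)
  ids <- as.character(diagnoses[[id_col]])
  codes <- as.character(diagnoses[[code_col]])
  all_subjects <- if (is.null(subjects)) unique(ids) else
    unique(as.character(subjects))
  by_subject <- split(codes, factor(ids, levels = all_subjects))
  status <- vapply(all_subjects, function(s)
    classify_subject(by_subject[[s]], rule), character(1))
  out <- data.frame(subject = all_subjects, status = unname(status),
                    stringsAsFactors = FALSE)
  counts <- table(factor(out$status, levels = c("case", "control", "unknown")))
  message(rule$disease_label, ": ", counts[["case"]], " cases, ",
          counts[["control"]], " controls, ", counts[["unknown"]], " unknown")
  out
}

#' Read / write phenotyping rules as YAML
#'
#' @param path YAML file path.
#' @param rule a [phenotype_rule()].
#' @return [read_phenotype_rule()] returns a `phenotype_rule`.
#' @export
read_phenotype_rule <- function(path) {
  doc <- yaml::read_yaml(path)
  phenotype_rule(doc$disease_label %||% "unnamed",
                 unlist(doc$case_codes),
                 doc$min_case_events %||% 2L,
                 unlist(doc$exclusion_codes) %||% character(0),
                 doc$control_requires_zero %||% TRUE)
}

#' @rdname read_phenotype_rule
#' @export
write_phenotype_rule <- function(rule, path) {
  yaml::write_yaml(list(disease_label = rule$disease_label,
                        case_codes = as.list(rule$case_codes),
                        min_case_events = rule$min_case_events,
                        exclusion_codes = as.list(rule$exclusion_codes),
                        control_requires_zero = rule$control_requires_zero),
                   path)
  invisible(path)
}
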