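#' Validate a diagnosis-category map
#'
#' A category map assigns each ICD-9-CM code to exactly one category
#' (mutual exclusivity, as in single-level CCS).  A code appearing twice
#' with conflicting categories is rejected; exact duplicate rows collapse.
#'
#' @param entries data.frame with columns `code`, `category_id`, `label`.
#' @return the validated map (class `category_map`, still a data.frame).
#' @export
category_map <- function(entries) {
  abort_if(!is.data.frame(entries) ||
             !all(c("code", "category_id", "label") %in% names(entries)),
           "category map needs columns code, category_id, label")
  entries$code <- as.character(entries$code)
  entries$category_id <- as.character(entries$category_id)
  entries <- unique(entries[, c("code", "category_id", "label")])
  dup <- entries$code[duplicated(entries$code)]
  abort_if(length(dup) > 0,
           "code(s) mapped to more than one category (mutual exclusivity ",
           "violated): ", paste(unique(dup), collapse = ", "))
  rownames(entries) <- NULL
  class(entries) <- c("category_map", "data.frame")
  entries
}

#' Load a category map from disk
#'
#' Accepts two dialects: the plain fixture dialect (`code,category_id,label`
#' CSV with a header) and the single-level CCS distribution dialect, whose
#' fields are wrapped in single quotes with stray padding (e.g.
#' `'25000','49','Diabetes mellitus without complication'`); codes in the
#' CCS dialect may carry trailing blanks inside the quotes.
#'
#' @param path CSV file path.
#' @return a [category_map()].
#' @export
load_category_map <- function(path) {
  abort_if(!file.exists(path), "no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  abort_if(length(lines) == 0, "empty category-map file: ", path)
  if (grepl("'", lines[min(2, length(lines))], fixed = TRUE)) {
    # CCS single-level dialect: data rows start with a quoted ICD-9-CM code
    # (digits or a V/E prefix); header lines do not and are skipped
    data_lines <- which(grepl("^\\s*'\\s*[VE]?[0-9]", lines))
    rows <- lapply(data_lines, function(i) {
      fields <- regmatches(lines[i], gregexpr("'[^']*'", lines[i]))[[1]]
      if (length(fields) < 3) {
        stop("line ", i, ": malformed CCS row (need >= 3 quoted fields)",
             call. = FALSE)
      }
      vals <- trimws(gsub("'", "", fields))
      data.frame(code = vals[1], category_id = vals[2],
                 label = paste(vals[3:length(vals)], collapse = " "),
                 stringsAsFactors = FALSE)
    })
    return(category_map(do.call(rbind, rows)))
  }
  df <- tryCatch(
    utils::read.csv(path, stringsAsFactors = FALSE,
                    colClasses = "character"),
    error = function(e) stop("cannot parse ", path, ": ", conditionMessage(e),
                             call. = FALSE))
  bad <- which(is.na(df$code) | !nzchar(df$code))
  abort_if(length(bad) > 0,
           "line ", bad[1] + 1L, ": malformed row (empty code)")
  category_map(df)
}

#' @rdname load_category_map
#' @param map a `category_map`.
#' @export
write_category_map <- function(map, path) {
  utils::write.csv(as.data.frame(map)[, c("code", "category_id", "label")],
                   path, row.names = FALSE)
  invisible(path)
}

#' Cluster subjects into phenome categories
#'
#' Groups diagnosis bindings (subject, code pairs from the federated query)
#' by mapped category.  A subject is counted once per category regardless of
#' event multiplicity; a subject with codes in k categories appears in k
#' clusters.  Codes absent from the map are routed to an `"unmapped"`
#' bucket and reported via a warning — never silently dropped.
#'
#' @param bindings data.frame whose first two columns (or columns named
#'   `subject`/`code`) give subject id and ICD-9-CM code; duplicates allowed.
#' @param map a [category_map()].
#' @return object of class `phenotype_clusters`: a list of clusters, each
#'   with `category_id`, `label`, `subjects` (distinct ids), `n_subjects`
#'   and `n_events` (rows attributed to the cluster).
#' @export
cluster_subjects <- function(bindings, map) {
  map <- category_map(as.data.frame(map))
  if (!all(c("subject", "code") %in% names(bindings))) {
    abort_if(ncol(bindings) < 2,
             "bindings must have subject and code columns")
    names(bindings)[1:2] <- c("subject", "code")
  }
  subject <- as.character(bindings$subject)
  code <- as.character(bindings$code)
  idx <- match(code, map$code)
  cat_id <- ifelse(is.na(idx), "unmapped", map$category_id[idx])
  n_unmapped <- sum(is.na(idx))
  if (n_unmapped > 0) {
    warning(n_unmapped, " event(s) with ",
            length(unique(code[is.na(idx)])),
            " code(s) not in the category map; routed to 'unmapped'",
            call. = FALSE)
  }
  labels <- c(stats::setNames(map$label[!duplicated(map$category_id)],
                              map$category_id[!duplicated(map$category_id)]),
              unmapped = "Unmapped diagnosis codes")
  ids <- unique(cat_id)
  ids <- c(sort(setdiff(ids, "unmapped"), method = "radix"),
           intersect("unmapped", ids))
  clusters <- lapply(ids, function(id) {
    rows <- cat_id == id
    subs <- unique(subject[rows])
    structure(list(category_id = id, label = unname(labels[[id]]),
                   subjects = subs, n_subjects = length(subs),
                   n_events = sum(rows)),
              class = "phenotype_cluster")
  })
  structure(clusters, class = "phenotype_clusters")
}

#' @export
print.phenotype_clusters <- function(x, ...) {
  cat("Phenome clusters:", length(x), "categories\n")
  df <- as.data.frame(x)
  print(df, row.names = FALSE)
  invisible(x)
}

#' @export
as.data.frame.phenotype_clusters <- function(x, ...) {
  data.frame(category_id = vapply(x, `[[`, character(1), "category_id"),
             label = vapply(x, `[[`, character(1), "label"),
             n_subjects = vapply(x, `[[`, integer(1), "n_subjects"),
             n_events = vapply(x, function(cl) as.integer(cl$n_events),
                               integer(1)),
             stringsAsFactors = FALSE)
}

#' Retain clusters by minimum subject count
#'
#' Clusters with fewer subjects than the threshold are dropped, the standard
#' minimum-cell-size rule for a phenome scan; the default of 25 excludes
#' exactly the clusters having less than 25 subjects.  Order is preserved.
#'
#' @param clusters a `phenotype_clusters` object (or plain list of clusters).
#' @param min_subjects retention threshold; a cluster is kept iff
#'   `n_subjects >= min_subjects`.
#' @return filtered `phenotype_clusters`.
#' @export
filter_clusters <- function(clusters, min_subjects = 25) {
  abort_if(!is.numeric(min_subjects) || min_subjects < 0,
           "min_subjects must be >= 0")
  keep <- vapply(clusters, function(cl) cl$n_subjects >= min_subjects,
                 logical(1))
  structure(unclass(clusters)[keep], class = "phenotype_clusters")
}

#' Write a cluster report
#'
#' @param clusters a `phenotype_clusters` object.
#' @param path TSV output path.
#' @export
write_cluster_report <- function(clusters, path) {
  utils::write.table(as.data.frame(clusters), path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}
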