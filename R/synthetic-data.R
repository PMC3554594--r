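#' Cohort specification for the synthetic EHR-linked biobank
#'
#' Describes the study subgroups of the emulated biobank cohort.  The default
#' reproduces the published composition of the emulated genome-consortium
#' phase-I cohort: five subgroups (peripheral-arterial-disease cases and
#' controls, venous-thromboembolism cases and controls, and pancreatic-cancer
#' controls) totalling 6,307 unique participants, with the published per-group
#' mean/SD age, female fraction and mean medical-record length.
#'
#' @param subgroups data.frame with columns `label`, `n`, `mean_age`,
#'   `sd_age`, `female_frac`, `record_len_mean` (record length in years).
#' @param seed integer master seed; every downstream draw derives its stream
#'   from it.
#' @return An object of class `cohort_spec`.
#' @examples
#' spec <- cohort_spec()
#' sum(spec$subgroups$n)  # 6307
#' @export
cohort_spec <- function(subgroups = default_subgroups(), seed = 1L) {
  abort_if(!is.data.frame(subgroups), "subgroups must be a data.frame")
  need <- c("label", "n", "mean_age", "sd_age", "female_frac", "record_len_mean")
  miss <- setdiff(need, names(subgroups))
  abort_if(length(miss) > 0,
           "subgroups is missing column(s): ", paste(miss, collapse = ", "))
  abort_if(any(is.na(subgroups$n)) || any(subgroups$n < 0) ||
             any(subgroups$n != floor(subgroups$n)),
           "subgroup sizes n must be non-negative integers")
  abort_if(any(subgroups$female_frac < 0 | subgroups$female_frac > 1),
           "female_frac must lie in [0, 1]")
  abort_if(any(subgroups$sd_age < 0), "sd_age must be >= 0")
  abort_if(any(duplicated(subgroups$label)), "subgroup labels must be unique")
  abort_if(!is_count(abs(seed)), "seed must be a single integer")
  structure(list(subgroups = subgroups, seed = as.integer(seed)),
            class = "cohort_spec")
}

#' @rdname cohort_spec
#' @export
default_subgroups <- function() {
  data.frame(
    label = c("PAD_case", "PAD_control", "VTE_case", "VTE_control",
              "PANC_control"),
    n = c(1612L, 1585L, 1233L, 1264L, 613L),
    mean_age = c(66, 61, 55, 56, 66),
    sd_age = c(10.7, 7.4, 16.2, 15.8, 10.0),
    female_frac = c(0.36, 0.40, 0.50, 0.52, 0.45),
    record_len_mean = c(23.4, 26.1, 13.7, 21.1, 30.2),
    stringsAsFactors = FALSE
  )
}

#' @export
print.cohort_spec <- function(x, ...) {
  cat("Synthetic biobank cohort spec:", sum(x$subgroups$n),
      "subjects in", nrow(x$subgroups), "subgroups (seed", x$seed, ")\n")
  print(x$subgroups, row.names = FALSE)
  invisible(x)
}

#' Default SNP scan panel
#'
#' The eight SNPs scanned in the phenome-wide analyses this package emulates:
#' four type-2-diabetes loci (KCNJ11 rs5219, TCF7L2 rs7903146 and rs12255372,
#' SLC30A8 rs13266634) and four thyroid-disorder loci (FOXE1 rs965513 and
#' rs7850258, PTPN22 rs2476601, TG rs2069561).  Risk/other alleles and the
#' per-SNP minor-allele frequencies used by the genotype generator are
#' package defaults for synthetic data, not estimates from any cohort.
#'
#' @return data.frame with columns `snp_id`, `gene_symbol`, `risk_allele`,
#'   `other_allele`, `trait_label`.
#' @examples
#' nrow(default_snp_panel())  # 8
#' @export
default_snp_panel <- function() {
  data.frame(
    snp_id = c("rs5219", "rs7903146", "rs12255372", "rs13266634",
               "rs965513", "rs7850258", "rs2476601", "rs2069561"),
    gene_symbol = c("KCNJ11", "TCF7L2", "TCF7L2", "SLC30A8",
                    "FOXE1", "FOXE1", "PTPN22", "TG"),
    risk_allele = c("T", "T", "T", "C", "A", "G", "A", "A"),
    other_allele = c("C", "C", "G", "T", "G", "A", "G", "C"),
    trait_label = c("T2DM", "T2DM", "T2DM", "T2DM",
                    "hypothyroidism", "hypothyroidism", "hypothyroidism",
                    "hypothyroidism"),
    stringsAsFactors = FALSE
  )
}

#' Validate a SNP panel table
#'
#' @param panel data.frame with at least `snp_id`, `risk_allele`,
#'   `other_allele`; `gene_symbol`/`trait_label` are carried through.
#' @return the validated panel (invisibly the same data.frame).
#' @export
snp_panel <- function(panel) {
  abort_if(!is.data.frame(panel) || nrow(panel) == 0, "panel must be a non-empty data.frame")
  need <- c("snp_id", "risk_allele", "other_allele")
  miss <- setdiff(need, names(panel))
  abort_if(length(miss) > 0, "panel missing column(s): ", paste(miss, collapse = ", "))
  abort_if(any(duplicated(panel$snp_id)), "panel snp_ids must be unique")
  abort_if(!all(grepl("^rs[0-9]+$", panel$snp_id)),
           "snp_id must match rs[0-9]+")
  abort_if(!all(panel$risk_allele %in% c("A", "C", "G", "T")) ||
             !all(panel$other_allele %in% c("A", "C", "G", "T")),
           "alleles must be one of A/C/G/T")
  abort_if(any(panel$risk_allele == panel$other_allele),
           "risk and other allele must differ")
  panel
}

#' Default per-SNP minor-allele frequencies
#'
#' Fixed, realistic frequencies for the default panel (the risk allele is
#' treated as the minor allele in the generator).  rs2476601 is deliberately
#' rare, which is what makes its homozygous-risk stratum small.
#'
#' @param panel a SNP panel data.frame.
#' @return named numeric vector of minor-allele frequencies.
#' @export
default_maf <- function(panel = default_snp_panel()) {
  defaults <- c(rs5219 = 0.36, rs7903146 = 0.30, rs12255372 = 0.29,
                rs13266634 = 0.31, rs965513 = 0.34, rs7850258 = 0.35,
                rs2476601 = 0.09, rs2069561 = 0.30)
  out <- defaults[panel$snp_id]
  out[is.na(out)] <- 0.25
  names(out) <- panel$snp_id
  out
}

#' Planted genotype-phenotype effect
#'
#' Encodes the simulation ground truth that a downstream scan estimates: a
#' SNP whose risk-allele carriers have elevated odds of membership in one
#' phenome category.  Membership is drawn per subject from a logistic model,
#' `logit(p) = logit(baseline_prev) + log(odds_ratio) * dosage`, with dosage
#' defined by the configured genetic model (dominant by default).
#'
#' @param snp_id rsID (must match `rs[0-9]+`).
#' @param risk_allele one of A/C/G/T.
#' @param category_id phenome-category id the effect targets.
#' @param odds_ratio positive real; 1 means no effect.
#' @param baseline_prev baseline category prevalence in non-carriers,
#'   strictly inside (0, 1).
#' @return object of class `planted_effect`.
#' @export
planted_effect <- function(snp_id, risk_allele, category_id, odds_ratio,
                           baseline_prev) {
  abort_if(!is_string(snp_id) || !grepl("^rs[0-9]+$", snp_id),
           "snp_id must match rs[0-9]+")
  abort_if(!risk_allele %in% c("A", "C", "G", "T"), "risk_allele must be A/C/G/T")
  abort_if(!is.numeric(odds_ratio) || odds_ratio <= 0, "odds_ratio must be > 0")
  abort_if(!is.numeric(baseline_prev) || baseline_prev <= 0 || baseline_prev >= 1,
           "baseline_prev must be in (0, 1)")
  structure(list(snp_id = snp_id, risk_allele = risk_allele,
                 category_id = as.character(category_id),
                 odds_ratio = odds_ratio, baseline_prev = baseline_prev),
            class = "planted_effect")
}

#' Bundled diagnosis-category dictionary
#'
#' A small fixture dictionary of ICD-9-CM diagnosis codes grouped into
#' mutually exclusive single-level categories in the style of the AHRQ
#' Clinical Classifications Software (CCS).  It stands in for the full
#' 285-category diagnosis table, which is an external, version-dependent
#' download; category ids follow the single-level CCS numbering where a
#' natural match exists.  The `baseline_prev` column is the generator's
#' default background prevalence per category and is ignored by the
#' clustering stage.
#'
#' @return data.frame with columns `code`, `category_id`, `label`,
#'   `baseline_prev`: 60 codes in 15 categories.
#' @export
default_category_map <- function() {
  rows <- list(
    list("49",  "Diabetes mellitus without complication", 0.12,
         c("250.00", "250.01", "250.02", "250.03")),
    list("50",  "Diabetes mellitus with complications", 0.05,
         c("250.40", "250.50", "250.60", "250.70")),
    list("53",  "Disorders of lipid metabolism", 0.30,
         c("272.0", "272.1", "272.2", "272.4")),
    list("98",  "Essential hypertension", 0.35,
         c("401.0", "401.1", "401.9")),
    list("48",  "Thyroid disorders", 0.10,
         c("244.0", "244.1", "244.9", "245.2", "242.90")),
    list("96",  "Heart valve disorders", 0.06,
         c("424.0", "424.1", "424.2", "394.0")),
    list("101", "Coronary atherosclerosis", 0.18,
         c("414.00", "414.01", "412", "413.9")),
    list("108", "Congestive heart failure", 0.07,
         c("428.0", "428.1", "428.9")),
    list("118", "Phlebitis and thrombophlebitis", 0.08,
         c("451.11", "451.19", "453.40", "453.8")),
    list("127", "Chronic obstructive pulmonary disease", 0.09,
         c("491.21", "492.8", "496", "493.20")),
    list("200", "Other skin disorders", 0.20,
         c("701.1", "702.0", "706.2", "709.9", "700")),
    list("205", "Spondylosis and back problems", 0.22,
         c("721.0", "722.10", "724.2", "724.5")),
    list("89",  "Blindness and vision defects", 0.08,
         c("367.0", "367.1", "368.8", "369.9")),
    list("58",  "Nutritional and metabolic disorders", 0.10,
         c("278.00", "278.01", "276.1", "268.9")),
    list("663", "Screening and history of mental health codes", 0.05,
         c("V15.82", "305.1", "V79.0", "V11.3"))
  )
  out <- do.call(rbind, lapply(rows, function(r) {
    data.frame(code = r[[4]], category_id = r[[1]], label = r[[2]],
               baseline_prev = r[[3]], stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Generate the synthetic clinical cohort
#'
#' Draws one demographics row per subject and the biobank linkage table.
#' `internalKey` is the clinical-store primary key; `clinicNumber` the
#' institution-wide patient number; the genotype store addresses the same
#' person by `patientId`, which the linkage table maps onto `clinicNumber`
#' (stored as text there, exercising the cross-store key canonicalization
#' that federation performs).
#'
#' @param spec a [cohort_spec()].
#' @param biobank_frac fraction of subjects enrolled in the biobank (and
#'   hence present in the linkage table); default 1 = total overlap.
#' @return list with `demographics` (internalKey, clinicNumber, age, sex,
#'   subgroup, record_len) and `linkage` (clinicNumber, patientId).
#' @examples
#' ch <- generate_cohort(cohort_spec(seed = 7))
#' nrow(ch$demographics)
#' @export
generate_cohort <- function(spec, biobank_frac = 1) {
  abort_if(!inherits(spec, "cohort_spec"), "spec must be a cohort_spec")
  abort_if(biobank_frac < 0 || biobank_frac > 1, "biobank_frac must be in [0, 1]")
  sg <- spec$subgroups
  n_total <- sum(sg$n)
  if (n_total == 0) {
    demo <- data.frame(internalKey = integer(0), clinicNumber = integer(0),
                       age = integer(0), sex = character(0),
                       subgroup = character(0), record_len = integer(0),
                       stringsAsFactors = FALSE)
    link <- data.frame(clinicNumber = integer(0), patientId = character(0),
                       stringsAsFactors = FALSE)
    return(list(demographics = demo, linkage = link))
  }
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(sub_seed(spec$seed, "cohort"))

  idx <- rep(seq_len(nrow(sg)), times = sg$n)
  age <- round(pmin(100, pmax(18, stats::rnorm(n_total, sg$mean_age[idx],
                                               sg$sd_age[idx]))))
  sex <- ifelse(stats::runif(n_total) < sg$female_frac[idx], "F", "M")
  # record length: truncated normal around the subgroup mean, floor 1 year
  rl <- round(pmax(1, stats::rnorm(n_total, sg$record_len_mean[idx],
                                   0.6 * sg$record_len_mean[idx])))
  demo <- data.frame(
    internalKey = 1000000L + seq_len(n_total),
    clinicNumber = 5000000L + seq_len(n_total),
    age = as.integer(age), sex = sex, subgroup = sg$label[idx],
    record_len = as.integer(rl), stringsAsFactors = FALSE
  )
  in_bb <- if (biobank_frac >= 1) rep(TRUE, n_total) else
    stats::runif(n_total) < biobank_frac
  link <- data.frame(clinicNumber = demo$clinicNumber[in_bb],
                     patientId = as.character(demo$clinicNumber[in_bb]),
                     stringsAsFactors = FALSE)
  list(demographics = demo, linkage = link)
}

#' Generate genotype calls under Hardy-Weinberg equilibrium
#'
#' One row per (patientId, SNP).  The two alleles are drawn independently
#' with the stated minor-allele frequency, and the genotype string is the
#' two alleles sorted lexicographically, joined by a colon (the exact-string
#' form the federated query compares against, e.g. `"A:A"`).
#'
#' @param linkage linkage table from [generate_cohort()] (column `patientId`).
#' @param panel SNP panel (see [default_snp_panel()]).
#' @param maf named per-SNP minor-allele frequency vector, or one value for
#'   all panel SNPs; every value must be in (0, 0.5].
#' @param seed integer seed.
#' @return data.frame `patientId`, `rsID`, `genotype`.
#' @export
generate_genotypes <- function(linkage, panel = default_snp_panel(),
                               maf = default_maf(panel), seed = 1L) {
  panel <- snp_panel(panel)
  if (length(maf) == 1L && is.null(names(maf))) {
    maf <- stats::setNames(rep(maf, nrow(panel)), panel$snp_id)
  }
  unknown <- setdiff(names(maf), panel$snp_id)
  abort_if(length(unknown) > 0,
           "maf names not in panel: ", paste(unknown, collapse = ", "))
  missing <- setdiff(panel$snp_id, names(maf))
  abort_if(length(missing) > 0,
           "maf missing for panel SNP(s): ", paste(missing, collapse = ", "))
  abort_if(any(maf <= 0 | maf > 0.5), "every maf must be in (0, 0.5]")

  pid <- as.character(linkage$patientId)
  n <- length(pid)
  if (n == 0) {
    return(data.frame(patientId = character(0), rsID = character(0),
                      genotype = character(0), stringsAsFactors = FALSE))
  }
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(sub_seed(seed, "genotypes"))

  out <- vector("list", nrow(panel))
  for (i in seq_len(nrow(panel))) {
    snp <- panel$snp_id[i]
    p <- maf[[snp]]
    minor <- panel$risk_allele[i]
    major <- panel$other_allele[i]
    a1 <- ifelse(stats::runif(n) < p, minor, major)
    a2 <- ifelse(stats::runif(n) < p, minor, major)
    gt <- paste(pmin(a1, a2), pmax(a1, a2), sep = ":")
    out[[i]] <- data.frame(patientId = pid, rsID = snp, genotype = gt,
                           stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

# risk-allele dosage of a genotype string under a genetic model
allele_dosage <- function(genotype, risk_allele, model = "dominant") {
  alleles <- strsplit(genotype, ":", fixed = TRUE)
  count <- vapply(alleles, function(a) sum(a == risk_allele), numeric(1))
  switch(model,
         additive = count,
         dominant = as.numeric(count >= 1),
         recessive = as.numeric(count == 2),
         stop("unknown genetic model: ", model, call. = FALSE))
}

#' Generate the synthetic diagnosis table
#'
#' Every subject acquires membership in each phenome category by a Bernoulli
#' draw whose log-odds are the category's baseline log-odds plus
#' `log(odds_ratio) * dosage` summed over planted effects targeting the
#' category (dosage under `model`).  Members receive 1 to `max_events`
#' diagnosis events with concrete ICD-9-CM codes of that category, dated
#' uniformly within the subject's record length.
#'
#' @param demographics,linkage,genotypes tables from the generators above.
#' @param effects list of [planted_effect()] objects (may be empty).
#' @param map category dictionary data.frame (`code`, `category_id`, `label`,
#'   optionally `baseline_prev`); codes per category are drawn from it.
#' @param background named per-category baseline prevalence; defaults to the
#'   map's `baseline_prev` column (0 prevalence categories draw no members).
#' @param model genetic model for the planted dosage: "dominant" (default),
#'   "additive" or "recessive".
#' @param max_events most diagnosis events per member per category.
#' @param seed integer seed.
#' @return data.frame `eventId`, `internalKey`, `icd9_code`, `dx_date`.
#' @export
generate_diagnoses <- function(demographics, linkage, genotypes,
                               effects = list(),
                               map = default_category_map(),
                               background = NULL,
                               model = "dominant", max_events = 3L,
                               seed = 1L) {
  abort_if(!is.data.frame(map) ||
             !all(c("code", "category_id") %in% names(map)),
           "map must have columns code and category_id")
  cats <- unique(map$category_id)
  if (is.null(background)) {
    background <- if ("baseline_prev" %in% names(map)) {
      stats::setNames(map$baseline_prev[!duplicated(map$category_id)], cats)
    } else {
      stats::setNames(rep(0.1, length(cats)), cats)
    }
  }
  abort_if(is.null(names(background)) && length(background) != 1,
           "background must be named per category (or a single value)")
  if (length(background) == 1L && is.null(names(background))) {
    background <- stats::setNames(rep(background, length(cats)), cats)
  }
  for (e in effects) {
    abort_if(!inherits(e, "planted_effect"), "effects must be planted_effect objects")
    abort_if(!e$category_id %in% cats,
             "effect category ", e$category_id, " has no codes in the map")
    abort_if(!e$snp_id %in% unique(genotypes$rsID),
             "effect SNP ", e$snp_id, " absent from the genotype table")
  }

  n <- nrow(demographics)
  empty <- data.frame(eventId = integer(0), internalKey = integer(0),
                      icd9_code = character(0), dx_date = character(0),
                      stringsAsFactors = FALSE)
  if (n == 0) return(empty)

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(sub_seed(seed, "diagnoses"))

  # patientId of each demographics row (NA when not biobank-linked)
  pid <- linkage$patientId[match(demographics$clinicNumber, linkage$clinicNumber)]

  # per-category planted log-odds shift for each subject
  effect_shift <- function(cat_id) {
    shift <- numeric(n)
    for (e in effects) {
      if (e$category_id != cat_id) next
      g <- genotypes[genotypes$rsID == e$snp_id, ]
      gt <- g$genotype[match(pid, g$patientId)]
      dos <- ifelse(is.na(gt), 0, allele_dosage(ifelse(is.na(gt), "N:N", gt),
                                                e$risk_allele, model))
      shift <- shift + log(e$odds_ratio) * dos
    }
    shift
  }

  record_len <- if ("record_len" %in% names(demographics)) {
    demographics$record_len
  } else rep(10, n)
  start_date <- as.Date("1995-01-01")

  pieces <- list()
  for (cat_id in cats) {
    base <- if (cat_id %in% names(background)) background[[cat_id]] else 0
    eff <- effect_shift(cat_id)
    p <- if (base <= 0) {
      ifelse(eff > 0, stats::plogis(stats::qlogis(1e-12) + eff), 0)
    } else {
      stats::plogis(stats::qlogis(base) + eff)
    }
    member <- stats::runif(n) < p
    m <- sum(member)
    if (m == 0) next
    k <- sample.int(max_events, m, replace = TRUE)
    codes <- map$code[map$category_id == cat_id]
    rows_idx <- rep(which(member), times = k)
    total <- length(rows_idx)
    dx_code <- sample(codes, total, replace = TRUE)
    offset <- stats::runif(total) * record_len[rows_idx] * 365.25
    dx_date <- format(start_date + floor(offset), "%Y-%m-%d")
    pieces[[length(pieces) + 1L]] <- data.frame(
      internalKey = demographics$internalKey[rows_idx],
      icd9_code = dx_code, dx_date = dx_date, stringsAsFactors = FALSE)
  }
  if (length(pieces) == 0) return(empty)
  out <- do.call(rbind, pieces)
  out <- out[order(out$internalKey, out$icd9_code, out$dx_date), , drop = FALSE]
  out <- data.frame(eventId = seq_len(nrow(out)), out, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Generate a complete synthetic study bundle
#'
#' Convenience wrapper running cohort, genotype and diagnosis generation with
#' one master seed, returning everything the downstream stages consume.
#'
#' @inheritParams generate_cohort
#' @inheritParams generate_genotypes
#' @inheritParams generate_diagnoses
#' @param spec a [cohort_spec()]; its seed is the bundle master seed.
#' @return list of class `fixture_bundle`: `demographics`, `diagnoses`,
#'   `genotypes`, `linkage`, `category_map`, `panel`, `seed`.
#' @export
generate_bundle <- function(spec = cohort_spec(), panel = default_snp_panel(),
                            maf = default_maf(panel), effects = list(),
                            map = default_category_map(), background = NULL,
                            model = "dominant", biobank_frac = 1) {
  cohort <- generate_cohort(spec, biobank_frac = biobank_frac)
  genotypes <- generate_genotypes(cohort$linkage, panel, maf, seed = spec$seed)
  diagnoses <- generate_diagnoses(cohort$demographics, cohort$linkage,
                                  genotypes, effects = effects, map = map,
                                  background = background, model = model,
                                  seed = spec$seed)
  structure(list(demographics = cohort$demographics, diagnoses = diagnoses,
                 genotypes = genotypes, linkage = cohort$linkage,
                 category_map = map[, c("code", "category_id", "label")],
                 panel = panel, seed = spec$seed),
            class = "fixture_bundle")
}

#' Write / read a fixture bundle
#'
#' Writes six RFC-4180 CSV files (demographics, diagnoses, genotypes,
#' linkage, ccs_map, panel) plus a JSON `manifest.json` recording the seed
#' and table row counts; [read_fixture_bundle()] loads them back.
#'
#' @param bundle a `fixture_bundle` from [generate_bundle()].
#' @param outdir output directory (created if missing).
#' @return invisibly, the paths written (write) / the bundle (read).
#' @export
write_fixture_bundle <- function(bundle, outdir) {
  abort_if(!inherits(bundle, "fixture_bundle"), "bundle must be a fixture_bundle")
  ok <- dir.exists(outdir) || dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  abort_if(!ok, "cannot create output directory: ", outdir)
  files <- c(demographics = "demographics.csv", diagnoses = "diagnoses.csv",
             genotypes = "genotypes.csv", linkage = "linkage.csv",
             category_map = "ccs_map.csv", panel = "panel.csv")
  paths <- file.path(outdir, files)
  names(paths) <- names(files)
  for (nm in names(files)) {
    utils::write.csv(bundle[[nm]], paths[[nm]], row.names = FALSE)
  }
  manifest <- list(
    seed = bundle$seed,
    tables = lapply(names(files), function(nm) {
      list(file = unname(files[[nm]]), rows = nrow(bundle[[nm]]))
    })
  )
  names(manifest$tables) <- names(files)
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(c(paths, manifest = file.path(outdir, "manifest.json")))
}

#' @rdname write_fixture_bundle
#' @param dir directory holding a written bundle.
#' @export
read_fixture_bundle <- function(dir) {
  abort_if(!dir.exists(dir), "no such bundle directory: ", dir)
  rd <- function(f, colClasses = NA) {
    utils::read.csv(file.path(dir, f), stringsAsFactors = FALSE,
                    colClasses = colClasses)
  }
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"))
  bundle <- list(
    demographics = rd("demographics.csv"),
    diagnoses = rd("diagnoses.csv",
                   colClasses = c(icd9_code = "character", dx_date = "character")),
    genotypes = rd("genotypes.csv", colClasses = c(patientId = "character")),
    linkage = rd("linkage.csv", colClasses = c(patientId = "character")),
    category_map = rd("ccs_map.csv", colClasses = c(code = "character",
                                                    category_id = "character")),
    panel = rd("panel.csv"),
    seed = manifest$seed
  )
  structure(bundle, class = "fixture_bundle")
}

# Save/restore the global RNG state so seeded generators do not perturb the
# caller's stream.
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}

.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  invisible(NULL)
}
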