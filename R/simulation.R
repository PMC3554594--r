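#' Parameter-recovery simulation
#'
#' Generates one synthetic cohort with a single planted effect and runs the
#' scan stage on it, returning the estimated odds ratio for the planted
#' (SNP, category) pair.  Generation and estimation both use the dominant
#' model, under which the 2x2 exposure-by-membership odds ratio is a
#' consistent estimator of the planted odds ratio.
#'
#' @param odds_ratio planted odds ratio (1 = null).
#' @param n cohort size.
#' @param seed integer seed for this replicate.
#' @param baseline_prev baseline category prevalence in non-carriers.
#' @param maf minor-allele frequency of the planted SNP.
#' @param min_subjects cluster-retention threshold applied before the scan.
#' @return one-row data.frame `odds_ratio`, `ci_lo`, `ci_hi`, `p_value`,
#'   plus the planted truth as `truth`.
#' @export
recovery_sim <- function(odds_ratio, n = 5000, seed = 1L,
                         baseline_prev = 0.1, maf = 0.3, min_subjects = 25) {
  panel <- snp_panel(data.frame(
    snp_id = "rs7903146", gene_symbol = "TCF7L2", risk_allele = "T",
    other_allele = "C", trait_label = "T2DM", stringsAsFactors = FALSE))
  map <- default_category_map()
  map <- map[map$category_id %in% c("49", "98", "200"), , drop = FALSE]
  spec <- cohort_spec(data.frame(
    label = "SIM", n = as.integer(n), mean_age = 60, sd_age = 12,
    female_frac = 0.5, record_len_mean = 20, stringsAsFactors = FALSE),
    seed = seed)
  effect <- planted_effect("rs7903146", "T", "49", odds_ratio, baseline_prev)
  bundle <- generate_bundle(spec, panel = panel,
                            maf = c(rs7903146 = maf),
                            effects = list(effect), map = map,
                            model = "dominant")
  pid_of <- as.character(bundle$demographics$clinicNumber)
  dx_pid <- pid_of[match(bundle$diagnoses$internalKey,
                         bundle$demographics$internalKey)]
  clusters <- cluster_subjects(
    data.frame(subject = dx_pid, code = bundle$diagnoses$icd9_code,
               stringsAsFactors = FALSE),
    category_map(bundle$category_map))
  retained <- filter_clusters(clusters, min_subjects)
  res <- phewas_scan(bundle$genotypes, retained, panel = panel,
                     model = "dominant", adjust = "none")
  hit <- res[res$snp_id == "rs7903146" & res$category_id == "49", ,
             drop = FALSE]
  abort_if(nrow(hit) == 0,
           "planted category fell below the retention threshold")
  data.frame(odds_ratio = hit$odds_ratio, ci_lo = hit$ci_lo,
             ci_hi = hit$ci_hi, p_value = hit$p_value, truth = odds_ratio)
}

#' Null-scan simulation
#'
#' Generates one cohort with no planted effects (every category at its
#' background prevalence, independent of genotype) and scans the full
#' default panel against all categories, returning the unadjusted p-values.
#' Over replicates, the fraction below 0.05 measures the scan's type-I
#' error calibration.
#'
#' @param n cohort size.
#' @param seed integer seed for this replicate.
#' @param model scan model kind.
#' @return numeric vector of unadjusted p-values (one per SNP x retained
#'   category).
#' @export
null_scan_sim <- function(n = 5000, seed = 1L, model = "dominant") {
  spec <- cohort_spec(data.frame(
    label = "NULL", n = as.integer(n), mean_age = 60, sd_age = 12,
    female_frac = 0.5, record_len_mean = 20, stringsAsFactors = FALSE),
    seed = seed)
  bundle <- generate_bundle(spec, model = "dominant")
  pid_of <- as.character(bundle$demographics$clinicNumber)
  dx_pid <- pid_of[match(bundle$diagnoses$internalKey,
                         bundle$demographics$internalKey)]
  clusters <- cluster_subjects(
    data.frame(subject = dx_pid, code = bundle$diagnoses$icd9_code,
               stringsAsFactors = FALSE),
    category_map(bundle$category_map))
  retained <- filter_clusters(clusters, 25)
  res <- phewas_scan(bundle$genotypes, retained, panel = bundle$panel,
                     model = model, adjust = "none")
  res$p_value
}
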