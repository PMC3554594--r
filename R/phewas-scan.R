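#' Genetic exposure model
#'
#' Defines how genotype calls partition subjects into exposed and unexposed
#' groups.  `genotypic-exact` compares the genotype string literally (the
#' selection mode of the federated demonstration query, e.g. `"A:A"`);
#' `dominant` exposes carriers of >= 1 risk allele; `recessive` exposes
#' homozygous risk-allele carriers.
#'
#' @param kind one of `"genotypic-exact"`, `"dominant"`, `"recessive"`.
#' @param risk_allele required for dominant/recessive.
#' @param genotype literal genotype string, required for genotypic-exact.
#' @return object of class `genetic_model`.
#' @export
genetic_model <- function(kind = c("genotypic-exact", "dominant", "recessive"),
                          risk_allele = NULL, genotype = NULL) {
  kind <- match.arg(kind)
  if (kind == "genotypic-exact") {
    abort_if(is.null(genotype) || !grepl("^[ACGT]:[ACGT]$", genotype),
             "genotypic-exact needs a genotype literal like \"A:A\"")
  } else {
    abort_if(is.null(risk_allele) || !risk_allele %in% c("A", "C", "G", "T"),
             kind, " model needs a risk allele (A/C/G/T)")
  }
  structure(list(kind = kind, risk_allele = risk_allele, genotype = genotype),
            class = "genetic_model")
}

#' Partition genotyped subjects into exposed / unexposed groups
#'
#' The unexposed group is the complement of the exposed group within the
#' subjects genotyped at this SNP (not the whole EHR population); subjects
#' with a missing call at the SNP are excluded, not imputed.
#'
#' @param genotypes data.frame `patientId`, `rsID`, `genotype`.
#' @param snp_id rsID to partition on.
#' @param model a [genetic_model()].
#' @return list with character vectors `exposed` and `unexposed`.
#' @export
exposure_groups <- function(genotypes, snp_id, model) {
  abort_if(!inherits(model, "genetic_model"), "model must be a genetic_model")
  g <- genotypes[genotypes$rsID == snp_id, , drop = FALSE]
  abort_if(nrow(g) == 0, "SNP ", snp_id, " absent from the genotype table")
  ok <- !is_null_value(g$genotype)
  g <- g[ok, , drop = FALSE]
  exposed_mask <- switch(
    model$kind,
    "genotypic-exact" = g$genotype == model$genotype,
    dominant = allele_dosage(g$genotype, model$risk_allele, "dominant") == 1,
    recessive = allele_dosage(g$genotype, model$risk_allele, "recessive") == 1)
  list(exposed = unique(as.character(g$patientId[exposed_mask])),
       unexposed = unique(as.character(g$patientId[!exposed_mask])))
}

#' 2x2 contingency table
#'
#' Cell layout: `a` exposed with the category, `b` exposed without, `c`
#' unexposed with, `d` unexposed without.
#'
#' @param a,b,c,d non-negative counts.
#' @return object of class `contingency_2x2`.
#' @export
contingency_2x2 <- function(a, b, c, d) {
  cells <- c(a = a, b = b, c = c, d = d)
  abort_if(any(!vapply(cells, is_count, logical(1))),
           "all four cells must be non-negative integers")
  structure(as.list(cells), class = "contingency_2x2")
}

#' @export
print.contingency_2x2 <- function(x, ...) {
  m <- matrix(c(x$a, x$b, x$c, x$d), 2, 2, byrow = TRUE,
              dimnames = list(c("exposed", "unexposed"),
                              c("with", "without")))
  print(m)
  invisible(x)
}

#' Build the 2x2 table for one SNP x category pair
#'
#' @param exposed,unexposed disjoint subject-id vectors (from
#'   [exposure_groups()]).
#' @param cluster a `phenotype_cluster` (or anything with a `subjects`
#'   field).
#' @return a [contingency_2x2()].
#' @export
build_table <- function(exposed, unexposed, cluster) {
  abort_if(length(intersect(exposed, unexposed)) > 0,
           "exposed and unexposed groups overlap")
  subs <- cluster$subjects
  a <- sum(exposed %in% subs)
  c_ <- sum(unexposed %in% subs)
  contingency_2x2(a, length(exposed) - a, c_, length(unexposed) - c_)
}

#' Odds ratio with Woolf confidence interval
#'
#' OR = ad/bc.  When any cell is zero the Haldane-Anscombe correction adds
#' 0.5 to all four cells before both the estimate and the interval, so the
#' estimator is finite for every table.  The interval is the Woolf normal
#' interval on the log odds ratio of the (possibly corrected) cells.
#'
#' @param table a [contingency_2x2()].
#' @param conf_level confidence level (default 0.95).
#' @return named list `or`, `lo`, `hi`, `corrected`.
#' @examples
#' odds_ratio_ci(contingency_2x2(20, 10, 10, 20))$or  # 4
#' @export
odds_ratio_ci <- function(table, conf_level = 0.95) {
  abort_if(!inherits(table, "contingency_2x2"), "table must be a contingency_2x2")
  cells <- c(table$a, table$b, table$c, table$d)
  corrected <- any(cells == 0)
  if (corrected) cells <- cells + 0.5
  or <- (cells[1] * cells[4]) / (cells[2] * cells[3])
  se <- sqrt(sum(1 / cells))
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  list(or = or, lo = exp(log(or) - z * se), hi = exp(log(or) + z * se),
       corrected = corrected)
}

# Two-sided Fisher exact p by the point-probability method: conditioning on
# both margins, sum the hypergeometric probabilities of every table whose
# probability does not exceed the observed one (relative tolerance 1e-7, the
# conventional guard against ties lost to rounding).
fisher_p <- function(a, b, c, d) {
  m <- a + b            # exposed margin
  n <- c + d            # unexposed margin
  k <- a + c            # outcome margin
  if (m + n == 0 || k == 0 || k == m + n || m == 0 || n == 0) return(1)
  lo <- max(0L, k - n)
  hi <- min(k, m)
  support <- lo:hi
  dens <- stats::dhyper(support, m, n, k)
  d_obs <- stats::dhyper(a, m, n, k)
  min(1, sum(dens[dens <= d_obs * (1 + 1e-7)]))
}

#' Association test for a 2x2 table
#'
#' Default is the two-sided Fisher exact test (point-probability method,
#' computed by hypergeometric enumeration over the conditional support); a
#' continuity-corrected chi-square test is available for large tables.  An
#' all-degenerate table (an empty margin) returns p = 1 by convention.
#'
#' @param table a [contingency_2x2()].
#' @param method `"fisher"` or `"chisq"`.
#' @return two-sided p-value.
#' @export
exact_test <- function(table, method = c("fisher", "chisq")) {
  method <- match.arg(method)
  abort_if(!inherits(table, "contingency_2x2"), "table must be a contingency_2x2")
  a <- table$a; b <- table$b; c <- table$c; d <- table$d
  if (method == "fisher") return(fisher_p(a, b, c, d))
  if (a + b == 0 || c + d == 0 || a + c == 0 || b + d == 0) return(1)
  p <- suppressWarnings(
    stats::chisq.test(matrix(c(a, b, c, d), 2, byrow = TRUE),
                      correct = TRUE)$p.value)
  if (is.na(p)) 1 else p
}

#' Phenome-wide association scan
#'
#' For every panel SNP and every retained phenome cluster, builds the 2x2
#' exposure-by-membership table, estimates the odds ratio with its Woolf
#' 95% interval, tests association, and adjusts p-values for multiplicity
#' within each SNP's family of categories.
#'
#' @param genotypes data.frame `patientId`, `rsID`, `genotype`.
#' @param clusters a `phenotype_clusters` object, already size-filtered (see
#'   [filter_clusters()]); cluster subject ids must be patient ids.
#' @param panel SNP panel (needs `snp_id`, `risk_allele`).
#' @param model model kind (`"genotypic-exact"`, `"dominant"`,
#'   `"recessive"`) applied per SNP with the panel's risk allele (for
#'   genotypic-exact, the homozygous risk genotype), or a single
#'   [genetic_model()] applied to every SNP.
#' @param adjust multiplicity adjustment: `"bh"` (Benjamini-Hochberg,
#'   default), `"bonferroni"` or `"none"`.
#' @param test association test passed to [exact_test()].
#' @return object of class `phewas_result`: a data.frame with one row per
#'   SNP x category (`snp_id`, `model`, `category_id`, `label`, `a`, `b`,
#'   `c`, `d`, `odds_ratio`, `ci_lo`, `ci_hi`, `p_value`, `p_adjusted`),
#'   sorted by SNP then p-value.
#' @export
phewas_scan <- function(genotypes, clusters, panel = default_snp_panel(),
                        model = "dominant", adjust = c("bh", "bonferroni", "none"),
                        test = c("fisher", "chisq")) {
  adjust <- match.arg(adjust)
  test <- match.arg(test)
  abort_if(!is.data.frame(panel) || nrow(panel) == 0, "panel must be non-empty")
  abort_if(length(clusters) == 0, "no clusters to scan")
  per_snp_model <- function(i) {
    if (inherits(model, "genetic_model")) return(model)
    kind <- match.arg(model, c("genotypic-exact", "dominant", "recessive"))
    ra <- panel$risk_allele[i]
    if (kind == "genotypic-exact") {
      genetic_model(kind, genotype = paste(ra, ra, sep = ":"))
    } else {
      genetic_model(kind, risk_allele = ra)
    }
  }
  rows <- list()
  for (i in seq_len(nrow(panel))) {
    snp <- panel$snp_id[i]
    gm <- per_snp_model(i)
    groups <- exposure_groups(genotypes, snp, gm)
    for (cl in clusters) {
      tab <- build_table(groups$exposed, groups$unexposed, cl)
      est <- odds_ratio_ci(tab)
      p <- exact_test(tab, method = test)
      rows[[length(rows) + 1L]] <- data.frame(
        snp_id = snp, model = gm$kind, category_id = cl$category_id,
        label = cl$label, a = tab$a, b = tab$b, c = tab$c, d = tab$d,
        odds_ratio = est$or, ci_lo = est$lo, ci_hi = est$hi, p_value = p,
        stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, rows)
  adj_method <- c(bh = "BH", bonferroni = "bonferroni", none = "none")[[adjust]]
  res$p_adjusted <- stats::ave(res$p_value, res$snp_id,
                               FUN = function(p) stats::p.adjust(p, adj_method))
  res <- res[order(match(res$snp_id, panel$snp_id), res$p_value,
                   res$category_id), , drop = FALSE]
  rownames(res) <- NULL
  structure(res, class = c("phewas_result", "data.frame"),
            adjust = adjust, test = test)
}

#' @export
print.phewas_result <- function(x, n = 10, ...) {
  cat("PheWAS scan:", length(unique(x$snp_id)), "SNPs x",
      length(unique(x$category_id)), "categories =", nrow(x), "tests (",
      attr(x, "test"), "test,", attr(x, "adjust"), "adjustment )\n")
  cat("Top associations:\n")
  top <- as.data.frame(x)[order(x$p_adjusted), ][seq_len(min(n, nrow(x))), ]
  top$odds_ratio <- signif(top$odds_ratio, 4)
  top$ci_lo <- signif(top$ci_lo, 4); top$ci_hi <- signif(top$ci_hi, 4)
  top$p_value <- signif(top$p_value, 3); top$p_adjusted <- signif(top$p_adjusted, 3)
  print(top[, c("snp_id", "category_id", "label", "odds_ratio", "ci_lo",
                "ci_hi", "p_value", "p_adjusted")], row.names = FALSE)
  invisible(x)
}

#' @export
summary.phewas_result <- function(object, alpha = 0.05, ...) {
  hits <- object[object$p_adjusted < alpha, , drop = FALSE]
  cat(nrow(hits), "of", nrow(object),
      "SNP x category pairs with adjusted p <", alpha, "\n")
  by_snp <- split(as.data.frame(object), object$snp_id)
  for (snp in unique(object$snp_id)) {
    df <- by_snp[[snp]]
    best <- df[which.min(df$p_adjusted), ]
    cat(sprintf("  %-11s best: %s (OR %.2f, adj p %.3g)\n", snp,
                best$label, best$odds_ratio, best$p_adjusted))
  }
  invisible(hits)
}

#' Manhattan-style plot of a scan
#'
#' One point per SNP x category at -log10(adjusted p), categories on the
#' x-axis, one color per SNP; the dashed line marks adjusted p = 0.05.
#'
#' @param x a `phewas_result`.
#' @param ... passed to [graphics::plot()].
#' @export
plot.phewas_result <- function(x, ...) {
  cats <- unique(x$category_id)
  snps <- unique(x$snp_id)
  xi <- match(x$category_id, cats)
  ci <- match(x$snp_id, snps)
  y <- -log10(pmax(x$p_adjusted, 1e-300))
  graphics::plot(xi, y, col = ci, pch = 19, xaxt = "n",
                 xlab = "phenome category", ylab = "-log10 adjusted p", ...)
  graphics::axis(1, at = seq_along(cats), labels = cats, las = 2, cex.axis = 0.7)
  graphics::abline(h = -log10(0.05), lty = 2)
  graphics::legend("topright", legend = snps, col = seq_along(snps),
                   pch = 19, cex = 0.7)
  invisible(x)
}

#' Export scan results for plotting
#'
#' Writes the category-indexed `-log10(p_adjusted)` table per SNP, the
#' numeric content behind a phenome-scan scatter plot; byte-deterministic
#' for fixed input.
#'
#' @param results a `phewas_result`.
#' @param path TSV output path.
#' @export
manhattan_export <- function(results, path) {
  df <- data.frame(snp_id = results$snp_id,
                   category_id = results$category_id,
                   label = results$label,
                   n_subjects_with = results$a + results$c,
                   odds_ratio = sprintf("%.6g", results$odds_ratio),
                   neg_log10_p_adj = sprintf("%.6g",
                                             -log10(pmax(results$p_adjusted,
                                                         1e-300))),
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write full scan results
#'
#' @param results a `phewas_result`.
#' @param path output path.
#' @param format `"tsv"` or `"json"`.
#' @export
write_phewas_results <- function(results, path, format = c("tsv", "json")) {
  format <- match.arg(format)
  df <- as.data.frame(results)
  if (format == "tsv") {
    utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  } else {
    jsonlite::write_json(df, path, dataframe = "rows", digits = NA)
  }
  invisible(path)
}
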