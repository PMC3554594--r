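gts <- function(...) {
  g <- c(...)
  data.frame(patientId = sprintf("p%d", seq_along(g)), rsID = "rs1001",
             genotype = g, stringsAsFactors = FALSE)
}

test_that("exposure groups follow the genetic model definitions", {
  g <- gts("A:A", "A:G", "G:G")
  dom <- exposure_groups(g, "rs1001", genetic_model("dominant", risk_allele = "A"))
  expect_setequal(dom$exposed, c("p1", "p2"))
  expect_setequal(dom$unexposed, "p3")
  exact <- exposure_groups(g, "rs1001",
                           genetic_model("genotypic-exact", genotype = "A:A"))
  expect_setequal(exact$exposed, "p1")
  rec <- exposure_groups(gts("G:G", "G:G"), "rs1001",
                         genetic_model("recessive", risk_allele = "A"))
  expect_length(rec$exposed, 0)
  expect_error(genetic_model("dominant"), "risk allele")
  # missing calls are excluded from both groups
  g2 <- gts("A:A", NA, "G:G")
  both <- exposure_groups(g2, "rs1001", genetic_model("dominant", risk_allele = "A"))
  expect_equal(sort(c(both$exposed, both$unexposed)), c("p1", "p3"))
})

test_that("2x2 construction preserves margins and rejects overlap", {
  cl <- list(subjects = c("p1", "p3", "p9"))
  tab <- build_table(c("p1", "p2"), c("p3", "p4", "p5"), cl)
  expect_equal(c(tab$a, tab$b, tab$c, tab$d), c(1, 1, 1, 2))
  expect_error(build_table(c("p1"), c("p1", "p2"), cl), "overlap")
  # randomized sets vs direct intersection arithmetic
  set.seed(3)
  for (i in 1:20) {
    pool <- sprintf("p%d", 1:100)
    exp_g <- sample(pool, 40)
    unexp <- setdiff(pool, exp_g)
    members <- sample(pool, sample.int(60, 1))
    tab <- build_table(exp_g, unexp, list(subjects = members))
    expect_equal(tab$a, length(intersect(exp_g, members)))
    expect_equal(tab$c, length(intersect(unexp, members)))
    expect_equal(tab$a + tab$b, length(exp_g))
    expect_equal(tab$c + tab$d, length(unexp))
  }
})

test_that("odds ratios match closed forms, with Haldane correction at zeros", {
  expect_equal(odds_ratio_ci(contingency_2x2(20, 10, 10, 20))$or, 4.0)
  sym <- odds_ratio_ci(contingency_2x2(10, 10, 10, 10))
  expect_equal(sym$or, 1.0)
  expect_equal(log(sym$hi), -log(sym$lo))  # symmetric about 1 on log scale
  corr <- odds_ratio_ci(contingency_2x2(0, 10, 10, 10))
  expect_equal(corr$or, (0.5 * 10.5) / (10.5 * 10.5))
  expect_true(corr$corrected)
  expect_true(is.finite(corr$lo) && is.finite(corr$hi))
  # OR always finite, CI ordered around the estimate when all cells > 0
  set.seed(9)
  for (i in 1:30) {
    cells <- sample(0:15, 4, TRUE)
    est <- odds_ratio_ci(do.call(contingency_2x2, as.list(cells)))
    expect_true(is.finite(est$or))
    expect_lte(est$lo, est$or)
    expect_gte(est$hi, est$or)
  }
})

test_that("Fisher p-values equal enumeration and reference implementations", {
  expect_equal(exact_test(contingency_2x2(1, 9, 9, 1)),
               oracle_fisher_p(1, 9, 9, 1), tolerance = 1e-14)
  expect_equal(exact_test(contingency_2x2(10, 10, 10, 10)), 1.0)
  expect_equal(exact_test(contingency_2x2(0, 0, 0, 0)), 1.0)
  # exhaustive small-margin sweep against the choose() oracle
  for (r1 in 0:12) {
    for (r2 in 0:12) {
      for (a in 0:r1) {
        for (c_ in 0:r2) {
          mine <- exact_test(contingency_2x2(a, r1 - a, c_, r2 - c_))
          expect_equal(mine, oracle_fisher_p(a, r1 - a, c_, r2 - c_),
                       tolerance = 1e-12)
        }
      }
    }
  }
  # independent library cross-check on random tables
  set.seed(41)
  for (i in 1:50) {
    cells <- sample(0:25, 4, TRUE)
    mine <- exact_test(do.call(contingency_2x2, as.list(cells)))
    ref <- stats::fisher.test(matrix(cells, 2, byrow = TRUE))$p.value
    expect_equal(mine, ref, tolerance = 1e-10)
  }
})

test_that("chi-square alternative is available and sane", {
  p <- exact_test(contingency_2x2(30, 10, 10, 30), method = "chisq")
  expect_lt(p, 0.001)
  expect_equal(exact_test(contingency_2x2(0, 0, 5, 5), method = "chisq"), 1)
})

sim_clusters <- function(bundle) {
  pid_of <- as.character(bundle$demographics$clinicNumber)
  dx_pid <- pid_of[match(bundle$diagnoses$internalKey,
                         bundle$demographics$internalKey)]
  cluster_subjects(data.frame(subject = dx_pid,
                              code = bundle$diagnoses$icd9_code,
                              stringsAsFactors = FALSE),
                   category_map(bundle$category_map))
}

test_that("the scan produces one result per SNP x retained category", {
  sg <- data.frame(label = "S", n = 1500L, mean_age = 60, sd_age = 10,
                   female_frac = 0.5, record_len_mean = 15)
  b <- generate_bundle(cohort_spec(sg, seed = 12))
  retained <- filter_clusters(sim_clusters(b), 25)
  expect_length(retained, 15)  # all fixture categories clear 25 at n = 1500
  res <- phewas_scan(b$genotypes, retained, panel = b$panel,
                     model = "dominant", adjust = "bh")
  expect_equal(nrow(res), 8 * 15)
  expect_true(all(res$p_adjusted >= res$p_value))
  expect_true(all(res$p_value >= 0 & res$p_value <= 1))
  # margins equal group sizes within each SNP
  one <- res[res$snp_id == "rs5219", ]
  expect_equal(length(unique(one$a + one$b)), 1)
  expect_equal(length(unique(one$c + one$d)), 1)
  # adjust = "none" leaves p untouched
  res0 <- phewas_scan(b$genotypes, retained, panel = b$panel,
                      model = "dominant", adjust = "none")
  expect_identical(res0$p_adjusted, res0$p_value)
  expect_error(phewas_scan(b$genotypes, retained,
                           panel = b$panel[integer(0), ], model = "dominant"),
               "panel")
})

test_that("a strong planted effect ranks first within its SNP family", {
  top_rank <- vapply(1:50, function(s) {
    panel <- snp_panel(data.frame(snp_id = "rs7903146", gene_symbol = "TCF7L2",
                                  risk_allele = "T", other_allele = "C",
                                  trait_label = "T2DM"))
    map <- default_category_map()
    map <- map[map$category_id %in% c("49", "98", "200"), ]
    sg <- data.frame(label = "S", n = 5000L, mean_age = 60, sd_age = 10,
                     female_frac = 0.5, record_len_mean = 15)
    b <- generate_bundle(cohort_spec(sg, seed = 5000 + s), panel = panel,
                         maf = c(rs7903146 = 0.3),
                         effects = list(planted_effect("rs7903146", "T", "49",
                                                       4.0, 0.1)),
                         map = map)
    retained <- filter_clusters(sim_clusters(b), 25)
    res <- phewas_scan(b$genotypes, retained, panel = panel,
                       model = "dominant", adjust = "bh")
    fam <- res[res$snp_id == "rs7903146", ]
    fam$category_id[which.min(fam$p_adjusted)] == "49"
  }, logical(1))
  expect_gte(mean(top_rank), 0.9)
})

test_that("plot-data export is complete, monotone and deterministic", {
  sg <- data.frame(label = "S", n = 800L, mean_age = 60, sd_age = 10,
                   female_frac = 0.5, record_len_mean = 15)
  b <- generate_bundle(cohort_spec(sg, seed = 6))
  retained <- filter_clusters(sim_clusters(b), 25)
  res <- phewas_scan(b$genotypes, retained, panel = b$panel,
                     model = "dominant")
  f1 <- withr::local_tempfile(fileext = ".tsv")
  f2 <- withr::local_tempfile(fileext = ".tsv")
  manhattan_export(res, f1)
  manhattan_export(res, f2)
  tab <- utils::read.delim(f1)
  expect_equal(nrow(tab), nrow(res))
  expect_equal(order(tab$neg_log10_p_adj), order(-res$p_adjusted))
  expect_identical(readLines(f1), readLines(f2))
})
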