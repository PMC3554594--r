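# fedphewas

A desk-scale, fully synthetic re-creation of a semantic-web PheWAS system
over an EHR-linked biobank — for informaticians and biostatisticians who
want to study, test or teach the pipeline that sits between two relational
clinical/genotype stores and a phenome-wide association result, without
touching protected patient data.

A **PheWAS** (phenome-wide association scan) is the reverse of a GWAS: for
a given genotype it tests association against many clinical phenotypes at
once.  Running one against a real biobank means solving three plumbing
problems first — exposing two separately keyed relational stores (a
clinical warehouse and a genotype repository) in a joinable form, linking
a patient across them, and collapsing raw ICD-9-CM billing codes into a
manageable set of phenotype categories.  `fedphewas` implements the whole
stack:

1. **Synthetic data** — a seeded generator emulating a biobank cohort of
   6,307 subjects in five study subgroups, Hardy–Weinberg genotype calls
   for an 8-SNP panel, and diagnosis histories with configurable *planted*
   genotype–phenotype effects (the simulation ground truth the scan must
   recover).
2. **RDF virtualization** — the direct-mapping rule (primary/foreign keys
   become IRIs, every other column a predicate, every row an `rdf:type`
   statement; a row with *c* populated plain columns and *f* foreign keys
   yields exactly 1 + *c* + *f* triples), with R2RML-style overrides by
   ontology terms, N-Triples/Turtle serialization, and YAML mapping files.
3. **Federation** — SERVICE-clause evaluation against named graph
   endpoints with equality-filter joins and key canonicalization
   (`"0123"` joins `123`), provably transparent with respect to querying
   the merged store.
4. **Phenome clustering** — ICD-9-CM codes grouped into mutually
   exclusive single-level CCS-style categories, counting distinct
   subjects, with clusters under 25 subjects dropped.
5. **Association scan** — per SNP × category 2×2 tables; odds ratio
   OR = ad/bc with the Haldane–Anscombe +0.5 correction when a cell is
   zero; Woolf 95% interval exp(log OR ± 1.96·√(1/a+1/b+1/c+1/d));
   two-sided Fisher exact p by hypergeometric enumeration
   (point-probability method); Benjamini–Hochberg adjustment within each
   SNP's family of categories.

## Worked example

Generate a cohort with one planted effect (rs7903146 carriers get odds
ratio 2.0 for the diabetes category, baseline prevalence 0.12) and run the
pipeline end to end — generation, virtualization, federated retrieval,
clustering, retention filtering, scan:

```r
library(fedphewas)
cfg <- run_config(seed = 1, outdir = "run1",
                  effects = list(planted_effect("rs7903146", "T", "49",
                                                2.0, 0.12)))
out <- cmd_scan(cfg)
print(out$results, n = 5)
#> PheWAS scan: 8 SNPs x 15 categories = 120 tests ( fisher test, bh adjustment )
#> Top associations:
#>     snp_id category_id                                  label odds_ratio  ci_lo
#>  rs7903146          49 Diabetes mellitus without complication     2.0310 1.7710
#>  rs7903146         118         Phlebitis and thrombophlebitis     0.8325 0.6898
#>  rs7903146         127  Chronic obstructive pulmonary disease     1.1430 0.9595
#>  rs7903146         205          Spondylosis and back problems     0.9133 0.8106
#>  rs7903146         108               Congestive heart failure     1.1510 0.9503
#>  ci_hi  p_value p_adjusted
#>  2.329 4.86e-25   7.29e-24
#>  1.005 6.15e-02   4.62e-01
#>  1.360 1.43e-01   4.73e-01
#>  1.029 1.44e-01   4.73e-01
#>  1.394 1.58e-01   4.73e-01
```

The planted pair is recovered: the estimated odds ratio 2.03 (Woolf 95% CI
1.77–2.33) brackets the planted 2.0, its adjusted p-value 7.3e-24 is the
only one below 0.05, and every other SNP × category pair behaves as a
null.  `summary(out$results)` lists the best hit per SNP;
`plot(out$results)` draws the Manhattan-style scan.  `out$clusters` holds
the retained phenome clusters (all ≥ 25 subjects) and `run1/` the
results TSV, plot data, cluster report, phenotype statuses and a seeded
manifest.

The federated layer can be driven directly — the demonstration query
retrieves every patient homozygous for the rs2476601 risk allele together
with all their diagnosis codes, joining the genotype and clinical
endpoints on patient id = clinic number:

```r
eps <- virtualize_bundle(out$bundle)
hits <- run_federated(biobank_query("rs2476601", "A:A"), eps)
length(unique(hits$pid))
#> [1] 45
```

A thin CLI wraps the same stages: `inst/exec/fedphewas generate|query|scan
--seed 1 --outdir run1`, with query files in a minimal SPARQL-like syntax
(see `inst/extdata/demo-query.rq`).

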