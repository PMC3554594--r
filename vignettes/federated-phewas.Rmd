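---
title: "Federated semantic-web PheWAS: models, assumptions and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Federated semantic-web PheWAS: models, assumptions and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

A phenome-wide association scan (PheWAS) reverses the usual GWAS direction:
for a given genotype it asks which of many clinical phenotypes are
associated with it.  Running one against an EHR-linked biobank requires
joining two administratively separate stores — a clinical warehouse holding
diagnosis histories keyed by an internal patient key, and a genotype
repository keyed by its own patient id — and then grouping tens of
thousands of raw billing codes into a tractable set of phenotype categories
before any statistics are possible.

`fedphewas` re-creates that whole stack at desk scale, on synthetic data,
so that every stage is executable, testable and seeded: relational tables
are virtualized into RDF by a direct-mapping rule, queried jointly through
a SERVICE-style federated evaluator, clustered into mutually exclusive
diagnosis categories, and scanned for SNP–category associations.

```{r, eval = FALSE}
library(fedphewas)
out <- cmd_scan(run_config(seed = 1, outdir = "run1",
                           effects = list(planted_effect("rs7903146", "T",
                                                         "49", 2.0, 0.12))))
print(out$results)
```

## The synthetic cohort generator

The generator's defaults are the study conditions, not tuning knobs.  The
default cohort is five subgroups — peripheral-arterial-disease cases
(n = 1612) and controls (1585), venous-thromboembolism cases (1233) and
controls (1264), and pancreatic-cancer controls (613) — totalling 6,307
unique subjects, with each subgroup's published mean/SD age, female
fraction and mean medical-record length (years).  Ages are truncated-normal
draws clipped to [18, 100]; record lengths are truncated-normal draws with
SD set to 60% of the subgroup mean and a one-year floor (the sources report
means, not full distributions, so a dispersion had to be chosen once; 60%
reproduces the broad right spread such registries show).

Genotypes for the eight-SNP default panel are drawn under Hardy–Weinberg
equilibrium at fixed per-SNP minor-allele frequencies (0.29–0.36 for the
common loci, 0.09 for rs2476601, which is genuinely rare and is what makes
its homozygous stratum small).  Genotype calls are strings `"X:Y"` with
alleles sorted lexicographically; all comparisons downstream are exact
string equality, matching the way the demonstration query selects
`"A:A"`.

Diagnosis histories come from a per-category Bernoulli membership model:

$$\mathrm{logit}\,P(\text{member}) = \mathrm{logit}(\pi_0)
  + \log(\mathrm{OR}) \cdot d$$

where $\pi_0$ is the category's background prevalence (a `baseline_prev`
column of the bundled dictionary, 0.05–0.35 per category), OR is a planted
effect's odds ratio and $d$ the risk-allele dosage under the configured
genetic model.  The default dosage model is **dominant** ($d = 1$ for
carriers): under it, the scan's 2×2 carrier-vs-non-carrier odds ratio is a
consistent estimator of the planted OR, which is what makes
parameter-recovery testing meaningful.  Members then receive 1–3 events
with concrete ICD-9-CM codes of the category, dated uniformly within the
subject's record length.  The bundled dictionary has 60 codes in 15
single-level CCS-style categories; it stands in for the full 285-category
release, which is an external, version-dependent download (the loader also
accepts that distribution's single-quoted dialect).

What the generator does **not** emulate: disease natural history and
comorbidity correlation (categories are drawn independently given
genotype), coding practice drift over time, medications/labs/notes, and
ancestry structure.  Passing tests therefore demonstrate the pipeline's
correctness and calibration under independence, not robustness to real EHR
confounding.

All randomness flows from one integer master seed through deterministic
per-stage sub-seeds (an FNV-1a hash of stage labels), so any table can be
regenerated in isolation and whole runs are byte-reproducible.

## RDF virtualization

The direct-mapping rule renders any relational table as RDF: each row gets
a subject IRI `{base}/{table}/{pk1}[-{pk2}…]` built from its primary-key
values (percent-encoded, with `-` escaped inside components so composite
keys stay injective) plus one `rdf:type` statement; each column that is
neither a primary- nor foreign-key column becomes a literal-valued
predicate `{base}/{table}#{column}`; each foreign key becomes an IRI
reference to the target row's subject.  A row with $c$ populated plain
columns and $f$ populated foreign keys therefore yields exactly
$1 + c + f$ triples; NULLs (NA or empty string) emit nothing, the de-facto
direct-mapping convention.  Literal datatypes follow column types: integer
and date columns get `xsd:integer`/`xsd:date` typed literals, text stays
plain.

Mappings are first-class objects: `override_mapping()` swaps the
auto-generated class IRI or a column predicate for a term from a
standardized ontology without changing triple counts, and mappings
round-trip through a YAML dialect mirroring R2RML's structure (logical
table, subject map, predicate–object maps) so they can be hand-edited.
Only this direct-mapping + override subset is implemented — arbitrary
R2RML templates, SQL-view logical tables and named graphs are out of
scope, as is any live RDBMS connectivity: the "virtual" graphs here are
triple tables materialized on demand from the CSV-backed stores.

One deliberate deviation from the naive rule: in the default store
schemas, the registry and genotype-call tables receive **surrogate integer
keys** at virtualization time, so that `patientId` and `rsID` remain plain
columns.  Under the strict rule, primary-key columns surface only inside
IRIs, which would make selections like `?rsID = "rs2476601"` impossible to
express against key-valued data; surrogate keys keep the emitted triple
arithmetic exactly $1 + c + f$ while leaving the natural keys queryable as
literals, which is the shape the demonstration query requires.

## Federated evaluation

A federated query is one or more SERVICE clauses (a basic graph pattern
plus local equality/inequality filters, evaluated against one named
endpoint), cross-clause equality join filters, selection filters and a
projection — exactly the fragment the demonstration query uses; OPTIONAL,
UNION, negation, aggregates and property paths are out of scope.  Variable
scopes are per clause: the same name may not appear in two clauses, and
cross-clause joins are expressed only through join filters.

Join keys are canonicalized before comparison: integer-looking strings
lose leading zeros and compare equal to their numeric form, so the
clinical store's integer `clinicNumber` joins the genotype store's textual
`patientId`.  The two stores type the same person identifier differently
on purpose, to keep this canonicalization exercised.

Evaluation is per-clause materialization followed by hash joins.  Within a
basic graph pattern, an equality filter connecting two otherwise disjoint
pattern groups is used as a hash-join condition rather than a cross
product, and any filter whose variables are fully bound is applied as
early as possible; this is an efficiency device only and does not change
the filter+join semantics.  The governing contract is *federation
transparency*: for every supported query, the federated result equals — as
a multiset — evaluating the same conjunctive pattern over the union of all
endpoint graphs (`run_monolithic()`).  This holds because the stores have
disjoint IRI vocabularies (distinct base IRIs), so each pattern can only
match its own store's triples; the property is exercised on randomized
fixtures up to thousands of triples.  Endpoint unavailability is a
distinct, injectable error, never conflated with an empty result.

## Phenome clustering and phenotyping

Diagnosis bindings are grouped by mapped category with **subject-level**
counting: a subject contributes once per category no matter how many
events they have, because phenome-scan category sizes report subjects, not
encounters (the sources are silent on this; subject counting is this
package's stated choice).  Codes absent from the map go to an explicit
`unmapped` bucket with a warning — EHR extracts routinely contain codes
outside any dictionary version, and silent dropping would bias the
event-conservation invariant the tests assert.

The retention rule drops clusters with fewer than 25 subjects; "less than
25 … not included" is read strictly as *retain iff n ≥ 25*, and the
threshold is configurable.  Below that size, exact-test p-values are so
quantized that a scan row carries essentially no evidence.

Case/control labels come from a code-count surrogate rule (≥ 2 events with
a case prefix ⇒ case; zero case and exclusion events ⇒ control; otherwise
unknown).  The consortium phenotyping algorithms this stands in for also
use medications, laboratory values and NLP; those inputs are outside this
package's data model, so the rule is deliberately minimal, labelled as a
surrogate, and externalized to YAML.  Status is exposed as an optional
stratifier rather than a hard scan filter, since the scan population is
all genotyped subjects.

## The association scan

For each panel SNP, subjects genotyped at that SNP are partitioned by a
genetic model — `genotypic-exact` (literal string match, the demonstration
query's mode and the scan default), `dominant`, or `recessive` — with the
unexposed group defined as the complement *within genotyped subjects*, and
missing calls excluded rather than imputed.  Each SNP × retained-category
pair yields a 2×2 table; the effect estimate is the cross-product odds
ratio with a Woolf (log-OR normal) 95% interval, applying the
Haldane–Anscombe +0.5 correction to all four cells exactly when some cell
is zero, so the estimator is finite for every table.

The test is the two-sided Fisher exact test by the point-probability
method: conditioning on both margins, the p-value sums the hypergeometric
probabilities of all tables no more probable than the one observed, with a
relative tie tolerance of 1e-7 (the conventional guard against ties lost
to floating-point rounding).  It is computed by direct enumeration over
the conditional support, which is exact at any margin size; a
continuity-corrected chi-square alternative is available for users who
prefer it at large counts.  Degenerate tables (an empty margin) return
p = 1 by convention.  The sources present "associations" without naming a
statistic, so Fisher + OR + Woolf is this package's documented choice, and
all three pieces are configurable.

Multiplicity is adjusted **within each SNP's family** of categories
(Benjamini–Hochberg by default, Bonferroni or none as options): a PheWAS
asks, per SNP, which phenotypes stand out, so the family is the set of
categories scanned for that SNP rather than the full SNP × category grid.

## Numerical and degenerate-input choices

* Seeds are 32-bit; derived sub-seeds are reduced modulo a prime below
  $2^{31}$.
* N-Triples output is sorted lexicographically so equal triple multisets
  serialize identically (reproducible diffs); Turtle groups by subject.
* Empty inputs are legal everywhere they can arise: empty cohorts produce
  empty tables, unsatisfiable filters produce empty binding sets (not
  errors), an all-zero 2×2 table has OR 1 after correction and p = 1.
* Ties in the scan ordering are broken by category id, making result files
  byte-deterministic for a fixed seed and configuration.

## Problem sizes used in the checks

The packaged tests and the acceptance script run the full 6,307-subject
default cohort end to end; parameter-recovery uses 50 replicates per
planted odds ratio (1, 2, 4) at n = 5,000 with a single-SNP panel and a
three-category dictionary; null calibration uses 100 replicates of the
full 8 × 15 scan at n = 5,000; the Fisher implementation is swept
exhaustively against a full enumeration oracle over all 164,176 tables
with every margin ≤ 30; federation transparency is checked on 100
randomized two-store fixtures.  These sizes were chosen to give stable
Monte-Carlo margins (binomial SE of the null rejection rate ≈ 0.002)
while keeping a complete run in the low minutes on one core.

## Known limitations

* The evaluator is not a SPARQL engine: no OPTIONAL/UNION/negation, no
  property paths, no HTTP protocol layer, and the concrete syntax is a
  minimal dialect, not the full grammar.
* Transparency is guaranteed only for stores with disjoint IRI
  vocabularies — which virtualization enforces here — and for
  filter+join queries (monotone; adding triples never removes rows).
* The scan is unadjusted for covariates (age, sex, ancestry); planted
  effects are recovered because the generator shares the scan's
  independence assumptions, and no claim is made about confounded real
  data.
* Category membership is independent across categories given genotype, so
  cross-phenotype correlation structure (pleiotropy, comorbidity) is not
  represented.
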