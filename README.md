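# relapsescore

Single-cell drug-sensitivity scoring and relapse-risk classification for
*MLL*-rearranged infant acute lymphoblastic leukemia (iALL) — and for any
cohort where a directional gene signature is read out in single cells and
aggregated into patient-level risk calls.

*MLL*-r iALL relapses in about two-thirds of patients despite initial
remission, and the relapse is usually fatal. The package implements a
classification built on a selection argument: genes apparently *up*regulated
in bulk samples after in vivo prednisone mark a preexisting subpopulation of
treatment-**resistant** cells (they survive, so their signature is
enriched), while apparently *down*regulated genes mark treatment-
**sensitive** cells that the drug eliminates. Scoring both programs in
single cells from an untreated diagnostic sample quantifies how much of the
leukemia is already primed to survive therapy; the relative abundance of
resistant cells predicts relapse. The intended users are computational
biologists evaluating signature-based single-cell risk stratification.

## The method

For cell *c* and gene module *M* (with expression-bin-matched control sets
*C(g)*, 100 control genes per module gene, 24 bins), on log-normalized
expression *x* (per-cell total rescaled to 3,500 transcripts):

```
score_M(c) = mean over g in M of [ x(c, g) − mean over g' in C(g) of x(c, g') ]
```

Cells are called **sensitive** when their sensitivity score is above the
dataset-wide median sensitivity score *and* their resistance score below the
median resistance score; **resistant** for the converse; ties and mixed
quadrants stay unclassified. Per patient the package reports the
sensitive/resistant cell fractions, the mean ± SEM of a first-principal-
component continuum score over the union of module genes, and a relapse-risk
call (default: predicted relapse when resistant cells outnumber sensitive
cells). Supporting analyses: Wilcoxon rank-sum differential expression
between the two cell states (Bonferroni over tested genes; natural-log fold
change), per-gene Spearman correlation with either module score, and
pseudobulk profiles by complete or equal-contribution downsampled pooling.

A negative-binomial synthetic-cohort generator plants the exact structure
the method assumes — per-patient expression offsets, a latent per-cell
resistance continuum driving two anti-correlated gene programs, lower
transcript counts in resistant cells, healthy T-like contaminants, outcome
labels tied to the planted resistant fraction — so the whole pipeline is
testable without access to patient data.

## Worked example

```r
library(relapsescore)

cohort <- generate_cohort(sim_config(n_patients = 6, cells_per_patient = 150,
                                     n_genes = 1000, n_sens_genes = 120,
                                     n_res_genes = 60, seed = 42))
fit <- relapse_fit(cohort$counts, cohort$modules,
                   patient_meta = cohort$patients,
                   marker_module = tcell_marker_module(cohort$counts),
                   seed = 1)
summary(fit)
```

```
Single-cell relapse-risk classification
  849 cells scored across 6 patients (51 excluded as healthy)
  score medians: sensitivity 0.0008, resistance -0.0244
  cells: 307 sensitive, 308 resistant, 234 unclassified
  risk rule: resistant-majority; 3 predicted-relapse / 3 predicted-no-relapse
  outcome agreement: 5/6 correct (accuracy 0.833)

Per-patient summary:
 patient n_cells n_sensitive n_resistant frac_sensitive frac_resistant mean_pc
     P01     137          89          16          0.650          0.117   2.282
     P02     143          72          29          0.503          0.203   1.177
     P03     141          39          56          0.277          0.397  -0.453
     P04     142          38          54          0.268          0.380  -0.168
     P05     141          55          45          0.390          0.319  -0.129
     P06     145          14         108          0.097          0.745  -2.587
```

Reading it: of the 900 simulated cells, 51 scored high for T-cell markers
and were excluded as healthy contaminants. Patient P01's cells sit mostly in
the sensitive quadrant (65% sensitive vs 12% resistant, high PC score → low
risk), P06 is the mirror image (74% resistant → predicted relapse). Five of
six calls match the planted outcomes; P05 is a borderline patient whose
resistant fraction (0.32) stayed just below its sensitive fraction (0.39).

`coef(fit)` returns the fitted score medians, `predict(fit, newdata)`
classifies new scored cells against them, `plot(fit)` draws the
sensitivity-resistance scatter with the quadrant boundaries, and
`run_pipeline(config)` executes the whole flow (simulate/load → preprocess →
score → classify → DE → bulkify) from a YAML or list config, writing every
artifact plus a manifest and a per-patient report.

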