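---
title: "Methods: essentiality-based biomarker screening"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: essentiality-based biomarker screening}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(depmarker)
```

## The problem

Genome-wide RNAi screens assign every gene a per-cell-line essentiality score
(DEMETER-like; more negative means knockdown is more lethal, with −2 the
conventional essentiality cutoff). Combined with mutation profiles of the
same cell-line panel, such screens let us ask: *within one tumor type, which
gene mutations predict sensitivity to inhibition of which targets?* A pair
(target, biomarker) where mutant lines are markedly more sensitive to
knockdown of the target than wild-type lines is a synthetic-lethality-style
hypothesis; if the target has a known inhibitor, it is directly actionable.

depmarker implements this screen end to end: input handling and imputation,
cohort-level target pre-filters, a moderated two-group t-test per pair,
grouped local-FDR multiplicity correction, and assembly of a ranked
target–biomarker–drug table.

## Statistical model

### Two-group model per pair

Let $E'$ be the cohort essentiality matrix (targets $\times$ $n'$ cohort
lines) and $m'_p$ the binary mutation vector of biomarker gene $p$. For each
target $t$ the null hypothesis is that the essentiality of $t$ is identical
in mutant and wild-type lines. The fitted effect is

$$\Delta\mathrm{Ess} = \bar e_{t,\mathrm{MUT}} - \bar e_{t,\mathrm{WT}},$$

with pooled residual variance $s^2_t$ on $n' - 2$ degrees of freedom.
Negative $\Delta\mathrm{Ess}$ means mutant lines are *more* essential
(sensitive) for that target; positive means mutants are resistant. The sign
convention is fixed so the ranked table can report both directions.

### Empirical-Bayes variance shrinkage

Cohorts are small (tens of lines), so per-target variances are noisy. We
assume the standard hierarchical model in which true variances follow a
scaled inverse chi-square prior with $d_0$ degrees of freedom and scale
$s_0^2$, estimated across targets by the method of moments on $\log s^2$
(digamma/trigamma matching; `estimate_variance_prior()`). The posterior
variance

$$\tilde s_t^2 = \frac{d_0 s_0^2 + d\, s_t^2}{d_0 + d}, \qquad d = n' - 2,$$

yields the moderated statistic
$t_t = \Delta\mathrm{Ess} / \sqrt{\tilde s_t^2 (1/n_\mathrm{MUT} +
1/n_\mathrm{WT})}$ on $d_0 + d$ degrees of freedom (two-sided; normal when
$d_0 = \infty$, the ordinary pooled t-test when $d_0 = 0$). When the
observed dispersion of $\log s^2$ does not exceed its sampling expectation
the prior degrees of freedom are infinite and every variance shrinks to the
common value. The unit tests verify both limits, the shrinkage bracketing
$\min(s^2, s_0^2) \le \tilde s^2 \le \max(s^2, s_0^2)$, and agreement with
`limma`'s F-distribution fit on simulated hierarchies.

**Prior scope.** By default one prior is estimated per biomarker across all
fitted targets, mirroring one shrinkage fit per design matrix
(`prior_scope = "biomarker"`); a single global prior is available. When a
biomarker grouping contains fewer than two fits, the global prior is used;
with fewer than two fits anywhere, no prior is learnable and the test falls
back to the ordinary pooled t-test ($d_0 = 0$).

### Grouped local false discovery rate

Testing every pair multiplies hypotheses into the tens of thousands, and
biomarker genes differ enormously in signal density. Following the
independent-hypothesis-weighting idea of grouping by an informative
covariate, p-values are partitioned by biomarker gene and each group
receives its own correction:

$$\mathrm{lfdr}(p) = \min\!\left(1, \frac{\pi_0 f_0(p)}{f(p)}\right),
\qquad f_0 \equiv 1 \text{ (uniform null)},$$

where $\pi_0$ is the Storey estimator over the $\lambda$-grid
$0.05, 0.10, \dots, 0.90$ smoothed by a cubic spline and read off at
$\lambda = 0.9$, and $f$ is estimated by transforming p-values to the probit
scale, applying a Gaussian kernel density (Silverman bandwidth scaled by
1.5, the convention of the reference lfdr implementation), and dividing by
the standard normal density. The lfdr is made monotone non-decreasing in $p$
by a running maximum, which removes density-estimation wiggles that would
otherwise make rankings irreproducible. p-values are clamped to
$[10^{-8}, 1 - 10^{-8}]$ before the probit transform.

Groups smaller than `min_group_size_lfdr` (default 50) cannot support their
own density; they are scored against the pooled all-pairs density with
$\pi_0$ forced to 1 — deliberately conservative, so every tested pair still
receives an lfdr and rankings stay total.

**Known limitation: tails of the kernel density.** At the most extreme
p-value of a group, the kernel estimate of $f$ is dominated by that point's
own kernel mass $K(0)/(nh)$ while the uniform-null reference density
$\varphi(x)$ at the same probit coordinate is much smaller; their ratio
inflates $f$ and deflates the lfdr. Consequently an *isolated* group-minimum
p-value of order $10^{-4}$ in a group of a few hundred tests can receive an
lfdr near 0.1–0.2 even under a complete null. This is intrinsic to
density-ratio lfdr estimators evaluated at their own extreme points, and it
is also what gives the method its sensitivity: a genuinely extreme p-value
($10^{-6}$ and beyond) earns a very small lfdr for exactly the same reason,
because the inflation scales as $1/\varphi(x)$. Users should treat lfdr
values near the decision boundary for pairs that are the lone small p-value
in their group with caution, and rely on the case-by-case p-value alongside.

## The screening pipeline

1. **Cohort selection** — all lines of a tumor type, or an explicit list;
   the remaining panel lines form the complement.
2. **Target pre-filters** (`target_prefilter()`), all three required:
   * essential (score strictly below −2) in **more than 20%** of cohort
     lines;
   * cohort-specific: essentiality odds ratio strictly above 1 *and*
     essential in **at most 20%** of complement lines. The odds ratio uses
     the Haldane–Anscombe +0.5 correction only when a 2×2 cell is zero, so
     clean tables are not perturbed;
   * expressed (**≥ 1 TPM**, inclusive) in **more than 75%** of cohort
     lines. Strict/inclusive boundaries follow the wording of each rule
     ("more than", "at most", "minimal expression score").
3. **Pair testing** — every (prefiltered target, biomarker) pair with at
   least `min_group` (default 2) mutants and wild-types.
4. **Grouped lfdr** over *all* tested pairs. The lfdr model is always built
   before any query restriction, so a query for one target, drug or
   mutation returns exactly the matching rows of the unrestricted screen,
   and case-by-case results agree with screen rows.
5. **Thresholds** — lfdr ≤ `max_lfdr` (default 0.5) and
   $|\Delta\mathrm{Ess}| \ge$ `min_abs_delta_ess` (default 2). The
   original description of the effect-size gate is directional but its
   intended sign is ambiguous; since reported hits occur in both
   directions, the gate is implemented as a magnitude threshold (both
   directions), configurable.
6. **Annotation** — drugs attached by exact target-symbol match against the
   DTI table (targets without drugs are kept; druggability is a flag, not a
   filter), unordered interaction-pair support flagged (and optionally
   required), direction labelled mutant-sensitive ($\Delta$ < 0) or
   mutant-resistant.
7. **Ranking** — lfdr ascending, then p-value, then $|\Delta\mathrm{Ess}|$
   descending, then lexicographic (target, biomarker). Only the first key is
   scientifically meaningful; the rest exist to make output byte-for-byte
   deterministic.

`test_pair()` assesses a single pair without the pre-filter battery. When
the pair is part of the screen model its row is returned verbatim; when only
the target was filtered out it is fit with the biomarker's screen prior and
scored against that biomarker's stored group model; when the biomarker has
no screen group at all, the model is built on demand from all targets
against that biomarker. This keeps case-by-case statistics identical to
screen statistics whenever both exist.

`mutation_cooccurrence()` cross-tabulates one biomarker against every other
mutated gene in the cohort (two-sided Fisher exact test, Haldane-corrected
odds ratio), supporting the check that a proposed biomarker is not merely a
passenger of another mutation.

## Input handling

* Matrices are TSV/CSV with row identifiers in the first column and
  cell-line ids in the header; the delimiter is sniffed. "NA"/empty cells
  are missing for essentiality, forbidden for mutation (strictly {0,1}),
  and zero-with-warning for expression.
* MAF-like variant tables are dichotomized per the rule *mutant iff at
  least one record survives the filters*: non-coding/silent classes
  (`Silent`, `Intron`, `3'UTR`, `5'UTR`, `5'Flank`, `IGR`, `RNA`) are
  excluded by default and an allele-fraction floor is available but off by
  default, since the upstream variant-calling filters of public panels are
  not published in reproducible form. A line absent from the variant table
  is wild-type; missing mutation status is not modelled.
* Cell lines are aligned by intersection across all sources (at least 3
  required), in the essentiality matrix's column order; each source's
  dropped lines are reported.
* Missing essentiality scores are imputed by nearest-neighbour averaging
  (`impute_knn()`, default k = 10, the convention of the reference
  implementation of that algorithm): distances between target rows are
  Euclidean over mutually observed coordinates scaled by the number of
  shared coordinates; donors must be observed in the missing line; ties
  break by row order. Imputation runs on the full panel before cohort
  selection, and the pre-filters refuse unimputed matrices.
* DTI potency filtering keeps measured rows (IC50/Ki) strictly below the
  threshold (default 1 µM) and always keeps curated mechanism-of-action
  rows without a measurement.

## Synthetic data and what the tests show

`generate_bundle()` produces fully synthetic panels with known ground
truth. Defaults: 400 lines containing a 22-line cohort, 500 targets, 40
biomarker genes with mutation frequencies uniform in 5–50%, essentiality
scores Gaussian (SD 1) around the grand mean plus planted shifts,
log-normal expression with 10% of targets forced below 1 TPM in much of the
cohort (so the expression filter is exercised), 0–3 fictitious drugs per
target, and an interaction set containing all planted pairs plus decoys.
Planted associations add a score shift (e.g. −3.9, the magnitude of the
strongest reported hit in the motivating application) to mutant lines, with
an optional exact cohort mutant count. An optional per-target baseline SD
(`target_effect_sd`, default 0) emulates genes differing in overall
essentiality; it is switched on (0.7) in the imputation tests, where row
structure is the signal nearest-neighbour averaging exploits, and left off
elsewhere so the null panels are exactly the model the calibration tests
assume.

What the generator does *not* emulate: correlated mutation co-occurrence
structure, copy-number or expression-driven dependencies, screen batch
effects, off-target RNAi structure, and heavy-tailed score noise. Passing
tests therefore demonstrate statistical correctness of the machinery under
its own model, not robustness to the full messiness of real panels.

Problem sizes in the test-suite and acceptance script (chosen to keep the
statistical assertions sharp at desk scale): 1,000 random fixtures for the
classical-t equivalence; 10–20 global-null panels at the default
400 × 500 × 40 scale for calibration; 50 replicate seeds for planted-pair
recovery; 20,000 draws for the beta-uniform lfdr oracle; 10,000 variances
for prior recovery; 20 masked matrices for imputation skill.

## Numerical choices and degenerate inputs

* Zero residual variances join prior estimation through an offset (smallest
  positive $s^2 \times 10^{-6}$); a posterior variance of exactly zero sets
  p to 0 with a degeneracy flag (or 1 when the effect is also zero).
* `trigamma_inverse()` uses Newton iteration with asymptotic guards, as in
  the standard moderated-t implementation.
* All-identical p-values make the probit density degenerate; every lfdr is
  then $\min(1, \pi_0)$, flagged.
* Ties in the neighbour search, drug lists and rankings all break by fixed
  deterministic rules (row order, lexicographic), so one seed produces one
  byte-identical output.
* Undersized mutant/wild-type groups are skipped with a recorded reason,
  never silently dropped; a biomarker with no eligible pairs is absent from
  the screen but `test_pair()` reports the group-size reason.

## Limitations

Beyond the KDE tail behaviour discussed above: the screen tests marginal
association one biomarker at a time (no joint modelling of co-occurring
mutations); covariates such as tissue-of-origin within the complement are
not adjusted for; expression enters only as a pass/fail filter on the
target; and potency filtering treats IC50 and Ki interchangeably. The
ranked table is a hypothesis generator — effect sizes from 22-line cohorts
with a handful of mutants carry wide uncertainty even after shrinkage.
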