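---
title: "Reporter-score enrichment of KEGG modules: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reporter-score enrichment of KEGG modules: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(koscore)
```

## The problem

Shotgun metagenomics of the gut microbiome yields, after profiling with a
tool such as HUMAnN2, a table of per-sample abundances of KEGG Orthology
(KO) gene families, optionally stratified by the genus contributing each
copy. In a two-group cohort — here, a case group of heart-failure patients
versus matched controls — the scientific questions are: which metabolic
*modules* (curated KO sets, e.g. branched-chain amino-acid biosynthesis)
are differentially represented between groups; whether the abundance of a
functional gene set tracks the host's circulating or fecal metabolite
levels; and which taxa are responsible for a module-level shift. `koscore`
implements that analysis chain end to end, together with a synthetic
cohort generator that provides planted ground truth for every stage.

## The reporter-score model

Per-KO differential abundance is tested with a one-tailed Mann-Whitney U
test, alternative "greater in cases", restricted to KOs observed
(non-zero) in **more than** `min_occurrence = 5` samples. Each p-value is
transformed to a Z-score; the default transform is the inverse-normal
(reporter-statistic) form

$$z_i = \Phi^{-1}(1 - p_i),$$

so $z_i \gg 0$ marks case-enrichment and $z_i \ll 0$ control-enrichment of
KO $i$. A module $M$ with $k$ tested member KOs gets the aggregate

$$Z_M = \frac{1}{\sqrt{k}} \sum_{i \in M} z_i,$$

which is then standardised against a size-matched random background: for
each distinct $k$, `n_random_sets = 1000` subsets of size $k$ are drawn
without replacement from the tested-KO universe, and

$$Z^{adj}_M = \frac{Z_M - \mu_k}{\sigma_k}$$

with $\mu_k$, $\sigma_k$ the mean and SD of the background scores.
$|Z^{adj}_M| \ge 1.6$ (inclusive; roughly 90% two-sided confidence under
a normal background) calls the module `enriched_case` or
`enriched_control` by sign.

### Design choices in the scoring

* **Sign convention and the literal variant.** An alternative transform
  that standardises the p-values directly, $z_i = (p_i - \bar p)/s_p$, is
  selectable as `z_variant = "literal_standardized_p"`. It is *not* the
  default because its sign runs backwards (small p, i.e. case-enriched,
  gives negative z), which contradicts the convention that positive
  reporter scores mark case enrichment; the inverse-normal quantile form
  is the canonical reporter statistic and is the default.
* **One signed axis.** Only one one-tailed direction ("greater in case")
  is tested; control enrichment emerges as a negative score. Running the
  two one-tailed tests separately and pooling would give the same calls
  at the same threshold.
* **Background universe.** Random sets are drawn from the post-filter
  tested-KO universe — the only universe the statistic sees — not from
  the full KO space. Modules of equal $k$ share one background draw: the
  backgrounds are statistically identical and sharing is 10–100× faster.
* **k counts tested KOs.** Module members missing from the profile are
  dropped from $k$; `coverage = k / |ko\_set|` is reported so that
  low-coverage modules can be screened downstream. No minimum-$k$ filter
  is imposed by default.
* **Numerical guards.** p-values are clipped to
  $[\varepsilon, 1-\varepsilon]$, $\varepsilon = 10^{-15}$, before the
  quantile transform so exact $p \in \{0, 1\}$ cannot produce infinite z.
  A degenerate background ($\sigma_k = 0$, e.g. all z equal) leaves the
  adjusted score undefined; such modules are never called.

### Mann-Whitney backend

All Mann-Whitney tests (per-KO one-tailed, per-stratum and per-variable
two-tailed) use the exact null distribution (`stats::pwilcox`) whenever
the pooled sample has no ties and both groups have fewer than 50
observations, and otherwise the tie-corrected normal approximation with
continuity correction — the same dispatch as `stats::wilcox.test`, with
which the backend agrees to machine precision in the test suite. The
rank/U computation is vectorised over features because a calibration run
tests tens of thousands of KOs.

A consequence of the exact test worth knowing: the two one-sided exact
tails obey $p_{greater} + p_{less} = 1 + P(U = u)$, so swapping the group
labels negates each z only up to the discrete mass $P(U = u)$ (about
0.02–0.04 in z units at $n = 22$ vs $11$). Module raw scores therefore
flip sign under label swap with a residual bounded by about
$0.05\sqrt{k}$ rather than exactly.

## Cohort statistics

Continuous variables are compared with a normality-gated dispatch:
Shapiro-Wilk on each group at $\alpha = 0.05$ (the conventional omnibus
choice at these group sizes); if both groups pass, a two-sided
pooled-variance Student's t-test with mean ± SD summaries, otherwise a
two-sided Mann-Whitney U with median (25th–75th percentile) summaries. A
group of identical values, on which Shapiro-Wilk is undefined, falls to
the Mann-Whitney branch with a warning.

Categorical 2×2 comparisons use Fisher's exact test under the
probability-mass two-sided rule (sum of the probabilities of all
fixed-margin tables no more probable than the observed one), i.e. the
convention of `stats::fisher.test`. This convention — not the tail-
doubling rule — reproduces the published cohort table's medication
p-values (0.002, 0.015, 0.278, 0.456, 0.438) at the printed precision.

Derived amino-acid panels follow the clinical definitions: essential
amino acids (EAA) = His + Ile + Leu + Lys + Met + Phe + Thr + Trp + Val;
branched-chain amino acids (BCAA) = Leu + Ile + Val; Fischer's ratio =
BCAA / (Phe + Tyr). A not-detected component propagates missingness to
every derived value that uses it, and Fischer's ratio is additionally
undefined when Phe + Tyr = 0.

## Gene-set–metabolite correlation

A gene set (a module's KO set, or the union over a `"target/role"` key
such as `"BCAA/biosynthesis"`) is summarised per sample as the sum of
community KO abundances. Spearman correlation against each analyte is
computed separately within the case and control groups (pooled
correlation behind a flag), with pairwise-complete deletion of
not-detected values — zero-imputation would manufacture ties and distort
the rank statistic, and "not detected" reflects a detection limit, not a
zero. The p-value is exact for $n \le 9$ without ties, otherwise the
asymptotic t approximation. Cells are flagged at raw $p < 0.05$; no
multiple-testing correction is applied across the matrix, matching how
such correlation heatmaps are conventionally starred.

## Contribution networks

The network stage automates the genus → KO → module diagram that is
usually drawn by hand. For each module: its tested KOs become nodes with
membership edges to the module node; for each KO, genera are ranked by
mean stratified abundance over *all* samples (descending, ties broken
alphabetically; the unclassified remainder is excluded from ranking but
reported), and an edge is drawn from every genus that is a top-5
contributor or has a significantly different stratified abundance
(two-sided Mann-Whitney, $p < 0.05$; whether the original hand-drawn
convention was one- or two-sided is unstated, and two-sided is the
conservative choice). Edge annotations carry the rank, top-5 flag,
p-value and direction (`up_in_case` / `down_in_case` by group medians,
falling back to means on a median tie). Genus nodes are flagged when in
the overall top 10 by mean community contribution, and a `depleted` flag
is set from a *supplied* differential-taxa list: taxon discovery (e.g.
LEfSe) is a separate published tool whose output this package consumes
rather than recomputes. Graphs are exported as GraphML via igraph;
not-applicable annotations on membership edges are written as `NaN`/empty
strings so documents round-trip cleanly through independent parsers.

## The synthetic cohort generator

The generator exists so that every downstream stage can be validated with
known ground truth. It emulates:

* a two-group design of 22 case and 11 control samples (the cohort
  structure the package targets);
* genus-level log-normal abundances — per-genus location drawn once from
  $N(\log 50, 1.5^2)$ and scale from $U(0.3, 0.8)$, a simple heavy-tailed
  model that is standard for microbiome toys;
* a fixed genus × KO incidence matrix (density 0.15 by default, every KO
  guaranteed at least one carrier); stratified abundance = genus
  abundance × multiplicative log-normal noise (CV 0.25), and community
  abundance = the exact sum over carriers, so stratified bookkeeping is
  exact by construction;
* planted effects: named genera depleted by a fold in cases, and planted
  modules whose carrier set can be restricted and whose strata can be
  scaled in cases;
* metabolite panels (plasma in µM, fecal in nmol/g, around plausible
  clinical concentration scales) in which linked analytes are built as
  monotone transforms of the linked gene-set's normal scores plus
  Gaussian noise, with the noise calibrated through
  $r_{Pearson} = 2\sin(\pi\rho_S/6)$ so the target Spearman correlation
  holds in expectation within the linked group only.

A single global seed governs all draws through a per-stage seed ladder
(community, module map, metabolites), so identical configurations are
bit-identical and stages are independently reproducible. Zero-inflation
is deliberately absent (default off): the underlying study gives no count
model, and adding one would change what the null-calibration tests mean.

What the generator does **not** emulate: compositional closure effects,
phylogenetic correlation between genera, read-count sampling noise,
zero-inflation, and covariate structure (age, medication). Passing the
planted-recovery tests therefore demonstrates that the statistics recover
effects of the planted kind at the study's sample sizes — not that real
cohort effects of a given biological size will be detected.

The packaged `default_bcaa_scenario()` mirrors the qualitative pattern
the pipeline is designed to detect: *Eubacterium* and *Prevotella*
depleted five-fold in cases while being the sole carriers of two BCAA
biosynthesis modules (M00535, M00432) and (for *Eubacterium*) a histidine
biosynthesis module (M00026); a histidine degradation module (M00045)
planted three-fold up in cases; and plasma Leu/Ile/Val linked to the
BCAA-biosynthesis gene-set abundance at Spearman ρ = 0.6 in cases only.
The depletion fold (5×) follows the canonical planted-depletion example;
ρ = 0.6 is a strong but realistic microbiome–metabolome association.

## Validation problem sizes

The shipped test-suite and acceptance script validate, among others:

* exact equivalence of the Mann-Whitney p-values with exhaustive
  label-assignment enumeration on every group split with total $n \le 8$,
  and of Fisher p-values with hypergeometric enumeration on 200 random
  tables;
* null calibration of the adjusted reporter score on exchangeable
  cohorts of 33 samples × 2,000 KOs with 500 null modules of
  $k \in 3..20$, over 20 seeds (adjusted scores mean ≈ 0, SD ≈ 1, and
  $|Z^{adj}| \ge 1.6$ call rate ≈ 0.11, the two-sided normal tail mass);
* planted-effect recovery on 20 scenario seeds (module direction calls
  and depleted-genus network edges) and planted-correlation recovery on
  50 seeds.

These sizes were chosen as the smallest at which the Monte-Carlo standard
errors are decisively below the tolerances being asserted.

## Known limitations

* Rank-based tests make the pipeline insensitive to the profile's
  normalisation (RPK vs CPM) within a sample set, but the package
  deliberately performs no renormalisation — inputs are validated, not
  rescaled, and mixed-normalisation inputs are the user's responsibility.
* The reporter score inherits the usual gene-set-statistic caveat:
  between-KO correlation (shared taxa) inflates module scores relative to
  an independence background. The random-set background corrects the
  marginal distribution, not the dependence structure.
* Two published cohort-table values (the 0.614 entries) are not
  reproducible under any standard two-sided Fisher convention applied to
  their printed counts and are treated as likely typographical; they are
  not part of the validated surface.
* The exact-test label-swap asymmetry described above is a property of
  exact one-sided tails, not an implementation artifact.
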