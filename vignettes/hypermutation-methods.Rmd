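---
title: "Methods: germline hypermutation analysis in trio cohorts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: germline hypermutation analysis in trio cohorts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hypermutr)
```

# The scientific problem

Every child carries a few dozen de novo mutations (DNMs) — variants present
in their genome but in neither parent. The count per child rises with
parental age, mostly paternal age, because spermatogonial stem cells keep
dividing throughout life. A small number of children, however, carry far
more DNMs than their parents' ages predict: *germline hypermutation*.
Identifying such children in large trio-sequencing cohorts, screening out
the call-set artifacts that mimic them, and attributing the excess to
causes (paternal DNA-repair defects, paternal chemotherapy exposure,
post-zygotic mutation) is the purpose of this package. Because the
clinical cohorts that motivate the analysis are managed-access, the
package ships a generative simulator of trio cohorts with known ground
truth; every stage of the pipeline is exercised and tested against that
truth.

# The count model

Per-child dnSNV counts are modelled with an **identity-link
negative-binomial regression**,

$$E(Y) = \beta_0 + \beta_1\,\mathrm{paternal\ age} +
\beta_2\,\mathrm{maternal\ age}, \qquad
\mathrm{Var}(Y) = \mu + \mu^2/\theta .$$

The identity link matters: mutation counts accumulate additively with each
year of parental germ-cell ageing, so the scientifically meaningful
coefficient is "extra mutations per year", not a rate ratio. The NB noise
captures the overdispersion left after age is accounted for ($\theta \to
\infty$ recovers the Poisson).

Most GLM stacks do not fit an identity-link NB robustly, because the
linear predictor must stay strictly positive. `fit_nb_identity()`
maximizes the NB likelihood directly over $(\beta, \log\theta)$ with an
analytic gradient (BFGS, Nelder–Mead fallback), started from a
least-squares solution shrunk toward the grand mean until feasible, with a
feasibility guard that rejects any step producing a non-positive mean.
Standard errors come from the inverse observed information; Wald p-values
are two-sided normal. Tests verify the optimum against a brute-force
refinement grid of the likelihood on small instances, against the
identity-link Poisson fit at large fixed $\theta$, and by parameter
recovery from simulated cohorts.

Single-parent phased models ($E(Y_{\mathrm{pat}}) = \beta_0 + \beta_1 f$,
and the maternal analogue) and carrier-covariate extensions (binary
paternal/maternal rare-variant indicators plus quality covariates and the
hypermutation-excess term, Bonferroni-corrected across the family of
regressions, conventionally eight) reuse the same machinery.

# Outlier detection

A child is a hypermutation candidate when its **studentized residual** is
extreme under a $t$ distribution with $N-3$ degrees of freedom, at a
Bonferroni threshold of $0.05/N$ where $N$ counts the children analyzed
after exclusions.

"Studentized residual" is OLS vocabulary; for a GLM a construction must be
chosen. We use leverage-scaled **deviance** residuals,
$d_i/\sqrt{1-h_i}$, with leverages from the weighted hat matrix
($W_i = 1/\mathrm{Var}(Y_i)$). This is the construction behind R's
`rstudent()` for GLMs, and the choice is not cosmetic: NB counts are
right-skewed, and leverage-scaled *Pearson* residuals inherit that skew,
so a nominal Bonferroni scan on them flags far more than $\alpha$ of null
cohorts. Deviance residuals normalize the skew and the scan then holds
its family-wise error in our null simulations. Pearson studentization
remains available (`studentized_residuals(fit, type = "pearson")`).

## The loss-of-transmitted-allele artifact

The dominant false-positive mode in trio call sets is a parental somatic
deletion in blood: the child's inherited allele looks de novo across the
deleted region, producing hundreds to over a thousand apparent DNMs
clustered on one chromosome, with a matching regional loss of
heterozygosity (LOH) in that parent. `artifact_screen()` flags a child
when (a) at least half of its calls fall inside a single clustering
window (default 100 kb on the package's 1/100-scale simulated genome, the
analogue of a 10 Mb window) and (b) a parent's regional het/hom site-count
ratio drops below half its genome-wide value. Regional counts are
overlap-weighted so windows straddling the implicated region do not
dilute the LOH signal. The two sub-flags are reported separately; both
are required to call an artifact, and `scan_with_artifact_exclusion()`
then removes artifact children and refits once — the screen-then-refit
procedure the two-pass thresholds ($0.05/N$ before and after exclusion)
describe.

## Characterization

Each candidate is profiled against cohort references: per-type enrichment
(two-sided Poisson tests for C>A, C>G, C>T, T>A, T>C, T>G and indels
against cohort per-child means, Bonferroni at $0.05/(12\times7)$ for the
conventional 12-individual follow-up), parental phase bias (two-sided
binomial against the cohort phased paternal fraction — not 0.5, since
"more paternal than expected" means relative to the ~0.77 cohort
expectation), VAF shift (binomial test of the proportion of calls with
VAF < 0.4, the post-zygotic mosaic signature), and transcriptional strand
bias (Poisson test of transcribed-strand counts against half the stranded
total). The two-sided Poisson test uses the minimum-likelihood
construction (sum of all outcome probabilities not exceeding the observed
one), which is what `stats::poisson.test` computes; a test verifies it
against direct enumeration.

# Parent-of-origin phasing

A DNM is phased from read evidence: heterozygous sites within 500 bp
(inclusive — "within" is read inclusively) where each child allele is
attributable to exactly one parent (sites heterozygous in child and both
parents are uninformative), and fragments observing both loci. The DNM is
called paternal or maternal only when every alt-carrying fragment points
to the same parent; mixed evidence is a conflict, and one supporting
fragment suffices by default (configurable), mirroring the "exclusively
on one haplotype" rule. A fragment counts once even if both mates span
both loci. The per-trio paternal proportion is regressed on paternal age
with an identity-link binomial GLM — the additive change-per-year scale —
with a logit option.

# Mutational signatures

Spectra are 96-channel counts in the conventional pyrimidine-strand
trinucleotide layout (six substitution classes alphabetical, 16 flanking
contexts alphabetical); purine-reference calls are folded by reverse
complement, conserving totals. Refitting onto a catalogue is plain
nonnegative least squares (`pracma::lsqnonneg`) with pruning of
exposures below 1% followed by a refit. De novo extraction is
multiplicative-update NMF (Frobenius objective, non-increasing by
construction) with random restarts; the best-objective run is kept and a
stability score (mean matched cosine of restarts against the best run) is
reported per rank, with the rank choice left to the caller. Signature
matching uses exhaustive best-assignment over permutations (ranks here
are small). The bundled `signature_catalogue()` is an explicitly
*synthetic* stand-in — five profiles with the qualitative shapes relevant
to germline work (CpG-deamination clock, flat background, platinum-like,
alkylating-like, T>C-rich repair-defect-like); any published catalogue in
the standard 96-row layout can be supplied instead.

# Variance decomposition

Counts are Poisson-noisy even at a perfectly known rate, so only
super-Poisson variance is explainable. The fraction of that variance
attributed to a model is

$$F = R^2 \cdot \frac{\mathrm{Var}(Y)}{\mathrm{Var}(Y) - \bar Y}
    = \frac{R^2}{1 - \bar Y/\mathrm{Var}(Y)} .$$

Three nested identity-link NB models are fitted — parental age only;
plus data-quality covariates (trio mean coverage, aligned-read
proportions, SNV counts, median VAF, median caller quality, standardized);
plus the hypermutation-excess covariate (observed minus cohort median for
flagged children, zero otherwise) — and component contributions are the
increments of $F$, which telescope exactly to the full-model $F$; the
residual fraction is $1 - F_{\mathrm{full}}$.

Two flavours of $R^2$ are supported, and the distinction matters. The
McFadden pseudo-$R^2$ ($1 - \ell/\ell_0$) is likelihood-based and is
systematically small on NB data (a cohort whose age terms carry ~70% of
the super-Poisson variance yields a McFadden ratio of only ~0.05–0.1, and
hence an $F$ far below the variance share). The OLS $R^2$ of the same
mean models *is* a variance ratio, so the resulting $F$ consistently
estimates the generative explainable-variance share — our recovery tests
confirm the configured 70% share is recovered within a few points. The
default is therefore `method = "ols"`, with `"pseudo_r2"` available; both
are computed from the same nested design.

Uncertainty comes from a case-resampling bootstrap over trios (1,000
replicates, 2.5/97.5 percentiles; resampling residuals instead was
considered and rejected as less assumption-free). The classic
small-cohort instability is demonstrated by `resampling_experiment()`:
repeatedly drawing 78 trios, fitting OLS of count on paternal age and
computing $F$ — the spread (sd above 0.05, a 95% interval wider than 0.3)
shows why early 78-family estimates of ~95% age-explained variance and
large-cohort estimates of ~70% are statistically compatible.

# Exposure analysis

Parents are classified from coded hospital records: eligibility requires
at least one record two or more years before the child's birth year (a
year-resolution proxy for "before conception"); a pre-conception cancer
diagnosis is any 'C'-prefix (malignant neoplasm) or 'Z85'-prefix
(personal history) code under the same dating rule, and 'Z511' marks an
antineoplastic-chemotherapy encounter. Prefix matching is literal; the
known sensitivity limit — parents treated without qualifying codes before
conception — is inherent to code-based classification and cannot be
recovered by design. Effects on offspring are tested by (i) Wilcoxon
rank-sum on residuals from the full NB model, (ii) an age-matched
comparison drawing 20 controls per case with replacement, matching
paternal and maternal age exactly first and widening to ±2 years if
needed (the caliper is our choice; none is prescribed), and (iii) exact
two-sided Fisher tests of hypermutation counts, verified exhaustively
against hypergeometric enumeration for small margins.

# The simulator: what it emulates, and what it does not

`simulate_cohort()` generates the statistical structure the analysis
assumes:

* **Ages.** Maternal age truncated-normal (mean 30, sd 4.5, range 18–45);
  paternal age = maternal + normal offset (mean 3, sd 2.5), truncated to
  18–60. Medians land near 33/30, the typical cohort values.
* **Counts.** NB with mean $20 + 1.28 f + 0.35 m$ — the canonical
  large-cohort slopes — and dispersion $\theta = 200$. The dispersion is
  not published for such cohorts; $\theta = 200$ was fixed from the
  closed-form variance decomposition so that parental age carries ≈70% of
  the super-Poisson variance under the default age distribution, giving
  Var/mean ≈ 2.2. It is a config field, not a constant.
* **Phase.** Each DNM is paternal with probability
  $0.77 + 0.0017\,(f - 33)$, clipped to a probability and validated over
  the configured age range.
* **Calls.** Each DNM gets a 96-channel class from its etiology's
  signature mixture (baseline: 16% clock-like, 84% flat — the usual
  SBS1/SBS5-like split), a uniform position on a 23-chromosome genome
  scaled to 1/100 of the human assembly, and binomial read support at
  ~35x. Depths are drawn from a >20-truncated Poisson and constitutive
  het calls keep their observed VAF inside (0.3, 0.7): the generator
  emulates a *released, QC-filtered* call set, which is what makes "true
  DNMs survive the filters" a structural property. Mosaic (post-zygotic)
  injections keep raw binomial draws at a true VAF of 0.10–0.35 — their
  shifted VAF is the biological signal.
* **Injections.** Hypermutators by etiology (repair defect: multiply the
  paternal count; chemotherapy-like: add paternal DNMs from a named
  signature; post-zygotic: add ~50/50-phase low-VAF DNMs) and the
  loss-of-transmitted-allele artifact (clustered pseudo-DNMs in one
  region plus depressed parental regional heterozygosity).
* **Trinucleotide context** is carried as a label on each simulated call
  rather than derived from a bundled reference sequence; the real-data
  path may derive contexts from a FASTA upstream.

What the simulator does **not** emulate — and hence what passing tests do
not show about real data: alignment and calling error beyond the modelled
artifact mode, mappability structure and clustered repeats, multi-site
linkage between DNMs, indel spectra (indels enter only as a count
channel), relatedness between trios, and real signature profiles (the
catalogue is synthetic). Results on real cohorts depend on those
upstream properties in ways desk-scale simulation cannot certify.

# Filtering rules

Two rule sets are implemented with per-rule failure accounting. The
whole-genome cohort set: child 0/1 and parents 0/0; trio read depth
strictly above 20; at most one alt read per parent; child VAF strictly
inside (0.3, 0.7); child depth at most 98; segmental-duplication and
simple-repeat BED masks (0-based half-open, point-in-interval); and
removal of *all* members of any chain of SNVs from the same child within
20 bp (inclusive, transitive — the source text does not say whether one
or both members were dropped; both is the conservative reading and is a
config choice). X-chromosome calls use sex-specific variants of the rules
with pseudoautosomal regions treated autosomally (hemizygous male calls
allowed). The 11-rule exome-cohort set adds strand-bias (Fisher on
forward/reverse alt reads, child versus parents combined — the exact 2×2
is not prescribed; this construction is documented in code), population
allele frequency, parental VAF, caller posterior and per-site error-rate
rules (one-sided binomial test of child VAF above the supplied error
rate). Printed inequalities are treated as strict exactly as written;
every threshold is overridable. A missing required field fails
"incomplete-record"; a missing optional DDD-path field marks the rule
"not-evaluable" and removes the call (conservative).

# Problem sizes and numerical choices

Test and acceptance runs use 5,000-trio cohorts for count-level work
(parameter recovery over 50 replicates; 200 null cohorts and 100
injection cohorts for the scan's operating characteristics), 400–1,500
trio call-level cohorts for phasing and artifact screening, 5,000 sampled
mutations for signature refitting, 24 samples for NMF recovery, and
2,000–5,000 resampling replicates — sizes at which every Monte-Carlo
tolerance in the test suite is a few multiples of its standard error.
Optimizer tolerances: BFGS relative tolerance 1e-12, NMF tolerance 1e-9
with up to 2,000 sweeps, NNLS exact via active set. Ties and degenerate
inputs: all-one-parent phased sets return a boundary fit (proportion 0
or 1, slope 0); all-zero carrier columns are reported inestimable rather
than dropped silently; constant responses warn; cohorts with
Var(Y) ≤ mean(Y) report F as undefined rather than extrapolating.

# Known limitations

Identity-link NB fits can sit near the feasibility boundary when slopes
are large and ages small; the fit flags boundary solutions rather than
constraining them away. The deviance-residual t approximation is
calibrated in our simulations but remains an approximation — with very
small cohorts (hundreds of trios) the scan should be read as a screen,
not a test. NMF recovery is only tested for well-separated planted
signatures; highly collinear signatures will not be resolved at desk
scale. The exposure classifier's sensitivity is bounded by record
coverage, as noted above.
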