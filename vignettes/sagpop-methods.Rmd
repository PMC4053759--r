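---
title: "Models and methods in sagpop"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods in sagpop}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

sagpop analyses populations of partial single-amplified genomes (SAGs):
it quantifies how much of the observed nucleotide variation entered the
population through homologous recombination rather than point mutation
(the r/m ratio), reconstructs gene gains and losses on a fixed genealogy,
measures synonymous divergence within and between tight subclades
("microclusters"), and recruits metagenome reads to a composite reference
to profile microcluster abundances in the environment. A first-class
synthetic-data generator produces all of these inputs with known ground
truth, so every estimator in the package is validated by parameter
recovery. This vignette describes the models, the defaults and why they
were chosen, and the limits of what the synthetic validation shows.

## The synthetic-data generator

The generator is the package's definition of the study conditions; its
defaults are not tuning knobs.

**Genealogy.** `simulate_genealogy()` draws a Kingman coalescent tree
(`ape::rcoal`, pairwise coalescence rate $k(k-1)/2$) and rescales branch
lengths so the root-to-tip depth is one unit; all rates are then "per site
per unit branch length". The coalescent is a neutral stand-in: nothing is
known about the true genealogy shape or effective population size of the
sampled population, and none of the downstream estimators depends on the
tree prior. The unscaled tree (`rescale = FALSE`) retains coalescent units,
under which the expected time to the most recent common ancestor is
$2(1 - 1/n)$ — used as a Monte-Carlo check of the implementation.

**Clonal substitutions.** Jukes–Cantor: a uniform random root sequence; on
a branch of length $l$, Poisson($\mu l L$) substitutions at uniform
positions, each to a uniform alternative base. JC was chosen because the
downstream synonymous-divergence estimator applies the JC multiple-hit
correction, so the generative and inferential models match. Every event is
recorded, which lets `overlay_imports()` replay the clonal history exactly
and superimpose recombination without re-drawing it.

**Imports.** On each branch, Poisson($R\,l\,L$) import initiations at
uniform starts; tract lengths are geometric with mean $\delta$ (memoryless
tracts, the standard model for bacterial gene conversion), truncated at the
sequence end without wraparound. Each tract site is substituted with
probability $\nu$ toward a uniform alternative base — mimicking divergent
donor DNA without simulating a donor population. The realized
recombination-to-mutation ratio is the ratio of import substitutions to
clonal substitutions; its expectation is $R\delta\nu/\mu$, and at
$L = 10^6$ the realized value is within a few percent of that target.

**Gene flux.** Root presence per ortholog cluster is Bernoulli(0.8); on a
branch of length $l$ an absent cluster is gained with probability
$1 - e^{-g l}$ and a present one lost with probability $1 - e^{-\ell l}$.
The default loss rate (0.4) exceeds the gain rate (0.2), reflecting the
streamlined, reduction-dominated genomes being modelled.

**Amplification dropout.** `degrade_to_sag()` keeps a Normal(mean, sd)
fraction of the genome (clipped to (0, 1], resampled while non-positive) as
5–100 contiguous blocks — multiple displacement amplification amplifies
contiguous regions — and injects per-base errors at `err_rate` (default
5×10⁻⁶, the benchmark assembly error regime). Defaults recover 60% ± 15%
per SAG, so a typical gene is seen in roughly 6 of 10 SAGs.

**Metagenome reads.** Uniform positions and strands from genomes drawn by
abundance weights; 400 bp reads (the pyrosequencing-era length implied by
the lake datasets' reads-to-megabase ratios) with constant quality strings.

**Microcluster community.** `simulate_microcluster_community()` fixes the
divergence geometry of the study population: three clusters of equal size,
members at 0.015 substitutions/site from their cluster ancestor (pairwise
within-cluster divergence 0.03, hence dS well below 0.05 and ~13–16 SNPs/kb
against the cluster consensus) and clusters separated by 0.5
substitutions/site pairwise. Because evolution here is neutral and uniform
across sites, dS, dN and total divergence coincide — real coding sequences
concentrate divergence at synonymous sites, so between-cluster *genome*
identity in these simulations (~63%) is lower than in real data with the
same dS. Conclusions that depend on that identity (e.g. which reads can be
recruited across clusters) are therefore conservative in the simulations.

**Randomness.** Every stage derives its own seed from the master seed and a
stage label (`stage_seed()`), so stages are independently reproducible and
identical seeds give bit-identical outputs.

## Recombination: the import HMM and r/m

The estimator mirrors the role a Bayesian import-detection method plays in
this kind of study, but it is deliberately *not* a re-implementation of
that machinery: it is a deterministic EM point-estimator of the same
generative quantities, reporting the same composite statistic (r/m).

The observation layer (`assign_substitutions()`) reduces the alignment to
per-branch binary event tracks by Fitch parsimony: each column's state
changes are assigned to branches top-down, keeping the parent state
wherever compatible and otherwise choosing the lexicographically smallest
compatible base — a deterministic convention that places ambiguous changes
rootward. Columns containing a gap or ambiguous base anywhere are treated
as missing on every branch. Two consequences matter: changes on the two
root-child branches cannot be polarized without an outgroup (they are
pooled in diagnostics), and at very high import densities homoplasy makes
parsimony scatter a few percent of import events onto wrong branches,
which biases r/m slightly downward (see Limitations).

Along each branch $b$, columns follow a two-state hidden Markov chain:

* clonal state: event probability $1 - e^{-l_b}$;
* import state: event probability $\nu$ (shared across branches);
* transitions: clonal→import $1 - e^{-R l_b}$, import→clonal $1/\delta$.

`fit_import_hmm()` runs forward–backward per branch (compiled code) and
Baum–Welch updates. $\nu$ and $\delta$ have closed-form M-steps; $l_b$
couples the clonal emission and the clonal→import transition, so $(l_b, R)$
are updated by coordinate ascent on the expected complete log-likelihood
(a generalized EM step), keeping the likelihood provably non-decreasing —
this is asserted at every iteration. Initialization: $\nu_0$ = 10× the mean
observed event rate, $\delta_0$ = 500 bp, $R_0 = 10^{-4}$, with ±50%
multiplicative jitter across restarts under fixed seeds; the best
likelihood wins. Convergence is relative (`tol`, default $10^{-6}$) with a
500-iteration cap; non-convergence returns the best fit flagged
`converged = FALSE`.

r/m is reported two ways: the primary estimate is the ratio of
posterior-expected event counts in the import versus clonal state, which
stays meaningful under model misfit; the plug-in $R\delta\nu$ is also
reported. When the fitted likelihood beats the clonal-only model by fewer
than 2 log units the fit is flagged `flat` (import state not identifiable).
`fit_recombination()` wraps tree inference (neighbor joining on
JC-corrected distances, midpoint-rooted, negative branches clamped to 0),
track assignment and the EM fit into a classed model object with the usual
`print`/`summary`/`coef`/`logLik`/`plot`/`residuals`/`simulate` methods.

**Regime conditions.** The two benchmark regimes are r/m = 0.14 with
$\mu = 0.01$, $\nu = 0.05$, $\delta = 1$ kb (a clonal, relatively diverged
population) and r/m = 60 with $\mu = 8\times10^{-4}$, $\nu = 0.1$,
$\delta = 1$ kb (a population whose diversity comes almost entirely from
imports; its *clonal* divergence is much lower — the study's marine
re-analysis dataset was likewise less diverged than the freshwater one).
The high-regime donor divergence was set to 10% because lower values
spread the same import substitution mass over proportionally more tract
coverage, to the point where overlapping tracts on ancestor–descendant
branches collide at the same sites and parsimony can no longer place
events — a physically unrealistic corner, not a harder version of the same
regime. For grid points between the extremes (r/m = 1, 10), $\mu$ and
$\nu$ are interpolated so total divergence stays moderate. Problem sizes
throughout (9 taxa × 25 kb, 50 seeds per headline regime, 2 EM restarts at
tolerance $10^{-5}$ for the bulk sweeps) were chosen to keep a full
validation run on one CPU in minutes while leaving Monte-Carlo error well
below the effect sizes being checked.

## Gene flux: Sankoff with ACCTRAN

`sankoff_reconstruct()` runs, per cluster, the bottom-up Sankoff dynamic
program over presence states {0, 1} with costs gain = 2, loss = 1 by
default, and no root-state prior. Two deterministic conventions resolve
ties (the original analysis tool's exact internal tie-breaking is not
published, so these are documented as this package's conventions):

* **Root ties resolve to absence.** A cluster confined to one clade then
  surfaces as a gain on that clade's stem rather than as parallel losses —
  the acquisition reading, and the one that makes simulated stem gains
  recoverable. An explicit `root_state` argument overrides this.
* **Traceback ties prefer a change on the current branch** (accelerated
  transformation: changes as close to the root as possible), with child
  order = input order.

Copy counts are binarized before reconstruction (presence/absence
disregarding copy number). `penalty_sweep()` re-runs the reconstruction
over gain costs 2–5 and reports gained-cluster counts on a focal branch.
For the clean clade patterns produced at low event rates the count is
non-increasing in the gain cost; note this is not a theorem for arbitrary
patterns — a pattern whose loss-explanation needs three or more
compensating losses can flip *toward* a stem gain as gains get more
expensive — so the monotonicity property is validated on simulated
gene-flux matrices, which is also the regime in which the sweep is
scientifically interpreted. `build_composite_taxon()` implements the
partial-genome pooling rule: a cluster counts for the composite if seen in
two or more partial genomes, or in exactly one but with an external-genome
hit. A fallback single-linkage clusterer (`cluster_genes()`) is provided
for when ortholog membership tables are not available from a dedicated
clustering tool.

Gains and losses inferred on branches adjacent to the root are polarity-
ambiguous without outgroups; reconstructions on outgroup-free trees should
be read accordingly.

## Divergence: NG86 dS, masking, consensus and SNP statistics

`ng86_ds()` implements Nei–Gojobori (1986) counting with Jukes–Cantor
correction: synonymous site counts per codon are the fraction of the three
possible changes per position that preserve the amino acid (changes to
stops count as nonsynonymous); multiply-substituted codons average their
difference counts over all minimal mutational pathways with equal weights,
dropping pathways through stop codons (if every pathway is blocked, all
are used with stop steps scored nonsynonymous). Codons containing gaps,
ambiguous bases or stops in either sequence are skipped pairwise;
ambiguous bases are treated as gaps everywhere in the package. dS is
$-\tfrac34\log(1 - \tfrac43 p_S)$, undefined (flagged `saturated`) at
$p_S \ge 3/4$. The study's original tool was a codon-frequency-weighted
maximum-likelihood counter whose internal weighting is not re-derivable
from its outputs; NG86 preserves every filtering decision and the
within/between contrast, and externally computed dS tables can be slotted
into the same long-format table.

`pairwise_ds_table()` applies the two 70% filters: members covering less
than 70% of the gene alignment are removed, and a gene is excluded for a
pair when fewer than 70% of alignment columns are actually used by the
calculation. Per-pair medians are taken over retained genes with defined
dS. `mask_blocks()` approximates conservative block filtering with two
rules — drop columns whose gap fraction exceeds 0.5, then drop kept runs
shorter than 10 columns; the full conservation-class logic of the original
block-masking tool is deliberately not reproduced. `consensus_sequence()`
takes the per-column majority among non-gap characters, ties to the
lexicographically smallest base. `count_global_snps()` counts mismatches
flanked by 20 perfectly matching columns on each side, normalized per
assembled megabase — the flank requirement suppresses alignment-edge
artifacts so the statistic tracks true per-base error rates.

## Recruitment: patchwork, filters, assignment

`build_patchwork()` joins scaffolds by end-overlap: seeded with the
largest scaffold of the first taxon, extended at either end by the unused
scaffold with the longest overlap of at least 10 kb, requiring 95%
identity over the overlap (the source procedure specifies only
"substantial" overlaps; 95% is this package's threshold). Non-overlapping
scaffolds are appended at the end, taxon by taxon. Segments record full
provenance and tile the reference without overlap.

`recruit_reads()` is a seed-and-extend aligner standing in for a
whole-genome aligner: exact 15-mer seeds vote for a diagonal, and a local
affine-gap alignment (match 1, mismatch −2, gap open 4, extend 1; band 32)
is computed around it on both strands, keeping the best score (ties to the
leftmost coordinate; one location per read). Because an exact 15-mer can
be absent near the 75%-identity boundary even where a qualifying local
alignment exists, seeding falls back to 11-mers when 15-mers find nothing
on a strand. The recruitment filters are strict inequalities: identity
> 0.75 AND aligned length > 150 bp AND aligned fraction of the read > 0.5.
The recruited set is validated against a full Smith–Waterman oracle plus
the same filters. `summarize_recruitment()` computes percent recruited and
fold coverage = recruited fraction × dataset Mb / reference Mb, with
one-decimal rounding for report output.

`trim_reads_to_genes()` intersects recruited intervals with gene
coordinates (GFF3 is 1-based closed on disk, 0-based half-open in memory;
conversion happens at I/O), keeping slices with ≥ 150 bp overlap; slice
sequences are cut from the read assuming near-collinear alignment, which
is exact for the indel-free simulations and approximate otherwise.
`assign_microcluster()` labels a slice by its highest-identity
microcluster consensus, requiring a 0.02 identity margin over the
runner-up — a distance-based substitute for per-gene phylogenetic
placement of reads, validated to ≥95% accuracy under the study divergence
regime. `abundance_profile()` turns assignments into per-sample fractions.

## Pipeline

`run_pipeline()` executes community simulation → divergence → two-regime
recombination fits → gene flux (+ penalty sweep) → recruitment on one
seed, writing plain-text outputs and a JSON manifest (seed, parameter
fingerprint, per-stage summaries); reruns with the same configuration are
bit-identical. `pipeline_config()` holds every threshold with the study
defaults (0.75 / 150 bp / 0.5 recruitment filters, 70%/70% dS filters,
10 kb patchwork overlap, 20 bp SNP flank, gain 2 / loss 1) and rejects
unknown keys. `make_report()` assembles whatever stage outputs exist into
`report.json`/`report.txt`, listing missing stages as skipped.

## Numerical choices and degenerate inputs

* Forward–backward is scaled per column; emissions and transitions are
  clamped away from 0/1; all-zero event tracks short-circuit to r/m = 0
  with a degenerate-fit warning.
* Saturated pairwise distances ($p \ge 3/4$) abort tree inference with an
  error naming the offending pair.
* `mask_blocks()` returning zero columns is a warning, not an error.
* Consensus ties and Fitch refinements use lexicographic conventions so
  every output is deterministic.
* Coordinates are 0-based half-open internally everywhere; GFF3 conversion
  happens only at the I/O boundary.

## Limitations

* The r/m estimator is a point estimator; it produces no credible
  intervals and does not co-estimate the genealogy. At very high import
  density the parsimony observation layer scatters a few percent of import
  events, biasing r/m downward (median recovery within a factor ~1.5 at
  r/m = 60); regime *contrast* is far more robust than absolute values.
* The simulator has no indels, no chimeras, no contamination, and no donor
  population; import substitutions are independent across sites, unlike
  real donor haplotypes.
* Neutral uniform-rate evolution makes nucleotide and synonymous
  divergence coincide; see the microcluster note above.
* The gene-flux reconstruction inherits parsimony's blindness to multiple
  events per branch and the root-polarity ambiguity on outgroup-free
  trees.
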