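# sagpop

Comparative population genomics for partial single-amplified genomes
(SAGs). The package answers a question that matters for any clonal
microbial population sampled one cell at a time: **how much of the
observed nucleotide variation entered the population through homologous
recombination rather than point mutation?** Around that core it provides
the companion analyses such a study needs — ancestral gene-content
reconstruction, synonymous-divergence profiling of tight subclades
("microclusters"), assembly-error statistics, and metagenome fragment
recruitment — together with a synthetic-data generator that produces every
input with known ground truth, so each estimator is validated by parameter
recovery.

## The models

**r/m estimation.** Along each branch *b* of a clonal genealogy, alignment
columns alternate between a *clonal* state, where a substitution occurs
with probability 1 − exp(−l_b), and an *import* state (DNA replaced by a
recombination tract), where it occurs with probability ν. Transitions
clonal→import happen at rate 1 − exp(−R·l_b) and import→clonal at 1/δ,
with R (import initiation rate), δ (mean tract length) and ν (donor
divergence) shared across branches. Substitutions are assigned to branches
by column-wise Fitch parsimony, the two-state HMM is fitted by
Baum–Welch EM (multiple jittered restarts, compiled forward–backward), and

&nbsp;&nbsp;&nbsp;&nbsp;r/m = (posterior-expected substitutions in the
import state) / (posterior-expected clonal substitutions),

with the plug-in R·δ·ν reported alongside. The fit is an S3 model object
with `print`, `summary`, `coef`, `logLik`, `plot`, `residuals` and
`simulate` methods.

**Gene flux.** Presence/absence of ortholog clusters (copy numbers
binarized) is reconstructed on a rooted tree by weighted Sankoff parsimony
(gain cost 2, loss cost 1 by default) with accelerated-transformation
tie-breaking, plus a gain-penalty sweep (costs 2→5) that separates
near-certain gains from gain-versus-repeated-loss ambiguities.

**Divergence.** Pairwise dS/dN by Nei–Gojobori (1986) counting with
Jukes–Cantor correction, under the study's filters (members covering
< 70% of a gene removed; genes with < 70% usable columns excluded per
pair); majority-rule consensus sequences; SNPs/kb against a microcluster
consensus; and a "global SNP" error statistic (mismatches flanked by 20 bp
of perfect identity per side, per assembled Mb).

**Recruitment.** A patchwork reference joined from scaffolds overlapping
by > 10 kb; seed-and-extend read recruitment with the strict filters
identity > 75%, aligned length > 150 bp, aligned fraction > 50%;
gene-boundary trimming (≥ 150 bp slices); nearest-consensus microcluster
assignment with an identity margin; per-sample abundance profiles.

## Worked example

Simulate a 9-taxon, 25 kb alignment in the low-recombination regime
(true R·δ·ν/μ = 0.14) and estimate r/m:

```r
library(sagpop)

tr  <- simulate_genealogy(9, seed = 7)
cfg <- sim_config(seed = 7)          # low-recombination defaults
sim <- overlay_imports(simulate_clonal_sequences(tr, cfg), tr, cfg)
realized_rm_oracle(sim$truth)        # ground truth for this replicate
#> [1] 0.04273504

fit <- fit_recombination(sim$alignment, seed = 7)
fit
#> Two-state import HMM fit (EM)
#>   r/m (posterior counts): 0.04409   r/m (plug-in R*delta*nu): 0.0251
#>   R = 0.00115 per site per unit branch, delta = 433.0 bp, nu = 0.0505
#>   log-likelihood -7586.54 after 4 iterations (converged)
```

The estimate (0.044) matches this replicate's realized truth (0.043): at a
generative ratio of 0.14 the per-seed realized value scatters widely
because only a handful of import tracts land on a 25 kb fragment — which
is exactly why regime-level conclusions are drawn from seed ensembles, not
single fits. Recruitment summaries use the printed-table arithmetic:

```r
summarize_recruitment(29262, 554862, 233, 1.05)
#>   recruited  percent coverage percent_report coverage_report
#> 1     29262 5.273744 11.70269            5.3            11.7
```

i.e. 29,262 of 554,862 reads (5.3%) from a 233 Mb dataset recruited to a
1.05 Mb reference imply 11.7× fold coverage. `run_pipeline()` chains all
stages on synthetic data and writes plain-text tables plus a JSON
manifest; reruns with the same seed are bit-identical.

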