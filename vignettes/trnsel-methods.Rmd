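---
title: "Methods: selection coefficients across a regulatory network"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: selection coefficients across a regulatory network}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(trnsel)
```

This vignette documents the statistical machinery of `trnsel`: the count
model and its assumptions, the synthetic-data generator that stands in for
the original genomic inputs, and the numerical and design choices that were
genuinely open when the package was written.

## The modified McDonald–Kreitman count model

The unit of data is a per-gene 2×2 table of mutation counts: silent versus
selected sites, polymorphic (segregating within the focal population)
versus fixed (divergent against the outgroup). "Selected" means replacement
(nonsynonymous) sites for the coding context, or the putative
*cis*-regulatory window for the regulatory context — the regulatory contrast
follows the classic modification of the MK test in which upstream sites are
compared against the same gene's silent sites.

Counts are modelled as independent Poissons on a log-linear scale:

$$\log E[y_{ic}] = \log L_{ic} + \mu + \beta_F I_{fixed}
 + (\beta_R + r_i)\,I_{sel} + (\beta_{RF} + s_i)\,I_{sel}I_{fixed} + a_i$$

* $a_i$ absorbs gene-level diversity (sequencing depth, local mutation
  rate, coalescent history);
* $r_i$ absorbs gene-level constraint on the selected class
  (the replacement-to-silent rate ratio);
* $s_i$ is the quantity of interest: the gene's departure of the
  fixed:polymorphic odds in the selected class from the silent class, i.e.
  a log fixation-rate ratio.

The total selection effect $e_i = \beta_{RF} + s_i$ maps to a
population-scaled selection coefficient through the Poisson random field
fixation-rate ratio $g(\gamma) = \gamma/(1 - e^{-\gamma})$ (with
$g(0) = 1$): $\hat\gamma_i = g^{-1}(e^{e_i})$. `g` is strictly increasing
and satisfies $g(\gamma)/g(-\gamma) = e^\gamma$ exactly, which the test
suite checks numerically. Inversion is by bracketed root finding to
$|g(\gamma) - r| < 10^{-10}$.

One deliberate simplification: only the divergence-side dependence on
$\gamma$ is modelled. In the full random-field derivation the polymorphism
level also depends (weakly) on $\gamma$; here that dependence is absorbed
into $r_i$. The synthetic generator uses the same convention, so recovery
tests are self-consistent, and the simplification biases real-data
estimates only through a reinterpretation of the constraint effect.

Classification uses point estimates, matching how results of this kind are
usually reported: $\hat\gamma > 1$ positive, $\hat\gamma < -1$ negative,
the closed interval $[-1, 1]$ near-neutral. Interval endpoints are
propagated through the monotone mapping from a normal approximation on the
$e$ scale.

## Estimation: Laplace fit plus mixture re-shrinkage

`fit_mk_glmm()` fits the marginal model by Laplace-approximate penalized
likelihood (lme4's `glmer`, Poisson family, independent random effects,
site-opportunity offsets). This is deterministic — identical inputs give
identical fits — which we prefer as a default over MCMC.

The per-gene conditional modes from a single normal prior on $s_i$ are,
however, a poor default estimator for this problem. Selection-effect
distributions are spike-and-tail shaped: most genes sit in a tight
near-neutral cluster while a minority are strongly selected. A single
normal prior must inflate its variance to accommodate the tails, and the
inflated prior then under-shrinks the near-neutral majority, spilling their
estimates across the $\pm 1$ class boundaries. During design we measured
this as a systematic few-percentage-point undercount of near-neutral genes
in mixture-truth simulations.

The default (`shrink = "mixture"`) therefore re-estimates the gene effects
by empirical Bayes under a 3-component normal mixture prior:

1. the conditional modes and conditional variances are "unshrunk" back to
   per-gene pseudo-MLEs $z_i$ with effective data variances $v_i$, using
   the normal-normal identities
   $v_i = (1/\mathrm{condvar}_i - 1/\sigma_s^2)^{-1}$ and
   $z_i = \beta_{RF} + \mathrm{mode}_i\,(v_i + \sigma_s^2)/\sigma_s^2$;
2. a mixture $\sum_k w_k\,N(m_k, \tau_k^2)$ is fitted to
   $z_i \sim N(e_i, v_i)$ by EM (component variances floored at $10^{-6}$,
   convergence at relative log-likelihood change $10^{-8}$, at most 300
   iterations, quantile initialization);
3. each $e_i$ is reported as its posterior mean, with the posterior
   variance feeding the intervals.

`shrink = "laplace"` retains the plain conditional modes. When the fitted
$\sigma_s^2$ is numerically zero the mixture step is skipped (all genes
collapse onto $\beta_{RF}$). Degenerate inputs are refused loudly: genes
with no silent counts are dropped with a logged reason, an all-zero
selected class is an identifiability error, and fits with fewer than 30
informative genes warn.

## The synthetic-data generator

The generator produces data *from the model the estimator assumes*, plus a
complete truth ledger. Its defaults encode the study conditions of the
system it emulates — a deeply resequenced, highly diverse honey bee
population with divergence data against a sister species, and a brain TRN
of roughly 190 TFs and 1500 targets:

* `theta = 0.04` segregating silent sites per site: the Watterson
  expectation $\theta_W a_n$ for ~39 genomes of a species with pairwise
  silent diversity near 0.008. Per-gene diversity is log-normal around
  `theta` with log-sd 0.3, because real genes vary in diversity.
* `delta = log(2.5)`: fixed differences accumulate ~2.5× faster per site
  than polymorphic ones at this divergence depth.
* Constraint offsets $\rho_i \sim N(\log 0.2, 0.3)$ for replacement sites
  (typical dN/dS-level constraint) and $N(\log 0.8, 0.3)$ for regulatory
  sites (mild constraint, consistent with a mostly near-neutral upstream
  class).
* Site opportunities `L_syn = 320`, `L_repl = 980` (a ~1.3 kb CDS split
  Nei–Gojobori style) and `L_reg = 905`, the observed average after
  truncating 1 kb windows at opposite-strand genes.
* True $\gamma$ comes from truncated-normal mixtures. The
  `"honeybee-regulatory"` preset uses weights 0.93/0.06/0.01 on components
  $N(-0.2, 0.35)$ on $(-1,1)$, $N(-4, 1.5)$ on $(-\infty,-1]$ and
  $N(2, 1.0)$ on $[1,\infty)$. The weights are the observed class
  fractions; the means and sds were chosen analytically (before any
  fitting) so the mixture mean is $-0.40$, the observed genome-wide
  regulatory average. The `"honeybee-coding"` preset is symmetric with
  mean exactly 0.
* TF out-degrees follow a discrete power law (default exponent 3, minimum
  degree 1, clipped at the number of targets — a TF cannot regulate more
  targets than exist); targets are sampled without replacement, so edges
  are unique and self-loop-free. `hub_gamma_shift` adds a configurable
  effect to the true $\gamma$ of hub genes for power studies.

Counts are generated at the Poisson-summary level the inference model
assumes. The generator therefore does **not** emulate linkage,
recombination, demography, site-frequency spectra, alignment or calling
error, or the ascertainment bias that depresses regulatory divergence in
real alignments. Passing recovery tests show the estimator is correct for
its own model class at realistic information levels — not that the model is
a complete description of real data.

`emit_fixture_genome()` goes one level deeper for the annotation stage: it
writes a small FASTA/GFF3/variant-table trio in which every planted variant
occupies a concrete genomic site whose codon effect and regional
assignment are known, including genes on both strands, a gene flush against
the chromosome start (empty upstream window), a planted stop-gain
(excluded from counts), and a divergent opposite-strand gene pair whose
1 kb windows truncate each other. The annotation roundtrip is tested for
exact count equality over many seeds.

## Annotation conventions

* Coordinates are 1-based inclusive everywhere, the native GFF3
  convention; Bioconductor containers and the on-disk formats then agree
  and no conversion layer exists to get wrong.
* Regulatory regions are the 1000 bp immediately 5′ of the start codon,
  clipped at chromosome ends. Overlap with *opposite-strand* gene bodies is
  removed by truncation — the retained region is the maximal contiguous
  clear segment adjacent to the start codon — rather than by discarding the
  gene, because the observed sub-window average length (905 bp) implies
  truncation; whole-gene exclusion is available via `mode = "exclude"`.
  Same-strand overlaps are flagged but not truncated.
* Each variant lands in at most one (gene, class) cell. CDS membership
  takes priority; a site inside two genes' CDS is ambiguous and excluded
  with a log entry. A site inside two regulatory regions (divergent
  promoters share their intergenic gap) is assigned to the gene with the
  nearest start codon, ties broken lexicographically — deterministic and
  symmetric under genome reverse-complementation, which the suite checks.
* Silent means synonymous only; nonsense (stop gain/loss) variants are
  excluded from counts but reported, a conservative choice. Site
  opportunities count all nine point mutations per codon, so
  `L_syn + L_repl` equals CDS length exactly.

## Network conventions

* Connectedness is role-specific: out-degree for TFs, in-degree for
  targets. Hubs are nodes whose connectedness strictly exceeds the
  empirical 80th percentile of their role class — the strict rule means
  ties at the threshold are never hubs and the hub set never exceeds the
  nominal 20%.
* Betweenness uses directed shortest paths (edges are regulatory
  directions) and is min–max rescaled to [0, 1] to match the convention of
  reporting centrality on a 0–1 scale; an undirected option exists. All
  raw scores equal (e.g. a star) rescale to all-zero.
* Eigenvector centrality is computed on the symmetrized graph: on a
  near-bipartite directed TRN the strictly directed variant assigns zero to
  every pure source, which carries no information.
* The power-law fit pools all node connectedness values by default
  (TF-only mode available, since in sparse TRNs only TF out-degrees reach
  large values). The exponent is the discrete MLE with Hurwitz-zeta
  normalization, searched on [1.01, 6]; the cutoff `x_min` minimizes the
  KS distance between the empirical and fitted tail CDFs. The bootstrap
  goodness of fit is semi-parametric: bodies resampled empirically, tails
  drawn from the fitted law (support enumerated to $10^6$; the truncated
  mass is negligible at the exponents involved), with the full cutoff
  search re-run per replicate unless the original fit fixed `x_min`.

## Group comparisons

Hub-versus-non-hub contrasts of $\gamma$ are one-tailed Wilcoxon rank-sum
tests (alternative: hubs lower), reflecting the a-priori expectation that
connectedness means pleiotropy means constraint; four contrasts are always
produced (TF/target × coding/regulatory), plus per-role chi-square tests of
hub enrichment for genes with negative coding $\gamma$. "Negative" in the
enrichment test means $\gamma < 0$; the stricter $\gamma < -1$ variant is a
parameter. The betweenness contrast between positively ($\gamma > 1$) and
negatively ($\gamma < -1$) selected genes is two-tailed. Exact Wilcoxon
p-values (by enumeration) are used for untied samples with at most 8
observations per group, otherwise the normal approximation with midranks,
tie correction and continuity correction; the chi-square applies the Yates
correction by default. No multiple-testing correction is applied, matching
the analysis style this package reproduces. Every comparison row carries
group sizes, means and SEMs (sd/√n) so bar-plot summaries can be
regenerated.

## Pipeline determinism and problem sizes

`run_pipeline()` derives every stage seed from the master seed, so a rerun
is bit-identical; the config echo written alongside the artifacts suffices
to reproduce any run. One pragmatic softening: group comparisons whose
selection classes are empty at the simulated scale (possible in small
networks) are recorded as skipped in the run log rather than aborting the
whole run, since the condition is data-dependent rather than a
configuration error.

The test suite exercises recovery at sizes chosen to be statistically
informative while keeping the suite quick: 2,000 genes for the headline
γ-recovery fit, 100-TF/300-target networks for the hub power and null
calibration studies (20 and 100 seeds), 500-value tails for exponent
recovery, 100 datasets × 49 bootstrap replicates for the goodness-of-fit
calibration, and 50 fixture seeds for the exact annotation roundtrip.

## Known limitations

* γ estimates inherit every assumption of the Poisson summary: free
  recombination between sites, no ascertainment correction, and the
  divergence-side-only γ mapping described above.
* The regulatory window is a proxy; enhancers outside 1 kb and intronic
  regulatory sequence are invisible to it.
* The mixture re-shrinkage assumes the effect distribution is reasonably
  described by three normal components; with very few genes (tens) the EM
  prior is weakly identified and `shrink = "laplace"` is the safer choice.
* The probe-mapping step implements a strict perfect-match rule only; it
  does not reproduce alignment-based (BLAST) remapping with mismatches.
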