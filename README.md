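# ervphylo

Phylogenetic analysis of endogenous retrovirus (ERV) insertion and
solo-LTR formation in primates.

## The problem

Proviruses carry a pair of initially identical long terminal repeats
(LTRs); non-allelic homologous recombination between them deletes the
internal genes and one LTR, leaving a solo-LTR. Because most ERV loci end
up as solo-LTRs, any account of past retroviral activity depends on how
fast — and how age-dependently — that deletion happens. `ervphylo` is for
researchers studying transposable-element dynamics who want to estimate
insertion and deletion rates jointly from presence/absence/solo-LTR data
across related genomes, rather than from LTR–LTR divergence dating of
full-length elements alone.

Each orthologous locus is summarised as a **site pattern**: a vector over
six primates (human, chimp, gorilla, orangutan, macaque, marmoset) with
states `0` (absent), `1` (full-length/partial provirus) and `x`
(solo-LTR). Only `0 → 1 → x` transitions are possible, so a pattern's
non-absent tips identify the branch of the host chronogram on which the
element inserted. The joint likelihood of a family's patterns is

```
Pr(U | M_i, M_d) = ∏_{i=1..9} e^{-φ_i} φ_i^{N_i} / N_i! × ∏_j Pr(U^(j) | M_d, T^(j))
```

with per-branch Poisson insertion means `φ_i = Φ_i T_i` and per-pattern
deletion probabilities computed by a pruning-style dynamic program that
sums over unobserved internal states. Deletion follows either an
exponential hazard (rate `ψ_e`) or a Weibull hazard (scale `ψ_w`, shape
`ω`; survival `exp[-(age/ψ_w)^ω]`), the exponential being the nested
`ω = 1` case. The package provides ML fitting with box constraints
(`[1e-6, 1e2]`), case-resampling bootstrap intervals, the `2Δℓ`
likelihood-ratio test against the χ²₁ 0.001 cutoff (10.83), forward
simulation with a Fisher-exact goodness-of-fit test, extraction of site
patterns from annotated six-way alignments, and a Wright–Fisher simulator
of mutation accumulation in the LTR pair of a new, segregating insertion.

## Worked example

Fit both deletion models to a synthetic HERV-H-like family generated under
the package's reference study conditions:

```r
library(ervphylo)

study <- generate_synthetic_study(seed = 1)
hh    <- validate_patterns(study[study$family == "HERV-H", ])
fe    <- erv_fit(hh, model = "exponential")
fw    <- erv_fit(hh, model = "weibull")
fw
#> Phylogenetic ERV insertion-deletion fit (weibull deletion model)
#>   113 site patterns; deletion log likelihood -120.90
#>   inverse scale = 0.06143 per Myr, shape omega = 0.2879
anova(fe, fw)
#> LRT (Weibull vs exponential): 2*dlogLik = 30.03 on 1 df (cutoff 10.83): reject exponential
round(100 * survival(fw$deletion, c(0.4, 25)))
#> [1] 71 32
```

Reading this output: the fitted shape `ω ≈ 0.29 < 1` says the deletion
hazard falls steeply with element age; the likelihood-ratio statistic
(here 30.0, far above 10.83) rejects the constant-hazard model; and the
fitted survival function says roughly 71% of insertions are still
full-length at 0.4 Myr (the expected fixation time of a neutral insertion)
but only 32% at 25 Myr. `erv_bootstrap(fw)` adds percentile confidence
intervals, `gof_test()` checks model adequacy against 10,000 simulated
insertions on the deepest branch, and `plot(fw)` draws the fitted deletion
CDF.

Patterns can also be built from annotated alignments
(`extract_patterns()`, with `make_fixture_alignment()` generating toy
inputs with known truth), and the Wright–Fisher side is driven by
`wf_run()`, `first_difference_stats()` and `fixation_mutation_spectrum()`.

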