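# episcape

Functional bottlenecks in fitness landscapes with **global epistasis only**.

## The problem

Combinatorial landscapes between two protein variants with distinct,
mutually exclusive phenotypes (say, a blue- and a red-fluorescent variant
separated by M mutations) sometimes funnel every viable mutational path
through a single "jumper" genotype — a *functional bottleneck*. Bottlenecks
are often read as evidence of network epistasis (irreducible pairwise and
higher-order interactions). `episcape` implements and analyzes a minimal
null model showing that bottlenecks emerge, with probability close to one,
from global epistasis alone: a nonlinear two-phenotype fitness map applied
to a perfectly additive trait.

The model: genotypes are binary vectors over L sites with random, zero-sum
single-mutation effects h_i drawn from a symmetric distribution P(h)
(unit-variance Gaussian, or Pareto-with-cutoff); the additive trait is
E(a) = Σ h_i a_i; blue fitness is φ0 / (1 + e^{β(E_th − E)}) and red is its
mirror image, so in the sharp-threshold regime a genotype is blue iff
E > E_th and red iff E < −E_th. Two reference variants are tuned from the
all-zero ancestor by stochastic greedy (probability p) / random
(probability 1 − p) mutation steps until the trait crosses ±E_T. The
connectivity threshold

    EC = min( max over the M! directed paths of the minimum intermediate |E|,
              min(EBref, |ERref|) )

is computed by a widest-path dynamic program over the subset lattice
(O(M·2^M), brute-force-verified), together with jumper genotypes,
surviving-path counts and topology classes. A calibration pipeline fixes
E_T(p) so that ⟨M⟩ ≈ 8 and selects the operating p; an empirical module
applies the same analysis to measured 2^K genotype tables (normalization,
power-law trait deconvolution, SME spectra, Pareto tail fits) and generates
synthetic fixtures emulating that data structure.

## Worked example

```r
library(episcape)

cfg <- model_config(preset = "gaussian_calibrated", n_instances = 500, seed = 7)
ens <- run_ensemble(cfg)
print(ens)
#> Ensemble of 500 instances (444 path-analyzed, 0 tuning failures)
#>   mean M                 = 7.862 (se 0.266)
#>   mean EBref/ET          = 1.578
#>   mean n_greedy          = 1.049 (median 1)
#>   mean EC/Emaxref        = 0.361 (restricted 0.359)
#>   P(single-jumper proxy) = 0.986
#>   P(EC < Eminref)        = 0.993
```

Reading the numbers: the tuned references differ by ~8 mutations on
average; the blue reference overshoots its target E_T = 2 by ~60% (the
final greedy step adds nearly the pool maximum); each tuning trace uses
about one greedy step plus a few random ones; the bottleneck threshold EC
sits strictly below the weaker reference in >99% of instances — a genuine
bottleneck, not the trivial cap — at roughly 0.36 of the stronger
reference trait.

A single instance, fully reproducible from its seed:

```r
inst <- generate_instance(cfg, instance_seed = 1)
print(inst)
#> Reference pair: M = 5, EBref = 3.108, ERref = -2.642 (Eminref = 2.642)
#> Path-space result: M = 5, EC = 1.274 (Eminref = 2.642), j = 2, 1 jumper(s),
#>   4 path(s) at EC, topology = single_jump_single_landing
```

All 5! = 120 mutation orders pass through one jumper genotype two
mutations from the blue reference; only 4 orders keep every intermediate
functional at EC. `export_path_graph(inst$subcube, inst$result$EC, "g.graphml")`
writes the surviving-path graph.

Measured (or synthetic) landscape tables go through the same machinery:

```r
land <- make_fixture(K = 6, noise_cv = 0.1, seed = 42, file = "fixture.tsv")
dec  <- deconvolve_trait(normalize_fitness(read_landscape_table("fixture.tsv")))
empirical_bottleneck(dec)
```

A thin CLI over the same functions lives in `inst/cli/episcape.R`
(subcommands `calibrate`, `ensemble`, `analyze-landscape`, `fixture`).

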