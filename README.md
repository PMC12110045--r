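# critdiv

Detecting critical phase transitions in families of conditional
distributions with a divergence-rate measure, validated on discrete
rate–distortion (RD) theory.

## The problem

Many systems — neural codes, annealed clusterings, lossy compressors —
are described by a codebook: a conditional distribution `p_t(y | x)` of
outputs given inputs, indexed by a control parameter `t`.  As `t` varies
the codebook can reorganise abruptly: output states appear or vanish
from its support.  Such *critical* parameter values carry scientific
meaning (phase transitions in efficient codes, cluster births, support
bifurcations along the rate–distortion curve), but locating them from
sampled codebooks is a noisy 1-D peak-finding problem.

`critdiv` implements the divergence rate

    M_t = (1 / dt) * sum_x q_x KL( p_t(.|x) || p_{t+dt}(.|x) )

— the input-averaged Kullback–Leibler divergence between consecutive
codebooks per unit of the control parameter.  For smooth fully supported
families `M_t` vanishes with the grid spacing; at a support transition it
diverges.  The series is z-score normalised, support losses are
saturated at a common sentinel magnitude, and a momentum-based noisy
peak finder extracts the significant peaks: the estimated critical
parameters.

The package ships everything needed to validate the measure end to end:

* a Blahut–Arimoto fixed-point solver (`ba_solve()`, `rd_curve()`) for
  discrete RD problems `(q, d)`, with warm-started continuation along
  trade-off grids (convention: `d[i, j]` = cost of coding input `j` as
  output `i`; rows = outputs);
* closed-form oracles: the high-beta matrix solution
  (`high_beta_output()`), exact first critical points
  (`first_critical_beta()`), the explicit two-state family
  (`two_state_outputs()`), the Berger three-state critical point
  (`berger_critical_w()`), and a Descartes rule-of-signs bound
  (`descartes_positive_root_bound()`);
* the measure itself (`kl_divergence()`, `divergence_rate()`,
  `divergence_series()`) and the peak finder
  (`find_all_local_maxima()`, `piecewise_gradient()`,
  `find_next_local_maximum()`, `find_significant_peaks()`);
* reproducible experiments: peak counts on random problems against the
  `n - 1` line (`conjecture1_experiment()`), weak universality of random
  distortions (`weak_universality_experiment()`), a criticality heatmap
  for the three-state family (`criticality_heatmap()`), a clustering
  demonstration (`cluster_problem()`), and an ON/OFF ternary image-patch
  coding pipeline (`ternarize_patch()`, `patch_rd_problem()`) driven by
  a built-in synthetic 1/f-noise image generator
  (`synthetic_image_generator()`).

## Worked example

The two-state problem `q = (1/2, 1/2)`, `d = [[0, 1], [2, 0]]` has one
critical point, known exactly: the second output state vanishes at
`w* = exp(-beta*) = (sqrt(5) - 1) / 2 = 0.6180...`.

```r
library(critdiv)

pr <- two_state_problem(2)
pr
#> Rate-distortion problem on 2 states
#>   q: 0.5 0.5
#>   d: 2x2 distortion matrix (rows = outputs, cols = inputs), max 2

first_critical_beta(pr)
#> Critical point: beta* = 0.48121183 (w* = 0.61803399), vanishing output state 2

scan <- critical_peaks(pr, abscissa = "w", n_grid = 400)
scan
#> Critical scan over w in [0.01123, 0.9888] (400 points)
#> Significant peaks: 1
#>          x  height
#> 1 0.617895 19.9249
```

The algebraic route (`first_critical_beta`, a bisection on the exact
high-beta solution) gives `w* = 0.61803399`.  The measurement route —
trace the RD curve on a 400-point `w` grid, compute the normalised
divergence-rate series of the codebooks, find significant peaks — puts
its single peak at `w = 0.617895`, within one grid step (0.00245) of the
exact value; its height, 19.9 standard deviations of the normalised
series, is the saturated support-loss spike.  The same pipeline on the
Berger three-state source at `u = 1/13` returns exactly two peaks,
bracketing the vanishing and re-emergence of the middle output state.

## Command line

A thin wrapper is installed as `exec/critdiv`:

```sh
critdiv first-critical --problem problem.json --out results/
critdiv rd-curve --problem problem.json --beta-min 0.05 --beta-max 10 --num 400 --out results/
critdiv divergence --problem problem.json --out results/
critdiv peaks --series results/divergence.tsv --alpha 1.0 --out results/
critdiv conjecture1 --n-min 2 --n-max 10 --trials 10 --seed 1 --out results/
```

Problem files are JSON (`{"q": [...], "d": [[...], ...]}`) or a pair of
delimited-text files; every run writes a `manifest.json` (subcommand,
seed, options, package version) so it can be reconstructed exactly.

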