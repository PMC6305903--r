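---
title: "Network-level validation of spiking network simulations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Network-level validation of spiking network simulations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spikeval)
```

## Why statistical validation

Two executable implementations of the same spiking network model — two
simulators, a software and a hardware realization, or simply two runs with
perturbed parameters — are in general not spike-to-spike identical. Floating
point versus fixed point arithmetic, ODE solver details, and threshold
detection all perturb individual spike times, and recurrent dynamics amplify
those perturbations. Whether two implementations are *statistically*
equivalent is therefore a question about distributions of activity measures,
not about spike identity. `spikeval` implements a battery of such measures at
increasing order — single-neuron, pairwise, and higher-order — together with
quantitative comparison scores, and a self-contained network simulator that
generates reproducible synthetic data to exercise the battery.

A deliberate design principle, inherited from validation practice in other
computational disciplines, is that both datasets of a comparison pass through
the *identical* extraction code path with the identical, fully resolved
parameter set (`comparison_config()`), so that a score difference can only
come from the data.

## The measure battery

**Single-neuron measures.** For a train of $n_{sp}$ spikes observed over $T$
seconds the firing rate is $FR = n_{sp}/T$ (Hz). The inter-spike intervals
$ISI_i = t_{i+1} - t_i$ (ms) characterize temporal structure. Regularity is
quantified by the local coefficient of variation over consecutive intervals,

$$ LV = \frac{1}{n-1} \sum_{i=1}^{n-1}
   \frac{3\,(I_i - I_{i+1})^2}{(I_i + I_{i+1})^2}, $$

which is 1 in expectation for a Poisson process, 0 for a clock-like train,
and $3/(2k+1)$ for a gamma renewal process of order $k$ — the three anchors
the test suite verifies by simulation. One sometimes sees this statistic
written with spike times in place of intervals; computed on times it does not
satisfy the Poisson anchor, so `spikeval` computes it on intervals and treats
the time-based spelling as a notational slip. Units with fewer than three
spikes have no defined LV; they are excluded and counted
(`n_excluded`), never silently set to 0, because silent zeros would bias the
downstream effect sizes.

**Pairwise measures.** Spike trains are binned (half-open bins, trailing
partial bin dropped) and correlated. The cross-correlation function of two
count series $x, y$ over $N$ bins is

$$ R_{xy}(\tau) = \frac{1}{N} \sum_{t=1}^{N} x(t)\, y(t+\tau), $$

with out-of-range samples treated as zero and a constant $1/N$ normalization
at every lag (the literal reading of the defining formula; the alternative
overlap normalization $1/(N - |\tau|)$ is *not* used — the difference is a
deterministic edge term of order $|\tau|/N$, negligible for the lag windows
used here, $|\tau| \le 50 \ll N$). Subtracting $\mu_x\mu_y$ gives the
covariance function, and dividing by $\sigma_x\sigma_y$ (full-record standard
deviations, $\sigma_x = \sqrt{C_{xx}(0)}$, not lag-dependent) the
cross-correlation coefficient function $\rho_{xy}(\tau)$, whose zero-lag
value is the Pearson coefficient.

Two matrix variants probe different time scales: `CC` (2 ms bins) captures
fine temporal coordination, `RC` (100 ms bins) the "rate correlations" of
slow population-wide fluctuations. Lagged coupling is summarized by the
integral correlation

$$ P_{xy} = \sum_{\tau=-\Delta}^{\Delta} \rho_{xy}(\tau), \qquad
   \Delta = 50 \text{ bins of } 2 \text{ ms (lags up to 100 ms)}. $$

Internally the lag sum is collapsed to one matrix product through a
zero-padded rolling sum, which is algebraically identical to the lag-by-lag
definition; the test suite checks it against a literal triple loop to
$10^{-9}$ relative. Pairs involving a zero-variance unit (silent, or
saturated at one count per bin) are undefined: they are masked and counted,
and operations that need a fully valid matrix (`eigendecompose()`,
`similarity()`) refuse masked input rather than propagate NaN —
`drop_invalid_units()` makes the exclusion explicit.

**Correlation structure.** The eigenvalue spectrum of a correlation matrix
($Cv_i = \lambda_i v_i$) summarizes how much variance single modes explain;
empirical correlation matrices are positive semidefinite, so the eigenvalues
are nonnegative up to floating-point tolerance (nonnegativity follows from
PSD-ness, not from symmetry alone, which is why the package asserts
PSD-up-to-tolerance). For display, `cluster_order()` orders neurons by the
leaf order of Ward-linkage agglomerative clustering on the matrix rows
(diagonal zeroed, Euclidean distance — `stats::hclust(method = "ward.D2")`,
which matches the common Ward implementation on raw distances), exposing
intra-correlated groups as blocks.

Whether two simulations place correlations on the *same pairs* is measured
by the normalized absolute scalar product of the two strict upper triangles,

$$ 0 \le \frac{|c_1 \cdot c_2|}{\lVert c_1 \rVert\, \lVert c_2 \rVert} \le 1,$$

which is 1 for identical and 0 for orthogonal structures. The score is
label-sensitive by construction, so its significance is assessed against a
surrogate null obtained by jointly permuting rows and columns of one matrix
(default 10,000 shuffles, seeded); the result records the observed score,
null mean and SD, and $z$. For homogeneous matrices the null is degenerate
(every relabeling preserves the score); this is detected and flagged
(`degenerate = TRUE`, `z = Inf` sentinel) instead of dividing by zero.

**Spatiotemporal patterns.** Higher-order coordination is probed by mining
repeated spike sequences: spike trains are binned at 3 ms and binarized, a
pattern is a set of (neuron, lag) items with minimum lag 0, and an
occurrence is a window start at which every item is present. Defaults keep
sequences with at least 5 spikes, repeating at least 3 times, spanning
strictly less than 60 ms ("shorter than" is read strictly). Reported
patterns are the *closed* frequent itemsets — no superset has the identical
occurrence set — which is the standard redundancy-removal rule in frequent
itemset mining and, unlike heuristics, is checkable against exhaustive
enumeration (the suite does exactly that on small fixtures). A
`maximal = TRUE` switch reports only patterns not item-wise contained in
another reported pattern, since the literature is not unanimous on the
reporting rule. Statistical significance filtering of patterns is
deliberately out of scope: the comparison uses all repeated sequences, and
the summaries are the pattern *count* and the pooled distribution of
pairwise lags within patterns. The miner enumerates closed sets by
prefix-preserving closure extension on projected databases; ordering items
as (lag, neuron) makes the minimum item of every lag-anchored pattern a
lag-0 item, so anchoring is obtained by restricting the first extension,
enumerating exactly one representative per shift-equivalence class.

**Comparison scores.** Each measure yields one sample distribution per
dataset (per neuron, per pair, per eigenvalue, or pooled intervals). The
standardized mean difference

$$ d = \frac{\mu_1 - \mu_2}{\sigma}, \qquad
   \sigma = \sqrt{\frac{(n_1 - 1)\sigma_1^2 + (n_2 - 1)\sigma_2^2}
                       {n_1 + n_2 - 2}} $$

uses the pooled standard deviation (equivalent to the equal-$n$ form of the
classical effect size; no small-sample bias correction is applied, matching
the defining formulas). The 95% CI uses the standard large-sample variance
$\operatorname{var}(d) \approx (n_1+n_2)/(n_1 n_2) + d^2/(2(n_1+n_2-2))$ —
an implementation choice, since no closed form is canonical. A zero pooled
SD with unequal means yields a signed-infinity sentinel with a flag. For
repeated runs (several network states) per-run effect sizes are averaged
unweighted with their SD. Hypothesis tests: two-sided two-sample Student's
t (equal-variance), Kolmogorov–Smirnov (ECDF supremum distance), and
Mann–Whitney U (rank sums), all delegated to `stats`. The t-test is only
applied to approximately normal measures — by default FR, LV, RC, and
log(ISI) — while KS and MWU apply everywhere. No multiple-comparison
correction is applied by default (an optional Bonferroni flag exists).
Effect sizes assume roughly Gaussian samples; for skewed distributions a
small $d$ does not imply matching shapes, which is why the harness always
pairs it with the nonparametric tests.

## The synthetic data source

The simulator implements a 1,000-neuron random network: a 4:1 mix of
excitatory (regular-spiking: $a=0.02, b=0.2, c=-65, d=8$) and inhibitory
(fast-spiking: $a=0.1, b=0.2, c=-65, d=2$) two-variable quadratic
integrate-and-fire neurons

$$ v' = 0.04v^2 + 5v + 140 - u + I, \qquad u' = a(bv - u), $$

with spike cut-off at $v \ge 30$ and reset $v \leftarrow c$,
$u \leftarrow u + d$. The neuron parameters are the canonical
regular-spiking/fast-spiking values of this model family; they are a design
input, fixed once. Every neuron projects to exactly 100 distinct targets
(no self-connections); inhibitory neurons target only excitatory ones.
Excitatory delays are uniform on 1–20 ms, inhibitory delays 1 ms; initial
weights are +6 (excitatory) and −5 (inhibitory), interpretable in pA. Drive
is one 20 pA current pulse per 1 ms step into one uniformly chosen neuron.

Numerics: each 1 ms step is integrated by 16 semi-implicit forward-Euler
substeps ($v$ first, then $u$ from the updated $v$) with threshold detection
at every substep; spike times are reported on the 1 ms grid (at most one
spike per neuron per step). Synapses are delta-currents: a spike delivers
its weight to the target's input current at $t_{spike} + \text{delay}$
through a ring buffer, simultaneous arrivals summing linearly; the synapse
model (instantaneous charge active for one step) is a documented choice
where finer kinetics were not prescribed. A runaway guard aborts with a
diagnostic when the mean per-neuron rate exceeds 500 Hz over a sustained
1 s block, which catches the divergent regimes that otherwise manifest as
numeric overflow. Everything is deterministic given (seed, configuration):
the recorded input series (`InputRecord`) re-injected into the same network
reproduces spikes exactly, implementing the frozen-weight replay protocol
(save connectivity $A$, delays $D$, input $I$, per-state weights $W$;
re-simulate with plasticity off).

Plasticity itself is out of scope. The multi-state protocol — comparing
several weight configurations of one topology under the same input — is
emulated by `network_states()`: seeded additive Gaussian jitter
(SD 1, clipped to $[0, 10]$) on the excitatory weights, inhibitory weights
fixed (they are non-plastic in the underlying model). The jitter SD and clip
were fixed once as a plausible spread of trained weights around their
initial value. This emulation produces genuinely different network states
with overlapping dynamics, which is what the comparison harness needs; it
does **not** reproduce the bimodal weight distributions or the polychronous
group structure that long plasticity runs develop, so passing tests here
demonstrate the statistical machinery, not fidelity of trained-network
dynamics. Likewise the synthetic data are stationary by construction and
contain none of the nonstationarities, recording artifacts, or unit-sorting
errors of experimental data.

**Spectra.** The population spectrum uses Welch's method on the population
count series binned at 10 ms (100 Hz sampling): 100-sample segments (1 Hz
resolution), 50% overlap, per-segment mean removal and a Hann taper. Only
the sampling rate, resolution and overlap were prescribed; mean removal and
the Hann window are standard Welch practice and are the package's choice.

## Parameters that matter

| Parameter | Default | Units | Where |
|---|---|---|---|
| CC bin width | 2 | ms | `comparison_config(cc_bin_ms=)` |
| RC bin width | 100 | ms | `comparison_config(rc_bin_ms=)` |
| Integral-correlation lag window $\Delta$ | 50 | bins | `comparison_config(p_delta_bins=)` |
| Pattern bin width | 3 | ms | `mining_config(bin_width=)` |
| Pattern thresholds | 3 occ., 5 spikes, <60 ms | — | `mining_config()` |
| Surrogate shuffles | 10,000 | — | `comparison_config(n_permutations=)` |
| Population histogram bin | 60 | ms | `comparison_config(pop_hist_bin_ms=)` |
| Simulation substeps | 16 | per ms | `simulate_network(substeps=)` |
| Input pulse | 20 | pA | `simulate_network(input_amplitude=)` |

Only the excitatory population enters the default analysis
(`excitatory_only = TRUE`), the convention for this network's comparisons;
inhibitory units can be included per config.

## Numerical and degenerate-input choices

* Bins are half-open and left-closed; a spike exactly at `t_stop` is
  excluded; trailing partial bins are dropped so all bins are equal width.
* Correlation matrices are computed via BLAS (`tcrossprod` of row-
  standardized counts) and clamped to $[-1, 1]$ against last-bit float
  excursions; the contract is agreement with the per-pair definition to
  $10^{-9}$ relative, enforced by oracle tests.
* Spike files print times with 4 fractional digits; the write–read round
  trip is exact at that precision.
* Report JSON serializes doubles with 17 significant digits so that scores
  recomputed from a report file match the in-memory values bit for bit.
* Ties in `hclust` leaf order are resolved deterministically by R's
  implementation; `cluster_order()` is reproducible for identical input.
* Degenerate cases carry flags, not NaNs: zero-variance pairs (masked),
  zero pooled SD (d = 0 or signed-infinity sentinel), degenerate surrogate
  nulls (`z = Inf`, `degenerate = TRUE`), fewer than 100 permutations
  (warning recorded in the result object).

## Problem sizes in the shipped tests

The test suite favors sizes that make independent oracles affordable:
correlation functions are checked against literal double/triple loops on
up to 8 neurons × 250 bins; the pattern miner against exhaustive
closed-itemset enumeration on up to 12 neurons × 200 windows; LV anchors
use 200 trains of 100 s; coupling recovery uses 40–50 pairs of 60 s at 2 ms
bins; test calibration uses 5,000 null replicates at $n=100$ (the KS test
is discrete at this size — true level 0.036 at the nominal 5% — so the
Monte Carlo standard error must be small relative to that number); the
end-to-end check runs the full default battery, patterns included, on two
60 s, 1,000-neuron simulations. The whole suite runs in a few minutes on
one core.

## Known limitations

* The similarity score compares correlation *structure* only up to the
  global sign ambiguity absorbed by the absolute value, and requires
  identical neuron labeling; it is meaningless across different populations.
* Closed-pattern counts grow with synchrony; strongly oscillatory regimes
  can yield large pattern sets (mining stays polynomial-delay but output
  size is data-dependent).
* The effect size inherits its Gaussian interpretation; for ISI-like skewed
  distributions the log transform is used for the t-test but not for $d$.
* No analog-signal (LFP/EEG) support; the battery is defined on spike
  trains.
* The simulator's network states are jittered, not trained; see above for
  what that does and does not represent.
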