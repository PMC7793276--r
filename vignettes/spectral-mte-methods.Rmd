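---
title: "Spectrally-resolved multivariate transfer entropy: model, surrogates, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Spectrally-resolved multivariate transfer entropy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spectralTE)
```

## The problem

Transfer entropy (TE) measures directed information transfer from a source
process to a target process as the conditional mutual information between
the source's past and the target's present, given the target's own past.
In a network of processes the multivariate form conditions additionally on
the pasts of the other relevant processes, removing cascade and
common-driver contributions:

$$
mTE_{tot}(S_i \to T) \;=\; I\!\left(T_t \,:\, S_{i,<t} \,\middle|\,
T_{<t},\, S_{<t} \setminus \{S_i, T\}\right).
$$

Many systems of interest — cortical rhythms foremost — organise their
communication spectrally, so one wants to know *which frequency band of
the source sends* the information and *which band of the target receives*
it.  Filtering the analysed signals before computing TE is not an option:
filters distort phase (creating spurious transfer) or fail to remove
information at all (reducing power does not reduce information), and
narrow-band analyses assume a within-band, one-to-one sender–receiver
relation that nonlinear couplings routinely violate.

## Frequency-specific surrogates instead of filtering

This package never filters the analysed data.  Frequency specificity is
obtained in the *null model*: the maximal-overlap discrete wavelet
transform (MODWT) decomposes a series of length $N$ into $J_0$
wavelet-coefficient series $\widetilde W_1 \dots \widetilde W_{J_0}$ plus
scaling coefficients $\widetilde V_{J_0}$ (all of length $N$, circular
boundary, exactly invertible).  A surrogate destroys the temporal order of
*one* scale's coefficients — by random (block) permutation or by IAAFT —
and reconstructs the series with the inverse transform.  The surrogate
differs from the original only in the targeted band; its power spectrum is
essentially preserved.  Scale $j$ corresponds to the nominal band
$(f_s/2^{j+1},\, f_s/2^{j}]$.

**Algorithm I** builds, for every scale $j$, a distribution of surrogate
transfer entropies $mTE'$ and compares the original $mTE_{tot}$ against
it:

* *source variant*: the source series is reconstructed from shuffled
  scale-$j$ coefficients and re-embedded — a drop means band $j$ of the
  source *sends* information;
* *target variant*: only the target's **present value** $T_t$ is taken
  from the reconstruction, while the target past $T_{<t}$ stays original —
  a drop means band $j$ of the target *receives* information.

Each scale gets a count-based p-value
$p_j = (1 + \#\{mTE' \ge mTE_{tot}\})/(1 + n_{perm})$, tested at the
Bonferroni level $\alpha/J_0$.  Because wavelet bands overlap and leak, the
default report interprets only the scale with the **maximal drop**
$\max_j \left( mTE_{tot} - \mathrm{median}(mTE'_j) \right)$; a flag
(`summary(res, all_significant = TRUE)`) releases all Bonferroni-significant
scales when multiple transfer bands are expected a priori.

**Algorithm II (SOSO)** asks whether an identified source band $j$ and
target band $r$ exchange information *directly*: destroy the target scale
$r$ ($N$ times, present-value contract), within each destroy the source
scale $j$ ($K$ times), and compare the reference drop $\delta TE_S$
against the distribution $\delta TE'_n = mTE'_{T,n} -
\mathrm{median}_k(mTE''_{n,k})$.  If destroying the target band removes
just the information that destroying the source band would have removed,
$\delta TE'$ collapses and $\delta TE_S$ lands in its upper tail.
Redundant routing (the same information available in several bands) leaves
$\delta TE'$ large and the test correctly non-significant.

## Estimation

All information quantities use the Kraskov–Stögbauer–Grassberger
nearest-neighbour estimator (variant 1, conditional form) with max-norm
distances, $k = 4$ neighbours by default, implemented in C++ with kd-trees.
Three numerical safeguards matter in practice:

* **Normal-scores preprocessing.**  Every embedding dimension is mapped to
  exact standard-normal marginals by the rank transform before the
  neighbour search.  kNN information estimates are (approximately)
  invariant under monotone maps, but surrogate reconstruction slightly
  changes marginal shapes; without the rank transform those changes shift
  the estimator's bias by amounts comparable to the small (~0.01 nat)
  transfers of interest.
* **Theiler (dynamic-correlation) exclusion.**  Embedding vectors from the
  same trial overlap in time and therefore share coordinates; such rows
  are excluded from each other's neighbour searches up to the deepest
  embedding lag, so partial duplicates cannot masquerade as recurrences.
* **Tie-breaking jitter.**  kNN estimators are undefined under exact ties;
  seeded uniform jitter of amplitude $10^{-8}$ (after rank scaling)
  removes them deterministically.

Estimates are reported in nats (`nats_to_bits()` converts).  Negative
values are legitimate finite-sample outcomes near independence.

### Embedding defaults

* Target history: lags must cover at least a quarter cycle of the lowest
  analysed band, i.e. a depth of $2^{J_0-1}$ samples at $J_0$ levels.  A
  *unit-spaced* history of that depth (16 dimensions at $J_0 = 5$) makes
  the conditional estimator unusable at desk-scale sample counts — the
  measured transfers of these validation systems are ~0.005–0.05 nats,
  far below the high-dimensional bias fluctuations.  The default is
  therefore *dyadically spaced* lags $\{1, 2, 4, \dots, 2^{J_0-1}\}$: the
  same depth, one dimension per octave.  This mirrors the sparse
  non-uniform embeddings that greedy variable-selection methods produce on
  such systems.  `link_spec(target_lags = )` restores any explicit choice.
* Source past: the single lag at the scanned coupling delay $\delta$
  (configurable).
* Conditioning processes: lags 1–3 (the scanned delay range), never
  shuffled.
* Pooling: embedding vectors never span trial boundaries; trials are
  pooled after embedding.  The pooled sample is capped (default
  `n_max = 12200` rows, seeded subsample) and the *same rows* are reused
  for the original and every surrogate evaluation, so scale comparisons
  are paired.

### Permutation machinery

Surrogate shuffles are drawn independently within each trial (a fresh
permutation per trial), consistent with per-trial circular MODWT
decomposition and trial exchangeability.  All randomness derives from one
master seed through scale- and permutation-indexed sub-seed streams, so any
scale's surrogate distribution is reproducible in isolation and identical
seeds give bit-identical results end to end.  Surrogate $mTE'$ values may
lie *above* $mTE_{tot}$ for some scales; this inflation is an expected
property of reconstruction-based surrogates, not an error, and the
one-sided drop test is unaffected.

## The validation systems

`sim_system(1..9)` generates the nine ground-truth systems: uncoupled
harmonics (1); phase–amplitude cross-frequency coupling from a 6 Hz rhythm
to a 50 Hz carrier at delay 2 (2); unidirectional 45 Hz AR(2) pairs at
delay 2 (3); a bidirectional 5/45 Hz AR(2) pair (4); a three-node network
where a narrow-band 6 Hz driver sigmoid-modulates an 80 Hz carrier beside
a 90 Hz distractor (5); delay-coupled chaotic Rössler oscillators around
8 Hz (6); three source rhythms modulating one carrier (7); one rhythm
modulating three carriers (8); and a redundant-routing system in which a
strong 9 Hz component and a multi-band component cross-modulate two target
streams (9).

Interpretation choices that the printed equations leave open, and how they
were fixed:

* **Coupling acts on the latent signal.**  The additive noise terms $w$
  are treated as *observation* noise: the multiplicative couplings use the
  noise-free harmonic component (e.g. example 2's target is
  $\cos(2\pi f_2 t + \theta)\, S^{sig}_0(t-2) + w_2$).  The
  redundant-routing system's equations state this form explicitly, and it
  is the only reading under which the systems' band-limited ground
  truths are reproducible: had the coupling used the noisy source, its
  white noise would transfer information in *every* band (the top scale
  alone carries as much source variance as the rhythm), and the target
  would receive in every band rather than in the stated sidebands.
* **Phases are redrawn per trial** (uniform on $[0, 2\pi)$, independently
  per component), making trials exchangeable realisations.
* **Example 5's driver** is a zero-phase (forward–backward) order-4
  Butterworth band-pass of white noise (6 ± 0.2 Hz), normalised to unit
  variance before entering the sigmoid $g(x) = 1/(1+e^{-3x})$; the
  band-pass defines the simulated signal and is not analysis filtering.
* **Example 6's integrator** is fixed-step RK4 with a delay ring buffer.
  The natural frequencies $w = 0.8, 0.9$ imply about $w/2\pi \approx 0.13$
  cycles per model time unit, so the model-time step per sample is chosen
  as $h = 2\pi f_{target}/(\min(w_1, w_2) f_s)$ ($\approx 0.126$; delay
  $\tau$ = 2 samples = $2h$), anchoring the slower oscillator at the
  nominal 8 Hz at $f_s = 500$ Hz (measured peaks: 8.0 and 9.0 Hz, both
  inside the scale-5 band).  Integrating at $h = 1/f_s$ would put the
  rhythm at ~0.13 Hz, far from the intended band.  Divergent
  trajectories (possible for unlucky initial conditions) are regenerated
  and logged; a 2000-sample transient is discarded.
* **Example 7's frequencies** are unspecified in print; band-centre values
  12, 6, 3 Hz (source) and a 45 Hz target carrier reproduce the stated
  scales 3, 4, 5 → 1 at $f_s = 125$ Hz.
* **Example 9's parameter list** contains apparent typos (a duplicated
  9 Hz entry; a "40 Hz (j = 4)" annotation although 40 Hz at
  $f_s = 250$ Hz lies in scale 2).  The frequencies are implemented as
  printed; the ground truth (source scale 4, target scale 2, no direct
  4→2 transfer) follows the system's construction, not the annotations.
* **AR frequency convention**: pole argument $2\pi f/f_s$; observation
  noise sd 1 where unstated; 1000-sample burn-in.

What the generators deliberately do *not* emulate: measurement filtering,
line noise, volume conduction/signal mixing, non-stationarity across
trials, and 1/f backgrounds.  Passing the validation suite therefore
demonstrates correctness of the algorithmic chain on known ground truth,
not robustness to every artefact of real recordings.

## Problem sizes and statistical behaviour

The package's own validation runs use reduced versions of the full
study conditions: 20 trials of 4–10 s (system-dependent), 50 surrogate
permutations per scale for max-drop identification (the surrogate median
stabilises quickly), 100–200 permutations when Bonferroni significance at
$\alpha/J_0$ is claimed, $k = 4$, LA8 filter, block permutation with block
size 1, and a pooled-sample cap of 12 200 embedding rows.  The
cross-frequency system of example 2 is the least powered of the nine on
the *source* side: its per-band transfer is a few thousandths of a nat,
and at the reduced trial count the max-drop scale is not reliably
recoverable by any embedding we tried; the package's validation therefore
runs that one system at its full preset (100 trials × 10 s),
where recovery is stable.  The automated test suite shrinks permutation
counts and repetition numbers further (sizes are stated in each test) to
keep the default run short.

SOSO runs use $N_{outer} = K_{inner} = 20$–30; the procedure costs
$(N+1)K$ transfer-entropy evaluations, announced up front by
`soso(..., verbose = TRUE)`.

Delay scans are a special case: the per-delay mTE differences are governed
by the modulating rhythm's one-sample autocorrelation (e.g. 0.955 for 6 Hz
at 125 Hz), a few $10^{-4}$ nats for these systems — of the order of the
estimator's per-evaluation noise even at $10^4$-plus pooled points.
`scan_delay(n_rep = )` therefore averages over repeated evaluations with
fresh subsample rows; even so, at desk scale the argmax should be treated
as indicative rather than reliable for weak, slowly modulated couplings.
Strong couplings (e.g. the linear AR systems) scan cleanly.

## Degenerate inputs, ties, tolerances

* MODWT requires $1 \le J_0 \le \lfloor \log_2 N \rfloor$; reconstruction
  and energy identities hold to ~$10^{-10}$ relative.
* Max-drop ties break toward the smaller scale index (higher frequency),
  and are logged in the returned table.
* `te_significance()` exchanges whole trials of the source when at least 5
  trials exist, otherwise it falls back to per-trial circular rotation
  (reported by message).
* Zero-variance embedding columns are centred and left to the jitter;
  constant series produce exactly zero wavelet coefficients at all detail
  scales.
* IAAFT stops when the rank permutation is stable or after 100 iterations
  (warning; the best iterate is returned).

## Known limitations

* The nominal dyadic bands of the MODWT leak; adjacent scales of a strong
  transfer are often significant.  Only the max-drop scale is interpreted
  by default, which is conservative with multiple genuine bands (lift via
  `all_significant = TRUE`).  LA16 reduces leakage at the cost of longer
  boundary overlap.
* Redundant information transfer — the same content carried in several
  bands — is invisible to single-scale destruction by construction; the
  SOSO test can rule direct transfer *out* but redundancy *in* only
  indirectly.
* The estimator's absolute values carry finite-sample bias; all inference
  is relative (original vs surrogate), which is why surrogate-side biases
  must be matched carefully (rank transform, shared subsample rows,
  Theiler exclusion).
* Network identification (which links exist, their delays and embeddings)
  is assumed done; `scan_delay()`/`te_significance()` provide only a
  simplified single-link precomputation, not greedy multivariate network
  inference.
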