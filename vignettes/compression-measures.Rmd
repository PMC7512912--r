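---
title: "Compression-based DNA comparison: models, measures and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Compression-based DNA comparison: models, measures and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nrcomp)
```

## The idea

Algorithmic information is not computable, but a good lossless compressor
gives a usable upper bound: the better a model predicts a DNA sequence,
the fewer bits per symbol the sequence "costs". `nrcomp` never emits a
bitstream — it accumulates the *ideal* arithmetic-coding length
$\sum_i -\log_2 P(x_i)$, using compression purely as a measuring device.
Everything in the package is built on three coding modes:

* **Reference-free** $C(x)$: one adaptive pass over $x$; all model
  memories start empty and learn as they go.
* **Conjoint** $C(yx)$: one adaptive pass over the concatenation of $y$
  followed by $x$; approximates the joint description cost $C(x,y)$
  because the cost of describing the split point is negligible.
* **Relative** $C(x\|y)$: model memories are trained on the reference
  $y$, then frozen; $x$ is coded read-only. Only the mixture weights and
  the tolerant models' private histories adapt while coding $x$.

On top of these sit the normalized measures, with the 2-bit DNA alphabet
constant $\log_2 4$ in the denominator:

$$\mathrm{NC}(x) = \frac{C(x)}{2|x|}, \qquad
  \mathrm{NCD}(x,y) = \frac{C(xy) - \min\{C(x), C(y)\}}{\max\{C(x), C(y)\}},
  \qquad
  \mathrm{NRC}(x\|y) = \frac{C(x\|y)}{2|x|}.$$

NCD answers "how far apart are these two sequences?" and is approximately
symmetric. NRC answers "what fraction of $x$ cannot be built from $y$
alone?" and is deliberately asymmetric. The conditional NCD form,
$\max\{C(x|y), C(y|x)\} / \max\{C(x), C(y)\}$ with
$C(x|y) = C(yx) - C(y)$ via the chain rule, is available through
`ncd(..., type = "conditional")`; the conjoint form is the default
because it needs only two coder modes. Real coders can make a chain-rule
conditional marginally negative; we clamp it at zero and flag the result
rather than failing.

A consequence worth internalizing: because the frozen reference model can
never learn from $x$, describing $n$ concatenated copies of $x$ costs
almost exactly $n$ times one copy, $C(x^n\|y) \approx n\,C(x\|y)$. NRC is
therefore blind to self-redundancy in the target, while NC and NCD
exploit it. This single property explains most situations where the two
measures rank pairs differently.

## The model mixture

The coder is a soft-blended mixture of finite-context (Markov) models.
Model $m$ of depth $k$ predicts
$P_m(s \mid \mathrm{ctx}) = (n_s + \alpha) / (\sum_{s'} n_{s'} + 4\alpha)$
from its count memory; the blended probability is
$P(x_i) = \sum_m w_m P_m(x_i)$, and after each symbol the weights update
as $w_m \propto w_m^{\gamma} P_m(x_i)$ with a shared forgetting factor
$\gamma \in [0,1)$. Small $\gamma$ forgets quickly; $\gamma$ near 1
averages over a long performance history. Indexed literally, weight and
probability would depend on the symbol being coded; we mix with the
weights as they stood after symbol $i-1$, the only causal (decodable)
reading and standard compressor practice. After normalization, weights
are floored at $10^{-12}$ and renormalized so that no model is
permanently silenced by finite precision.

Four mechanisms matter beyond the plain counts:

* **Inverted repeats.** With the flag on, every $(k{+}1)$-mer update also
  counts its reverse complement (update-time only; prediction never
  queries the complemented context). DNA repeats frequently occur
  reverse-complemented, and this makes them visible to the model.
* **Substitution-tolerant context models (STCM).** A tolerant model
  shares the count memory of the same-depth plain model but predicts
  from a *private* history: on a misprediction it writes its own argmax
  prediction (ties broken A<C<G<T) into that history and counts a miss;
  after more than $t$ misses the history resets to the true past and the
  miss count to zero. This lets deep contexts survive isolated
  substitutions — exactly the regime of mutated copies. Miss accounting
  is cumulative-until-reset (no sliding window), the simplest
  deterministic reading of "allowed substitutions".
* **Cache-hash.** Deep-model memories are hashed stores; with bound
  $B > 0$ each bucket keeps at most the $B$ most recent contexts (FIFO,
  evaluated when a new context is inserted). This bounds memory on
  genome-scale inputs at a small cost in precision. Shallow models
  (depth $\le 11$) use direct count tables, which need no eviction.
* **Warm-up.** The first $k$ positions of any pass use a context
  left-padded with `A`, keeping profile length equal to sequence length
  (the alternative of skip-charging a flat 2 bits/symbol was rejected
  for that reason).

In relative mode the mixture weights restart uniform for the coding
phase: how well a model did while *training on* $y$ says little about
how useful it is for $x$, and the reset keeps
`compress_relative` a pure function of its inputs. Tolerant histories
likewise restart from $x$'s own padded past.

## Presets

`preset_config()` ships mixtures tuned to data scale: synthetic
(reference-free: 8 models; relative: 7 models; both $\gamma = 0.95$,
cache-hash 30), mitochondrial (5 models, $\gamma = 0.95$, depths to 13,
inverted repeats on the deep models), mRNA (7 models, $\gamma = 0.88$,
cache-hash 200, depths to 20) and whole-genome (6 models,
$\gamma = 0.88$, cache-hash 250). The `-relative` variants lower the
depth-14 alpha to 0.01 where such a model exists — a frozen, fully
trained memory deserves more trust than an adapting one. Deep models
carry small alphas (trust counts), shallow models $\alpha = 1$ (stay
near uniform until evidence accumulates); each depth pairs a plain model
with a tolerant one only where substitution-tolerance pays
(depths 13–20).

## What the synthetic generators emulate — and what they do not

`generate_random()` produces uniform i.i.d. DNA: the incompressibility
yardstick (NC $\approx$ 1). `mutate_substitutions()` applies i.i.d.
substitutions; a selected position always changes (the replacement is
drawn from the three other symbols), so the nominal rate *is* the
expected Hamming-distance fraction — identity draws would silently
deflate the x-axis of every mutation experiment.
`generate_blocks()` concatenates labelled blocks (uniform, low-entropy
motif repeats, mutated copies, reverse-complemented copies) into an
`x`/`y` pair with 0-based half-open annotations; BED export matches this
convention. `generate_repeat_rich()` pastes mutated substrings of a
random backbone at non-overlapping positions, optionally with a skewed
base composition, emulating repeat-laden genomic sequence.

Real genomes add what these generators deliberately omit: long-range
composition drift, insertion/deletion variation, sequencing and assembly
artefacts, and circular molecules (sequences here are linear; mtDNA
circularity is ignored). Passing tests on the synthetic conditions show
the measures behave as the theory predicts under controlled redundancy
and substitution load — not that any biological conclusion follows from
a particular dataset.

Non-ACGT input characters are replaced by a uniformly drawn symbol with
a deterministic draw keyed on (seed, position), recorded in the
sequence's `replaced` set. This preserves base composition better than a
fixed letter and is reproducible record by record.

## The rearrangement demonstration

`rearrangement_demo()` builds a 14-block pair in which every relation a
region can have to a reference occurs at least once: regions copied from
`y` with 1% substitutions (E, J, L), verbatim low-entropy copies (I, K),
unmatched high-entropy (A, N) and low-entropy (H) regions, and an
*internal* duplication — G and its copy M, both private to `x`. The
relative profile drops below 0.2 bits over everything describable from
`y` and stays near 2 bits over A, M and N; the reference-free profile
instead collapses over M (it has seen G) and over H. The mutated copy J
is described better by the relative coder than by the conjoint one: the
relative presets can afford smaller alphas because a frozen memory is
never diluted by the target's own novelties.

## Profiles, segmentation and similarity maps

Per-symbol profiles are noisy; `smooth_profile()` applies a centered
moving average (window shrinking at the edges, length preserved) and
`segment_low_information()` reports maximal runs below a threshold,
discarding runs shorter than `min_len`. Defaults: window 501, threshold
1.5 bits, `min_len` 100 positions. The threshold was calibrated on
planted-copy experiments: after smoothing, a genuine copy at 5%
substitutions excurses up to roughly 1.4 bits, while unrelated uniform
DNA never drops much below 1.8, so 1.5 keeps true copies whole without
admitting noise. (A half-maximum threshold of 1.0 bits splits 5%-mutated
copies and fails the recall requirement the package sets itself.)
`similarity_map()` reports the two one-sided segmentations of
$C(x\|y)$ and $C(y\|x)$ side by side; no attempt is made to pair
segments across sequences, because the coder keeps no positional
traceback into the reference.

## Numerical and degenerate-input choices

Probabilities are never zero (alpha-smoothing plus the weight floor), so
code lengths are finite. Empty sequences are rejected by every coder;
`rate` outside $[0,1]$, even smoothing windows, non-positive thresholds
and tolerant models without a same-depth plain partner are errors.
Identical inputs and configuration give bit-identical results; all
stochastic generators are seed-deterministic. Counts are exact 32-bit
integers (no halving), so single-model code lengths agree with a
brute-force counting oracle to floating-point accuracy.

## Scales used by the shipped experiments

The package's own experiments run at desk scale, chosen so the full
suite completes in minutes while every effect it asserts is far larger
than seed noise: 100 kb pairs for the substitution-rate sweeps, 10 kb
blocks for the rearrangement demonstration, 50 kb sequences with 10 kb
planted copies for the similarity maps, and 16 kb / 1 Mb references with
mutation multiples up to 8 for the expectation curves. The
mitochondrial-scale curves are visibly noisier than the 1 Mb ones at
equal rates — with only ~16000 symbols, collision effects in the
pseudo-random substitution process show — which is itself one of the
behaviours the experiments document.

The substitution-rate sweep offers two architectures. `"uniform"`
mutates a full copy of a uniform reference: NRC rises strictly with the
rate and NCD is symmetric to within a few parts per thousand.
`"repeat-rich"` emulates non-uniform, repetitive genomic data: the
reference is repeat-laden with an AT-skewed composition
(0.3, 0.2, 0.2, 0.3), and only a quarter of the target is copied (then
mutated); the rest is the target's own material of the same composition.
On that architecture NCD dominates NRC at every rate, for the reason
sketched above: NCD normalizes away material private to $x$, while the
relative coder pays full price for it.

## Known limitations

* The coder measures; it does not compress. There is no bitstream, no
  decompressor, and no entropy-coder overhead in the reported bits.
* Depths are capped at 28 (2-bit-packed 64-bit contexts).
* `compress_relative()` retrains on the reference at each call. For
  repeated queries against one reference this repeats work; a persistent
  frozen-model store is a possible extension.
* Cache-hash eviction makes deep-model contents order-dependent by
  design; two references differing only by a permutation of distant
  segments can yield slightly different frozen models.
* The similarity map reports one-sided segments only; mapping an
  `x`-segment to its source coordinates in `y` requires alignment-style
  traceback that a pure measurer does not keep.
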