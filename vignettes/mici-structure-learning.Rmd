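---
title: "Learning trustworthy network structure from discrete data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Learning trustworthy network structure from discrete data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(micinet)
library(dplyr)
```

## The problem and the design stance

Signaling-pathway inference from quantitative proteomics (or any
sample-by-variable discrete table) is often framed as Bayesian-network
structure learning: find the directed acyclic graph whose conditional
probability factorization

$$p(X_1, \dots, X_n) = \prod_{i=1}^n p\!\left(X_i \mid \mathrm{Pa}(X_i)\right)$$

best explains the data. In a biological network a single wrongly oriented
or spurious edge can mislead downstream interpretation badly, so `micinet`
takes a deliberately conservative stance: it prefers *reliable but
incomplete* output over *complete but uncertain* output. Concretely, the
learner

* reports a **partially directed graph** — it never guesses a direction it
  cannot defend, and
* separately reports the **trustworthy network**: the subset of edges whose
  direction was fixed by a score-based immorality (v-structure) test, the
  only 3-node, 2-edge pattern that data can distinguish from its Markov
  equivalence class.

The price is missed edges; the benefit, measured on simulated benchmarks,
is a near-zero wrong-edge rate.

## Scores and tests

**MDL score.** A node family (child $X_i$ with parents $\mathrm{Pa}(X_i)$)
is scored in bits as

$$\mathrm{score}(X_i) \;=\; \sum_{j=1}^{q_i} \sum_{k=1}^{r_i}
  N_{ijk} \log_2 \frac{N_{ijk}}{N_{ij}}
  \;-\; \frac{\log_2 N}{2}\, q_i (r_i - 1),$$

where $r_i$ is the child's state count, $q_i$ the number of parent
configurations, $N_{ijk}$ the count of cases with child state $k$ under
parent configuration $j$, and $N_{ij} = \sum_k N_{ijk}$. The first term is
the maximum-likelihood fit, the second the minimum-description-length
penalty for the $q_i(r_i-1)$ free parameters. A network's score is the sum
of its family scores (decomposability). Parent configurations are indexed
in mixed-radix order with the *last listed parent varying fastest*; this is
arbitrary but fixed, so scores are reproducible bit for bit.

**Information measures.** Entropy, mutual information (MI) and conditional
MI are empirical plug-in estimates in bits ($\log_2$); zero-count cells
contribute zero by the $0 \log 0 = 0$ continuity convention, and MI/CMI are
clamped below at 0. Base 2 is a readability choice for the reported
quantities; note that the base *does* interact with the candidate threshold
$\alpha$ (a threshold in bits is $\ln 2 \approx 0.693$ times looser than
the same numeral in nats). The package follows the bits convention
throughout, with $\alpha$ interpreted in bits.

**Conditional-independence test.** The source method states the CI
property ($P(X_i, X_j \mid X_k) = P(X_i \mid X_k) P(X_j \mid X_k)$) but no
operational decision rule. We use the standard likelihood-ratio test:
$G^2 = 2 N \ln(2)\, \hat I(X;Y \mid Z)$ referred to a chi-square
distribution with $(r_x - 1)(r_y - 1)\, r_z$ degrees of freedom (floored at
1 so single-state degenerate variables never error), default significance
0.05 (`ci_alpha`). This is asymptotically equivalent to thresholding
conditional MI and is the conventional choice in constraint-based
structure learning.

**Immorality test.** For a two-edge pattern $a - b - c$, the three
non-collider orientations ($a \to b \to c$, $a \leftarrow b \leftarrow c$,
$a \leftarrow b \to c$) are Markov equivalent and provably receive
*identical* MDL scores, so they are scored once; the collider
$a \to b \leftarrow c$ scores differently. The verdict is `IMMORAL` only
when the collider total strictly exceeds the equivalence-class total by
more than a 1e-9 tie tolerance; ties and losses return `UNDECIDED` ("cannot
decide the direction"). The test is evaluated on the induced three-node
family only, never the whole graph, so verdicts are local and independent
of processing order.

## The single-pass learner

Starting from the empty graph, all $n(n-1)/2$ pairs are scored by MI;
pairs below the threshold $\alpha$ (default $10^{-4}$ bits, the heuristic
value used in the original study) are discarded, and the survivors are
visited exactly once in decreasing MI order — higher MI first, because an
edge decided early constrains later decisions and high-MI pairs are most
likely to be real. Each candidate is classified against the current
skeleton and resolved by one of three rules:

1. **Triangle** — the endpoints already share a neighbour $k$. All three
   pair-edges of the triangle are CI-tested, each conditioning on the
   opposite node. If *exactly one* pair tests independent, the edge between
   that pair is superfluous: it is deleted (or the candidate declined, if
   the candidate is itself the independent pair). Any other outcome (0 or
   ≥ 2 independent pairs) declines the candidate. In every branch the two
   surviving edges are then offered to the immorality test and oriented
   head-to-head if the collider wins. With several common neighbours, each
   induced triangle is processed in column order of $k$ and the candidate
   must survive all of them — the strictest reading, consistent with the
   wrong-edge-averse design.
2. **Cycle** — the endpoints are already connected by a longer skeleton
   path, so adding the edge closes a cycle, which a DAG can only
   accommodate if at least one collision exists. Every existing skeleton
   edge incident to either endpoint is paired with the candidate and tested
   for immorality. No collision: the candidate is declined. One collision:
   the candidate is connected and both edges oriented head-to-head
   (trustworthy). Several: one is chosen uniformly at random from a
   dedicated seeded generator (a private LCG, so the global RNG stream is
   never disturbed and simulation seeds stay independent of learner seeds).
   A collision whose orientation is *unrealizable* — it would reverse an
   already-fixed trustworthy direction or close a directed cycle — cannot
   justify the candidate and is not counted. Without this consistency
   constraint, ASIA simulations occasionally produce a wrong trustworthy
   edge whose head-to-head arrows contradict an earlier, correct
   orientation.
3. **Plain** — neither of the above; the edge is connected without a
   connection test. Orientation is the subtle part. The natural reading of
   "no test except the MI test for the orientations" is implemented as an
   *unshielded-collider check*: every two-edge path completed by the new
   edge whose outer pair is marginally independent (MI below $\alpha$ — the
   MI test) is offered to the immorality test and oriented head-to-head if
   the collider wins. This pathway is essential, not cosmetic: for an
   isolated v-structure $A \to C \leftarrow B$ with independent parents,
   the pair $(A, B)$ has true MI 0, never enters the candidate list, and
   therefore never forms the triangle or cycle that would otherwise examine
   it. Without plain-case orientation the learner could never direct such
   structures, the benchmark's trustworthy network on ASIA would have ~2
   edges instead of the expected 4, and pure-collider simulations would
   essentially never be oriented. If instead the outer pair is marginally
   *dependent*, it is itself a future candidate and the triangle rule will
   adjudicate when it arrives, so no test is run early.

Edges deleted by a CI test are ineligible for reconnection (single-pass
discipline); the final directed subgraph is checked acyclic by
construction. Every candidate produces exactly one row in the decision
trace (`$trace`), including below-threshold pairs, so every connect, skip,
delete and orientation is auditable.

## What the synthetic benchmark emulates — and what it does not

`forward_sample()` draws i.i.d. cases by ancestral sampling from a known
network; `run_benchmark()` reproduces the published evaluation protocol:
20 replicate datasets of 50,000 cases, columns randomly permuted before
learning (so no method can exploit a topologically sorted variable order),
metrics averaged across replicates. The defaults are exactly that stated
protocol. The 8-node ASIA chest-clinic network ships as a built-in fixture
in its conventional Lauritzen–Spiegelhalter parameterization; larger
standard networks (ALARM, CAR DIAGNOSIS2) are not embedded because their
CPT files come from external tools — load them with `read_bif()` or
`read_bn_json()` and pass them to the same driver.

A green benchmark establishes that the learner recovers *this* kind of
world: complete cases, stationary i.i.d. sampling, faithful discrete CPTs,
moderate arities, $N$ large enough for the $G^2$ asymptotics. It does not
establish performance on real proteomic data, which is small-sample
(tens of cases, not tens of thousands), discretized from continuous
intensities, non-i.i.d. across time points, and possibly unfaithful.

Two stochastic failure modes of the single-pass design are worth knowing,
both observed in ASIA replicates and both inherent to the method rather
than to this implementation. First, a truly independent pair's empirical
MI occasionally crosses $\alpha$; such a pair usually lands in the cycle
case, where an explaining-away effect can hand it a genuine (at that
sample size) collider score advantage and a wrong edge. Second, sampling
noise can swap the MI ranks of two close true/indirect pairs so that a true
edge arrives late, lands in the cycle case, finds no immorality to justify
itself, and is declined — occasionally followed by a small cascade of
compensating wrong edges. Both modes are rare; they are why the wrong-edge
average over 20 replicates is near, but not always exactly, zero.

## Discretization of continuous measurements

`min_entropy_discretize()` implements supervised minimum-entropy (MDLP)
discretization for continuous expression-like inputs: recursive binary
splits minimizing the weighted class-conditional entropy, each accepted
only if its information gain clears the MDL stopping criterion, capped at
2–4 bins; if no split is accepted, a single median cut yields a 2-bin
fallback (flagged). The class label is a user choice; for a two-group
proteomic contrast the group label (e.g. transfected vs deficient) is the
natural supervision signal. Cut-point convention: intervals are
half-open $[\mathrm{low}, \mathrm{high})$, a value exactly at a cut goes to
the upper bin, and out-of-range values clamp to the end bins.

## Numerical and engineering choices

* Ties in MI ranking are broken by column-index pair order — deterministic
  for a given dataset, and sensitive to the column shuffle, as the
  randomized-order protocol intends.
* Immorality score ties within 1e-9 are `UNDECIDED`, never oriented.
* An orientation that would reverse an existing directed edge or close a
  directed cycle is skipped; trustworthy marks are only ever attached to
  directions that are actually realized in the output.
* The CI-test calibration check in the test suite runs 200 replicates at
  $N = 4{,}000$ rather than the benchmark's 50,000 purely for runtime; the
  $G^2$ null calibration is insensitive to $N$ at these sizes.
* Per-replicate benchmark seeds derive as `seed + replicate` (and offset
  streams for shuffling and learner tie-breaks), so any single replicate
  can be regenerated in isolation.
* The hill-climbing MDL baseline (`hill_climb_mdl()`) is a deterministic
  greedy search over additions/deletions/reversals from the empty graph,
  provided for benchmark comparison only.

## A worked example

```{r example}
net <- asia_network()
d <- forward_sample(net, 50000, seed = 1) |> shuffle_columns(seed = 2)
fit <- mici_learn(d, alpha = 1e-4, ci_alpha = 0.05, seed = 3)
tidy(fit)
compare_networks(fit, net)
```

The trustworthy rows are the four v-structure arrows of ASIA
(`tub -> either <- lung` and `bronc -> dysp <- either`); everything else is
reported as an undirected adjacency, exactly the reliable-but-incomplete
contract described above.

## Known limitations

* Conditioning sets never exceed one variable (triangles only), so
  higher-order independencies are invisible.
* No missing-data support; no continuous or hybrid networks.
* One pass means early mistakes are never revisited; the trace exists
  precisely so such decisions can be audited.
* The trustworthy set can be empty (accuracy is then reported as `NA`,
  not 0).
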