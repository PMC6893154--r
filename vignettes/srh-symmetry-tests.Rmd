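---
title: "Testing the SRH assumptions with matched-pairs tests of symmetry"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Testing the SRH assumptions with matched-pairs tests of symmetry}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(srhtest)
```

## The problem

Nearly all tree inference from concatenated alignments uses substitution
models that assume the process generating the data was **stationary**
(marginal state frequencies constant over time), **reversible** (detailed
balance: substitution flux between any two states is equal in both
directions), and **homogeneous** (one instantaneous rate matrix along the
whole tree) — the SRH conditions. Real data often violate them, and unlike
stochastic error, the resulting systematic bias does not shrink as data sets
grow. `srhtest` screens alignment partitions for evidence against SRH
evolution *before* trees are inferred, so that partitions carrying that
evidence can be examined or removed.

## The matched-pairs tests of homogeneity

Everything is computed from the **divergence matrix** of an ordered pair of
aligned sequences: the m-by-m table (m = 4 for nucleotides, 20 for amino
acids) whose entry $d_{ij}$ counts the alignment sites with state $i$ in the
first sequence and state $j$ in the second. Two sequences diverging under
SRH conditions accumulate differences symmetrically, so $E[d_{ij}] =
E[d_{ji}]$; asymmetry is evidence of model violation.

Three chi-square tests decompose that evidence:

* **MPTS (Bowker's test of symmetry).**
  $S_B^2 = \sum_{i<j,\; d_{ij}+d_{ji}>0} (d_{ij}-d_{ji})^2/(d_{ij}+d_{ji})$,
  with $f$ degrees of freedom, $f$ = number of unordered state pairs with
  $d_{ij}+d_{ji} > 0$. Rejection means the data are inconsistent with SRH
  evolution, without localizing the cause.
* **MPTMS (Stuart's test of marginal symmetry).**
  $S_S^2 = u^\top V^{-1} u$ where $u$ holds the row-minus-column marginal
  differences for the first $m-1$ states and $V$ is the covariance of $u$
  under marginal symmetry ($v_{ii} = d_{i\cdot}+d_{\cdot i}-2d_{ii}$,
  $v_{ij} = -(d_{ij}+d_{ji})$); $m-1$ degrees of freedom. Rejection points
  at unequal state composition, i.e. nonstationarity.
* **MPTIS (internal symmetry).** $S_I^2 = S_B^2 - S_S^2$ with $f-m+1$
  degrees of freedom: symmetry violation beyond the margins, pointing at
  changing relative rates, i.e. nonhomogeneity.

```{r}
d <- matrix(c(10, 2, 3, 4,
              5, 10, 6, 7,
              8, 9, 10, 1,
              2, 3, 4, 10), 4, 4, byrow = TRUE,
            dimnames = list(c("A","C","G","T"), c("A","C","G","T")))
matched_pairs_tests(as_divergence_matrix(d))
```

The mapping from tests to SRH conditions is indicative, not one-to-one: a
rejection localizes the symmetry that broke, not uniquely the assumption
that caused it.

### Numerical and degenerate-case choices

These choices are not forced by the definitions, so they are stated
explicitly:

* **Pairwise deletion.** A site enters the divergence matrix only when both
  residues are determinate alphabet states; gaps (`-`, `.`, `?`) and
  ambiguity codes (`N`, `R`, `Y`, `X`, ...) exclude the site for that pair
  and are tallied separately.
* **Singularity of V.** Stuart's statistic is declared ill-defined (test
  inapplicable, never scored) when the reciprocal condition number of $V$
  falls below $10^{-12}$. No pseudo-inverse is substituted: an inapplicable
  test is reported as such.
* **Negative $S_I^2$.** In exact arithmetic $S_B^2 \ge S_S^2$ whenever $V$
  is well conditioned; floating-point differences in $(-10^{-8}, 0)$ are
  clamped to 0, anything more negative marks the MPTIS inapplicable.
* **Degrees of freedom.** $f = 0$ (sequences identical at every counted
  site) makes the MPTS inapplicable; $f - m + 1 \le 0$ makes the MPTIS
  inapplicable. A chi-square with nonpositive df is undefined, so these are
  never reported as $p = 1$.
* **State order is fixed** (A, C, G, T; alphabetical one-letter amino-acid
  codes) so that dropping the last state in $u$ is deterministic and results
  are bit-reproducible. The statistic is invariant to which state is
  dropped.
* p-values are upper-tail chi-square probabilities; no continuity
  correction.

## From pairs to partitions: the MaxSymTest

The pair tests extend to a whole partition through its **maximum-divergence
pair**: every unordered pair of sequences is scored by the off-diagonal
fraction of its divergence matrix, and one pair is drawn uniformly at random
from those tied at the maximum (ties compared at tolerance $10^{-12}$). The
three tests applied to that pair are the **MaxSymTest** (MPTS),
**MaxSymTest_mar** (MPTMS) and **MaxSymTest_int** (MPTIS) for the
partition. Using the most divergent pair maximizes power without requiring
a tree.

A partition *fails* a test when the test is applicable and $p < \alpha$
(default $\alpha = 0.05$, configurable; no multiple-testing correction
across partitions, matching per-partition screening practice — a correction
can be applied to the verdict table's p-values by the user). Inapplicable
tests count as *pass*: no rejection is possible without a defined p-value.
One RNG seed governs every tie-break in a run and is recorded in all
outputs, making the otherwise arbitrary random choice reproducible.

`classify_dataset()` applies this to every partition of a scheme and
concatenates passing and failing partitions into `D_pass` and `D_fail` for
the selected test. Either side may be empty; the workflow completes and
reports the emptiness rather than inventing an empty alignment.

```{r}
bm <- make_benchmark_dataset(6, 0.5, effect_size = 1,
                             cfg_template = default_benchmark_config(1000),
                             seed = 11)
cls <- classify_dataset(bm$alignment, bm$scheme, test = "MPTS", seed = 42)
cls
summarize_classification(cls)$any_fail[c("n_fail", "prop_fail")]
```

Note the max-pair selection means the partition-level procedure is not
exactly a size-$\alpha$ test: selecting an extreme pair could inflate or
deflate the rejection rate. The suite measures this rate under SRH
simulation rather than assuming it; at the study conditions below it stays
inside the 99% binomial envelope of 0.05.

## Tree distances

Removing failing partitions matters only if it changes the inferred tree.
Tree inference itself is out of scope (the workflow documents an external
IQ-TREE invocation); the package quantifies disagreement between externally
inferred trees with three topology-only metrics, all ignoring branch
lengths and rooting:

* **Path difference (PD):** the Euclidean norm, over unordered leaf pairs,
  of the difference in topological (edge-count) leaf-to-leaf path lengths.
* **Normalized path difference (NPD):** PD divided by the mean PD of random
  pairs of trees with the same number of leaves (default 10,000 pairs; the
  normalizer can be precomputed once per leaf count with `pd_null_mean()`).
  0 = identical; 1 = as different as random trees; >1 possible.
* **Quartet distance (QD):** the fraction of 4-leaf subsets inducing
  different unrooted quartet topologies, in [0, 1]. Every quartet is
  scored exactly via the four-point condition on edge-count distances (for
  a binary tree the true split has the strictly smallest distance sum, so
  this enumeration is exact). Non-binary trees are rejected rather than
  scored under a polytomy convention, because the intended inputs are fully
  resolved ML trees.

The NPD null is **uniform over labelled unrooted binary topologies**,
generated by random stepwise addition (each new leaf attaches to an edge
drawn uniformly), which yields exactly the uniform distribution over the
$(2n-5)!!$ topologies. A uniform null is the most defensible default when
no generating process is specified; note that NPD values are sensitive to
this choice, so comparisons should use the same null.

On the conflicting 4-leaf quartets `((a,b),(c,d))` vs `((a,c),(b,d))`, four
leaf pairs change their path length by one edge, so PD = 2 and QD = 1 —
both verified in the tests against independent implementations
(`phangorn::path.dist`; exhaustive `ape::keep.tip` pruning).

## The simulator and what the calibrations mean

`simulate_alignment()` evolves i.i.d. sites down a fixed tree by
continuous-time Markov substitution: a reversible rate matrix built from
exchangeabilities and equilibrium frequencies, normalized to one expected
substitution per site per unit branch length, with transition matrices
computed per branch via the symmetrized eigendecomposition. Under
`violation = NULL` the process is SRH *by construction*, giving an exact
null for type-I error. Two minimal violations are provided:

* **Nonstationary:** branches in a chosen clade (stem included) re-target
  the equilibrium to new frequencies, same exchangeabilities — composition
  drifts, which marginal symmetry is designed to detect.
* **Nonhomogeneous:** those branches swap exchangeabilities with
  frequencies fixed — relative rates change, targeting internal symmetry.

Study conditions used by the test suite and the acceptance script, chosen
once as representative of moderately diverged empirical partitions:

* *Type-I error:* 1,000 replicates of two 1,000-site sequences separated by
  0.2 expected substitutions/site, frequencies (0.3, 0.2, 0.2, 0.3),
  HKY-style exchangeabilities with transition/transversion ratio 2.
* *Power:* 200 replicates on an 8-taxon balanced tree (all branches 0.05),
  1,000 sites, with tips t5–t8 re-targeted to the GC-rich equilibrium
  (0.05, 0.45, 0.45, 0.05) (effect size 1). At these conditions the
  MaxSymTest and MaxSymTest_mar reject essentially always while the
  MaxSymTest_int stays near the nominal level — the expected signature of
  pure composition drift.
* *NPD calibration:* 200 random 20-leaf tree pairs against a 2,000-pair
  null mean (the study-scale default of 10,000 remains the function
  default; the smaller null keeps the suite fast and its sampling error is
  well inside the tolerance checked).

The simulator draws alignments of i.i.d. sites with no rate heterogeneity,
no indels, no codon structure, and no among-site correlation. Passing
calibrations therefore demonstrate correctness of the statistics and of the
null behaviour of the full max-pair procedure — they do not certify
behaviour on real data, where alignment error, site-rate variation and
selection can all produce asymmetry of their own.

## Design notes

* Internal site coordinates are 1-based (native R indexing); both partition
  dialects (RAxML, NEXUS `sets`) are 1-based inclusive with codon-stride
  syntax `a-b\3`, so conversion is the identity and is covered by
  round-trip tests.
* FASTA and NEXUS parsing/writing delegate to `seqinr` and `ape`. Relaxed
  PHYLIP is read and written by a small internal routine because the
  available readers are either nucleotide-only or do not preserve arbitrary
  residue symbols for both alphabets; it accepts sequential and interleaved
  input and always writes sequential.
* `concatenate_alignments()` on an empty list is an error, not an empty
  alignment: the workflow must represent "no passing (or failing)
  partitions" explicitly, and does.
* Per-partition simulation seeds in `make_benchmark_dataset()` are derived
  deterministically from the master seed, so the whole benchmark corpus is
  reproducible from one integer.

## Limitations

* Power is low for pairs with few substitutions; a pass is evidence of
  absence only in proportion to the divergence available.
* The three tests share one pair of sequences per partition; they are not
  independent across tests or across partitions sharing taxa.
* QD enumerates all $\binom{n}{4}$ quartets; fine into the hundreds of
  leaves, but not asymptotically optimal.
* The test-to-assumption mapping (marginal → stationarity, internal →
  homogeneity) is heuristic; a rejection narrows, but does not identify,
  the violated condition.
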