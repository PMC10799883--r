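---
title: "Node criticality in MDS control: model, algorithm and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Node criticality in MDS control: model, algorithm and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mdscrit)
```

## The control model

A directed graph $G(V, E)$ is controlled, in the minimum dominating set
(MDS) framework, through a node subset $U$ such that every node is in $U$
or receives an edge from a member of $U$; driver signals injected at an MDS
suffice to steer the system. Because the MDS is rarely unique, each node
falls into one of three control categories: *critical* (member of every
MDS), *redundant* (member of none) or *intermittent* (member of some). The
per-node **criticality**

$$CR_i = \frac{|\{M \in M_{set} : v_i \in M\}|}{|M_{set}|}$$

refines the intermittent category into a continuous score, where $M_{set}$
is the set of all MDSs. Undirected graphs are handled by expanding every
edge to both directions at load time, which makes the same definition
apply.

Two structural facts drive the algorithm. Writing $\mathbf b_S$ for the
binary membership vector of a subset $S$, any two MDSs $S_1, S_2$ satisfy:

1. $d_H(\mathbf b_{S_1}, \mathbf b_{S_2})$ is even — both sets have size
   $|MDS|$, so $|S_1 \setminus S_2| = |S_2 \setminus S_1| = h$, the number
   of *swapped* nodes, and $d_H = 2h$.
2. $d_H \le 2\min(|IMDS| + |CMDS| - |MDS|,\; |MDS| - |CMDS|)$ — both sets
   contain all of $CMDS$, and everything outside $CMDS$ they contain is
   intermittent.

Both propositions are enforced as property tests over every pair of
solutions the package ever enumerates.

## The enumeration algorithm

`compute_criticality()` executes the following, with each step delegated to
an exported, separately tested function:

1. Classify every node (`classify_nodes()`). After one base solve giving
   $|MDS|$ and a seed solution, each node is resolved by one forced solve:
   a seed member with $x_v = 0$ (critical iff infeasible or worse than
   $|MDS|$), a non-member with $x_v = 1$ (redundant iff worse than
   $|MDS|$). A node in the seed can never be redundant and a node outside
   it can never be critical, so $|V| + 1$ solves suffice — this halves the
   naive $2|V| + 1$ forcing schedule while remaining a direct application
   of the category definitions.
2. Fix $x_v = 1$ on critical and $x_v = 0$ on redundant nodes for all
   further solves.
3. Set the initial Hamming bound $K = 2n - |MDS|$ with
   $n = \min(|IMDS| + |CMDS| - |MDS|, |MDS| - |CMDS|)$ (`initial_k()`).
   This is the closed-form maximum of proposition 2; no second solution
   needs to be solved for to obtain it. If $|IMDS| = 0$ the MDS is unique,
   $K = -|MDS|$ sits below the ladder floor and the result is the seed's
   indicator vector.
4. At the current $K$, repeatedly solve the ILP at cardinality $|MDS|$
   under one Hamming constraint
   $-\sum_{v \in S} x_v + \sum_{v \notin S} x_v \ge K$ per *already found*
   solution $S$ (a solution overlapping $S$ in $a$ nodes scores
   $|MDS| - 2a$ on this expression, so the constraint demands at least
   $(K + |MDS|)/2$ swapped nodes). Each infeasibility ends the round. When
   $K$ decreases, the constraints for **all** found solutions are rebuilt
   at the new level; this literal policy is what guarantees completeness
   at the floor.
5. Recompute scores over all found solutions and, from the second round
   on, the RMS change over intermittent nodes only,
   $dCR = \sqrt{\tfrac1I \sum_{v_i \in IMDS} (CR_i^K - CR_i^{K-2})^2}$
   (critical and redundant nodes are pinned at 1 and 0 and carry no
   convergence signal). Stop when $dCR < \theta$ or $K \le 2 - |MDS|$;
   otherwise set $K \leftarrow K - 2$.

At the floor $K = 2 - |MDS|$ the constraint only requires a new solution to
differ from each found one somewhere, so exhaustion at the floor means
$M_{set}$ is complete. With $\theta = 0$ the threshold never fires and the
run is exact; this is the reference mode, verified against the brute-force
oracle (`all_mds()`) on hundreds of random digraphs in the test suite.

### Parameters

* `theta` (default **0.01**): convergence threshold on $dCR$,
  dimensionless, on the same $[0,1]$ scale as the scores. Smaller is more
  precise; `0` is exact. 0.01–0.02 are the values used for the scaling
  studies the defaults are aligned with. Note that an early round that
  discovers no admissible solution yields $dCR = 0$ and terminates any
  $\theta > 0$ run, so approximate runs can be coarse on small graphs —
  the per-round trace (`$rounds`) is returned so this is auditable.
* `classify_by_score()` threshold (default **0.5**): high criticality is
  *strictly above* the threshold; a score exactly at the threshold is
  classified low. One-line tie rule, chosen because "high" is defined as
  strictly above 0.5.
* `solver_config(time_limit = 600)`: per-solve wall-clock budget in
  seconds. On timeout the whole run aborts with a partial-trace error
  rather than returning silently truncated scores.

### The solver

No linear-programming backend is a dependency: the domination ILP is solved
by an exact depth-first branch-and-bound written for this package.
Branching picks the undominated node with the fewest admissible dominators
and branches over them with exclusion, which visits each assignment at most
once; the lower bound is the ceiling of the undominated count over the best
single-node coverage; Hamming and cardinality constraints prune through
their attainable maxima. Variable order is node insertion order and no
randomness is involved, so reruns enumerate identically. Every "optimal"
set is re-validated in plain code against domination, forcing, Hamming and
cardinality constraints — a violation is a hard error, not a warning.
Worst-case cost is exponential (the problem is NP-hard); the intended
regime is the desk scale of the test corpus and of module-level analyses,
not connectome-scale inputs under tight deadlines.

## Downstream statistics

**Enrichment** (`enrichment()`): for an annotation with fraction
$f^D = N^D/N$ of the universe and fraction $f^D_{cat} = N^D_{cat}/N_{cat}$
of a criticality category, the score is $\log_2(f^D_{cat}/f^D)$;
significance is a two-tailed Fisher exact test on the corresponding 2×2
table. The two-tailed convention is the minimum-likelihood one (sum of all
table probabilities not exceeding the observed table's); the test suite
cross-checks it against `stats::fisher.test`. Zero overlap yields $-\infty$
with an explicit flag. The universe defaults to the analyzed network's node
set, with an optional exclusion set (e.g. zero-in-degree receptors) rather
than a hard-coded rule. No multiple-testing correction is applied — results
carry raw per-set p-values and a 0.05 reporting flag; correcting across
many annotation sets is the caller's responsibility. Degree-ranked baseline
sets (`degree_baseline_sets()`) mirror the high criticality set's size:
*top degree* takes the $|HCR|$ highest-degree nodes, *high degree* first
discards the $|CMDS|$ highest-degree nodes; ties are broken by identifier
order so the sets are reproducible.

**Module control** (`module_control()`): mean directed shortest-path
distance from sources to module nodes $\langle d\rangle$, number of direct
source-to-module edges (`links`, one count per (source, module node) pair),
and module coverage (`cov`, the fraction of module nodes with at least one
incoming source edge; only $|S_M| + 1$ values are possible). Unreachable
(source, module-node) pairs are excluded from $\langle d\rangle$ and
reported as a count — dense biological networks rarely produce them, and a
strict mode errors instead. The randomization test draws `trials` (default
10,000) uniform same-size node sets from the whole network (optionally
excluding the module), and reports one-tailed empirical p-values — lower
tail for $\langle d\rangle$, upper for `links` and `cov` — as raw fractions
that may be exactly 0; the conservative $(r+1)/(n+1)$ alternative is noted
but not applied, so a reported 0 means "no draw was as extreme". Centrality
baselines use igraph's closeness (outgoing mode), betweenness, PageRank
(damping 0.85, default convergence tolerance), out-degree and total degree,
with identifier-order tie-breaks.

## The synthetic generator

`scale_free_directed()` emulates the study conditions of the scaling
analyses: power-law in- and out-degree distributions with exponent
$\gamma = 2.5$ and mean in/out degree 3 (or 4). The mechanism — a choice
this package documents as its own, since a degree sequence alone does not
fix a generator — is a directed configuration model: degrees are drawn from
a truncated discrete power law on $1..k_{max}$ with
$k_{max} = \mathrm{round}(\sqrt{n \cdot \langle k\rangle})$ (the structural
cutoff), where the probability at degree 1 is adjusted so the expectation
equals the target mean while the tail stays exactly $\propto k^{-\gamma}$;
stub multisets are balanced by incrementing uniformly chosen nodes on the
smaller side; stubs are paired uniformly; self-loops and duplicate edges
are dropped; and the draw is rejected and redrawn until the realized mean
in-degree is within 10% of the target. In- and out-degrees are sampled
independently by default, with `degree_correlation` available to couple
them. All randomness flows through the single seed recorded in the output.

What this emulates: heavy-tailed degree heterogeneity at a controlled
density, the regime in which the Hamming ladder's pruning matters. What it
does not: degree-degree correlations, modular or bipartite structure,
reciprocity patterns of real signalling networks, or any specific published
network. Tests passing on these graphs demonstrate algorithmic correctness
and calibration, not biological conclusions.

`planted_fixture()` complements it with graphs whose MDS structure
factorizes over disjoint components (the MDSs of a disjoint union are the
Cartesian products of component MDSs), so exact criticality and the total
solution count are known in closed form: star forests (unique MDS), unions
of even directed cycles (two alternating MDSs per cycle, hence $2^k$
solutions and uniform CR 0.5), and arbitrary unions of the built-in
fixtures with expectations computed per component by the brute-force
oracle. Odd cycles are refused in `cycle_union` because their solution
count has no similarly clean closed form.

## Numerical and degenerate-input choices

* Self-loops are stripped on load: the $x_u$ term of the domination
  constraint already lets a node dominate itself.
* Duplicate edges collapse with a warning; the model is purely structural
  (no weights, multi-edges or temporal information).
* An empty network is an error everywhere; a single isolated node is a
  valid network whose unique MDS is itself.
* A node with in-degree 0 is necessarily critical (only itself can
  dominate it); this surfaces as a property test, not a special case in
  the code.
* Solver ties are broken by insertion order; exact-mode results are
  order-independent by construction, and approximate-mode results carry
  the full round trace for audit.
* Empirical p-values are raw fractions; Fisher p-values use a relative
  tolerance of $10^{-7}$ when comparing table probabilities, matching
  common practice.

## Problem sizes in the shipped tests

The suite enumerates exhaustively on 200 random digraphs of 6–12 nodes
(density 0.15–0.5) against the oracle, 25 further 12-node graphs for the
$\theta = 0.01$ accuracy report, planted unions up to six 4-cycles (64
solutions, 24 nodes), generator checks at $n = 5000$, and randomization
calibration at 1,000 trials × 100 experiments. These sizes were chosen to
keep the full suite in the minutes range on a single core while exercising
every code path; nothing in the method caps input sizes other than the
oracle's explicit 20-node refusal.

## Known limitations

* Exact enumeration is exponential in the worst case; very solution-rich
  networks (low $\theta$, high degeneracy) are the expensive regime, and
  the number of Hamming constraints grows with every found solution.
* For $\theta > 0$, early high-$K$ rounds favour solutions spread far from
  the seed; whether this transiently biases scores is not analyzed —
  exact mode is the reference.
* The branch-and-bound has no LP relaxation bound; on large dense inputs a
  dedicated MILP solver would prune better. The module surface would admit
  such a backend without interface changes.
* Criticality is a structural quantity of the MDS model; it does not by
  itself establish dynamical controllability properties beyond what the
  MDS framework provides.
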