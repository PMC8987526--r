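---
title: "Inferring Key-Event activation from transcriptomics with a causal subnetwork"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring Key-Event activation from transcriptomics with a causal subnetwork}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aopke)
```

## The problem

Adverse Outcome Pathways (AOPs) describe chemical toxicity as a linear
chain of measurable Key Events (KEs) leading from a molecular initiating
event to an adverse outcome. A KE such as *regenerative proliferation* —
compensatory hepatocyte division after repeated liver injury, a critical
step in liver-cancer AOPs — is itself the endpoint of a cascade of
molecular events. `aopke` represents that cascade as a causal subnetwork,
reads the state of its nodes from rat liver transcriptomics, and decides
per exposure condition whether the KE should be inferred active. The
package measures the state of the tissue after exposure; it does not
classify chemicals as carcinogenic or otherwise.

## The causal subnetwork

The bundled network (`rp_network()`) has 28 events — genes, proteins,
complexes, ligand families and processes — in which tissue injury engages
Wnt and hypoxia signaling, converging on dysregulated G1/S cell-cycle
transition and proliferation. Edges are signed (`activates`/`inhibits`),
typed by mechanism, and carry literature relationship numbers as metadata;
nodes are binary (active/inactive). Three transcriptional
negative-feedback edges (Tcf/Lef to Axin2 and to Dkk1, Dkk1 to Lrp) are
flagged `feedback = TRUE` and excluded from independence reasoning, which
requires an acyclic graph: the forward cascade is the causal pathway, the
feedback loops modulate it. Connectivity to the outcome is validated on
the full graph, since a pure feedback regulator such as Dkk1 acts only
through its feedback edge; acyclicity is validated on the feedback-free
working DAG.

Two transcription choices deserve note, because the source figure is not
machine-readable and the prose numbering is irregular. First, the
Cyclin-Cdk complex is given a direct edge into G1/S dysregulation,
compressing the stated chain "the complex inactivates pRb, whose loss
dysregulates G1/S"; the complex-inhibits-Rb1 edge is retained alongside.
Second, Foxm1 is given a direct inhibitory edge into G1/S dysregulation,
following the statement that dysregulation arises from inhibition of Rb1
and/or Foxm1. Whether Ccnd1 and Cdk4/6 additionally act on Rb1 directly
cannot be settled from text; the transcription follows the prose route
through the complex.

Fifteen nodes are measurable through a 25-gene panel (`rp_gene_panel()`).
Multi-gene nodes pool symbols (six Wnt ligands; Fzd1/2; Lrp5/6; Axin1/2;
Gsk3a/b). Three panel symbols required judgment calls: "Vh1" is read as
Vhl and "WNT2" as Wnt2 (capitalization/typo); Ctcf, which has no described
network relationship of its own, is carried on the Tcf/Lef:beta-catenin
complex node as the presumed intent of a Tcf/Lef-family member — the only
assignment under which the printed 25 symbols cover exactly 15 nodes.
Cdk6 belongs to the Cdk4/6 node but is not on the measured panel.

## Conditional independence and sufficiency

`d_separated()` answers conditional-independence queries on the working
DAG under standard d-separation semantics: a path is blocked at an
observed chain or fork node, and at a collider unless the collider or one
of its descendants is observed; edge signs are ignored. The
implementation moralizes the ancestral subgraph of the query and tests
connectivity, which is equivalent to checking every path — the test suite
verifies exact agreement with a brute-force path-enumeration oracle on
every labelled DAG with up to 4 nodes (every query) and on seeded random
5- and 6-node DAGs. Exhaustive enumeration at 6 nodes (3.8 million DAGs)
adds nothing a random sample does not and is out of computational
proportion, so the exhaustive sweep stops at 4 nodes.

The local Markov property — a node is independent of its non-descendants
given its parents — is the lens for reading the network: in the fixture,
Rb1 depends on each of its direct parents (the Cyclin-Cdk complex and
Psmd10) but is conditionally independent of Myc given them.

A *sufficient event* is one whose occurrence licenses inferring the
outcome. `sufficient_events()` combines two criteria: (i) proximity — a
directed path of at most `max_depth` (default 2) causal steps to the
process layer that directly drives the outcome, i.e. at most
`max_depth + 1` steps to the outcome itself; and (ii) a curated flag
backed by intervention evidence (silencing or loss of the event prevents
proliferation). The curated literature criterion is partly informal and
the two tests genuinely disagree at the margins, so the function returns
the conjunction *plus an audit*: on the fixture the result is Ccnd1, Rb1,
Cdk4/6 and Psmd10 (five proteins, counting Cdk4 and Cdk6 separately),
with Foxm1 and Gsk3 reported as proximal-but-not-curated. Proximity is
measured to the outcome's parent layer rather than the outcome because
the terminal process node (G1/S dysregulation) is an unmeasurable
bookkeeping node: counting it as a step would exclude every measurable
driver.

Each sufficient node has an expected direction — Ccnd1, Cdk4/6 and Psmd10
up, Rb1 down (loss of Rb1 is what releases the cell cycle). A sufficient
node observed in the opposite direction is recorded but neither triggers
the KE nor argues against it; activity of non-sufficient nodes alone never
triggers, because the outcome is conditionally independent of them given
the events in between.

## Differential expression

Probe intensities are quantile-normalized per chemical batch (all groups
and their controls together; the batching is configurable to global) with
the standard mean-of-order-statistics method, ties receiving the mean
reference value of their tied ranks, then log2-transformed. Each
(chemical, dose level, sacrifice time) group of replicate animals is
summarized by the mean `y` and standard error `se` of its log2 values; a
zero standard error (possible only for degenerate synthetic input) is
floored at `1e-6` and flagged.

Per probe, the package fits the partial-pooling hierarchical model

$$ y_j \sim N(\theta_j, \sigma_j^2), \qquad \theta_j = \mu + \tau\,\eta_j,
   \qquad \eta_j \sim N(0, 1), $$

with the group-level error $\sigma_j$ fixed at the replicate standard
error, $\mu \sim N(0, 10^2)$ and $\tau \sim \mathrm{HalfCauchy}(2.5)$ —
standard weakly-informative choices for this model family, both
configurable through `mcmc_control()`. Probes are fitted independently;
there is no hierarchy across probes and no multiple-testing adjustment
(decisions are per-probe and Bayesian).

**Exchangeability unit.** Which groups share one fit is a real modeling
choice. The default pools the time-matched control with the three dose
groups at one sacrifice time (J = 4), so doses inform each other but an
effect present in one group of a four-week study is not shrunk toward a
dozen unaffected groups sampled at other times. The alternative — all
dose-by-time groups and controls of a chemical in one fit — is available
as `exchangeability = "per_chemical"` in `diffexpr_calls()`. The default
was chosen quantitatively: in simulation at the package's reference
conditions (single-probe gene, true log2 fold change of log2 3 in one
group, five replicates, residual sd 0.3), the all-groups hierarchy
misses the effect in about 8% of replicates because fifteen conforming
groups pull the spread estimate down and the isolated effect is absorbed
as measurement noise, while the per-time fit misses about 0.5% with no
loss of null calibration. The per-time unit also matches studies with a
single sacrifice time, where the two choices coincide.

**Sampling.** The non-centered parameterization is sampled by Gibbs
updates for $\eta$ and $\mu$ (conjugate), an independence
Metropolis-Hastings update for $\tau$ proposing from its truncated
Gaussian pseudo-conditional (acceptance reduces to the half-Cauchy prior
ratio), and an interweaving step that re-updates $(\mu, \tau)$ under the
centered parameterization each sweep — the centered update mixes well
exactly where the non-centered one stalls (small $\tau$). Chains start
from overdispersed data-driven values; $\tau$ starts at a
method-of-moments spread estimate with multiplicative jitter, keeping
initial states out of the $\tau \approx 0$ funnel mouth where Gibbs
mixing is slowest. All updates are vectorized across probes, so a fit
over dozens of probes costs little more than one. Defaults are 4 chains
of 1000 retained draws after 1000 warmup; fits are bit-reproducible
given seed and settings. Convergence is summarized per probe by
split-R-hat and effective sample size on $\mu$ and $\tau$; R-hat above
1.05 triggers a recorded warning and a `converged = FALSE` flag, never a
silent pass. Divergent transitions are a Hamiltonian-sampler notion and
are reported as `NA`. The sampler is validated in the test suite against
a deterministic grid-integration posterior and an independent JAGS fit of
the same model, and against its analytic complete-pooling and no-pooling
limits.

**Decision rule.** For each treatment group the posterior difference
against the time-matched control is formed draw by draw and summarized by
its 95% highest-density interval (the narrowest interval holding 95% of
the draws — not equal-tailed, per the stated rule). Differences within a
1.5-fold change of zero are treated as practically equivalent to no
change: ROPE $= [\log_2(1/1.5), \log_2 1.5] \approx [-0.585, 0.585]$. A
probe is called `up` only if the entire interval lies above the ROPE,
`down` only if entirely below, otherwise `nochange` — an interval
straddling a ROPE edge is never a call. Gene-level calls take the
direction of any calling probe unless probes disagree, which yields
`nochange` with a conflict flag.

## From calls to a verdict

`node_states()` marks a measurable node active when any mapped gene is
called, with direction up/down/mixed (mixed never triggers sufficiency);
nodes whose biology is post-transcriptional (proteins, complexes) carry an
explicit caveat flag, since transcript abundance is only a surrogate for
protein activity. `infer_ke()` declares the KE active when at least one
sufficient node is active in its expected direction, and lists active
non-sufficient nodes as context. `chemical_report()` orders the verdicts
by sacrifice time and dose and reports the first activating condition.

## The synthetic-data generator

`generate_scenario()` emulates the Open TG-GATEs rat liver design: five
replicate animals per group, a control and three dose levels, the
chemical-specific sacrifice times, and single-channel intensities
generated as $2^{\text{baseline} + \text{effect} + \varepsilon}$ with
per-probe baselines $\sim N(8, 2^2)$ on the log2 scale, homoscedastic
Gaussian noise ($\varepsilon \sim N(0, 0.3^2)$ by default) and
configurable true log2 fold changes for named genes. Panel genes get 1-3
probes each (drawn from the seed). The simulated array also carries
30,000 unaffected background probes, matching the scale of the rat
genome array: quantile normalization is only meaningful against the
full-array distribution, and on a small array the sparse upper tail pins
strongly expressed probes to the extreme order statistics, distorting or
erasing their effects. The five presets (`preset_scenario()`) inject the
qualitative pattern each case study reported; their magnitude,
|log2 FC| = log2 3, is a synthetic choice placed comfortably beyond the
1.5-fold ROPE — the published figures print no numeric effect sizes.

The generator does *not* simulate probe-level microarray artifacts
(spatial effects, saturation, dye bias), probe-sequence effects,
correlated noise between genes, or dose-response shapes within a group.
Passing tests on this generator therefore show that the pipeline recovers
known effects under idealized noise of realistic magnitude, not that it
is robust to every artifact of real arrays; real Open TG-GATEs exports
can be analyzed through the same readers
(`read_expression()`/`read_design()`/`read_annotation()`) but are not
required or used by the tests.

## Numerical choices and degenerate inputs

* HDIs are computed from draws by scanning sorted-sample windows; with
  all-equal draws the interval collapses to a point.
* The ROPE boundary is exclusive: `hdi_low` exactly at $\log_2 1.5$ is
  `nochange`.
* The $\tau$ proposal guards its precision at $10^{-12}$ and truncates at
  zero; $\tau$ itself is floored at $10^{-12}$ after the interweaving
  step.
* Quantile normalization refuses non-positive or missing intensities and
  reports the offending cells; `to_log2()` likewise.
* Groups with fewer than two replicates are an error (no variance
  estimate); constant replicates get the flagged `se` floor.
* `locally_markov_independent(v, u)` with `u` a parent of `v` conditions
  on the remaining parents, so the query measures direct dependence.
* Relationship numbers are metadata only — the prose numbering is
  irregular (one number labels two distinct actions) — and are never used
  by the algorithms.

## Problem sizes used by the tests and the acceptance script

The suite runs the d-separation oracle comparison on all 572 labelled
DAGs of 2-4 nodes (every query) plus eight random 5-6-node DAGs; the
parameter-recovery check on 50 replicated eight-group experiments; the
null-calibration check on 100 seeded single-time studies; and each preset
verdict on 20 seeded runs with a scaled-down sampler (2 chains of 400
retained draws), sizes chosen so the whole suite completes in minutes on
one CPU while keeping every Monte-Carlo margin wide. The acceptance
script recomputes the same quantities from scratch with the seed it is
given.

## Known limitations

* Transcript abundance stands in for protein activity; the caveat flag
  marks where this matters (pRb, Gsk3, the complexes), but the inference
  itself cannot correct for it.
* The network is a curated transcription of published prose, not a mined
  or learned structure; alternative topologies consistent with the same
  prose exist at the edges noted above.
* Sufficiency verdicts are qualitative and per-condition; no
  dose-response or point-of-departure modeling is attempted.
* A sufficient node observed in the unexpected direction is recorded but
  not weighed against activation; the evidence model is one-sided by
  design.
* With two exposure groups the interweaving step is skipped (the
  inverse-gamma proposal needs at least three); mixing for $\tau$ is
  slower there, and the diagnostics will say so.
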