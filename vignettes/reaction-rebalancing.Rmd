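---
title: "Rebalancing incomplete reaction SMILES: models, rules and design choices"
author: "RxnRebalance"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Rebalancing incomplete reaction SMILES}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(RxnRebalance)
```

## The problem

Reaction databases routinely omit co-reactants and co-products: a recorded
esterification may list the acid, the alcohol and the ester but not the
water. Formally, a reaction $\sum_i s_i^- X_i \rightarrow \sum_j s_j^+ X_j$
is stoichiometrically balanced when for every element $a$ the total atom
counts agree, $n_a^- = n_a^+$, and the net formal charge is conserved,
$q^- = q^+$. Rebalancing means finding additional reactants and products
(with positive multiplicities) that restore both identities, under the
assumption that the recorded structures themselves are correct and only
compounds are missing.

`RxnRebalance` implements two complementary inference engines plus a
confidence model:

1. a **rule-based engine** for missing non-carbon compounds, operating on
   composition dictionaries, and
2. an **MCS-based engine** for missing carbon-containing compounds,
   operating on molecular graphs,

routed by carbon balance: already-balanced inputs pass through; a
carbon-balanced reaction with a one-sided (or a both-sides) imbalance goes
to the rule engine; a carbon-imbalanced reaction, or one the rule engine
cannot solve, goes to the MCS engine. Unsolvable inputs are returned
unmodified with a reason code, never an exception.

## Composition dictionaries and the rule-based engine

Each side of a reaction is summarized as a composition dictionary, a map
from element symbol to atom count with a reserved signed charge key `Q`.
Subtracting the two sides yields the difference dictionaries
$\Delta^-$ (reactant excess) and $\Delta^+$ (product excess), and the
four-way classification *balanced* / *reactant-dominated* /
*product-dominated* / *both-sides*. When only one side has element entries,
the entire charge difference is folded into that side; a pure charge
difference is folded into $\Delta^-$ by convention (the tie is not
chemically meaningful, but determinism requires a choice).

```{r}
rxn <- parseReaction("CC(=O)O.CCO>>CC(=O)OCC")
composition(rxn, side = "reactants")
reactionDiff(rxn)@deltaMinus
```

The engine then searches for multisets of **imputation rules**
$\hat r \rightsquigarrow X_r$ whose patterns sum exactly to the non-empty
difference dictionary. The search is a depth-first enumeration over the
library, order-canonical (each recursion level only considers rules at or
after the previous rule's position, so every multiset is visited exactly
once), with element entries required to be covered while charge may change
freely — this is what lets an ion-centric library explain a neutral delta
as, say, hydroxide plus proton.

### The shipped rule library

The default library (`inst/extdata/imputation_rules.tsv`, user-editable) is
ion-centric: water, ammonia/ammonium, hydroxide, proton, atomic and
molecular oxygen, molecular hydrogen, the halogen diatomics and halide
anions, common counter-ions (Na⁺, K⁺, Mg²⁺) and a free-electron rule.
Hydrogen halides are deliberately **not** rules: HBr is explained as
H⁺ + Br⁻. This keeps the library compact and gives the delta
`{H:2, Br:2}` exactly two minimal solutions, `{2 H⁺, 2 Br⁻}` and
`{H₂, Br₂}`, of which ranking prefers the ionic one.

Ranking minimizes the number of *distinct* rules used (so `{2 H⁺, 2 Br⁻}`
counts as two rules, not four); among ties a solution containing an ion is
preferred; remaining ties are broken lexicographically on canonical SMILES
so the result is deterministic. With water in the library, the delta
`{O:1, H:2}` is therefore resolved as one water molecule (a single rule)
rather than hydroxide plus proton — the enumeration still produces both,
and `dfsBalance()` exposes all of them.

Two guards bound the search: rules with at least one element entry are
always admissible (total applications are bounded by the delta's atom
count), while the pure-charge electron rule is only applied when it moves
the charge strictly toward zero; a configurable depth cap (default 8
applications) protects against pathological inputs. Within the small-delta
domain used by the test oracles these guards provably lose no solutions.

### Post-processing and redox notation

Three chemical-plausibility rules are applied to the compounds imputed on
the product side: (i) a free halogen as product invalidates the solution;
(ii) atomic oxygen as product becomes water, with H₂ added to the
reactants; (iii) molecular hydrogen as product — unless an alkali metal or
a hydride reagent is among the reactants — becomes water, with atomic
oxygen added to the reactants. Hydride detection is heuristic: any reactant
with hydrogen on B, Al, Si, Sn or a common metal, or an explicit hydride
ion. Both rewrites preserve balance exactly. If the top-ranked solution is
rejected, the next-ranked ones are tried in order.

Finally, imputed H₂ (O₂) among the *reactants* is rewritten as two unbonded
`[H]` (`[O]`) atoms — the chemist's convention for "some reducing
(oxidizing) agent", since molecular hydrogen rarely is the actual reagent:

```{r}
ruleBasedRebalance(parseReaction("CC(=O)O>>CCO"))
```

Both steps are toggles (`applyPostprocess`, `applyRedoxRefine`), and the
refinement never touches original input molecules, only imputed ones.

## The MCS-based engine

For carbon imbalances the engine orients the reaction so that $X$ is the
side with more carbons ($Y$ the other; ties broken by total atom count,
then reactants-as-$X$), and aligns each connected component $X_i$ of $X$
against $Y$ with a **connected maximum common subgraph** search. Matched
target vertices are removed after each component ("iterative alignment"),
so no $Y$ atom is matched twice; components are processed in decreasing
size order. The unmatched residue of each $X_i$, split into connected
fragments together with its cut edges (the broken bonds, each remembering
its bond order and the element of the matched partner atom), is the raw
material of the missing compound.

The solver is a backtracking enumeration over vertex pairs that keeps the
common subgraph connected and returns *all* maximum embeddings. Two problem
variants are implemented: the induced-subgraph variant (atom-count
objective) and the edge-subgraph variant (bond-count objective). Ring
constraints use bridge detection (an edge lies on a cycle iff it is not a
bridge): `ringMatchesRingOnly` restricts vertex and edge compatibility,
while `completeRingsOnly` is enforced as a filter on the maximum embeddings
(a configuration whose embeddings are all filtered simply contributes
nothing). A per-component node budget (default `2e5` search nodes) bounds
the worst case; exhausting it marks that configuration as timed out.

### Choosing among embeddings and configurations

The maximum common subgraph is rarely unique. Among equal-size embeddings
the engine picks the one whose removal leaves the fewest residue fragments
— the principle of minimum chemical distance: fewer fragments mean fewer
broken bonds — with ties broken by fewest cut edges, then by fewest
bond-order mismatches among matched edges, then lexicographically. The
bond-order tie-break matters in practice: when bond orders are ignored, an
alcohol can otherwise be matched onto an acyl C=O, which produces a
chemically wrong residue.

Five solver configurations form an ensemble (ring constraints × bond-order
constraint for the induced variant, plus the unconstrained edge variant).
Candidates are ranked by total matched size, then fewest fragments, then
fewest cuts, then configuration order; the pipeline below is attempted on
each candidate in rank order and the first one that completes wins. This
fall-through is the package's reading of the open "amalgamation" question:
a fragment set is only as good as the compound it reconstructs.

### Expand and merge rules

Cut edges are resolved pairwise: a **merge rule** inserts a bond between
two boundary atoms on *distinct* compounds (never two boundaries of the
same compound) and consumes one cut from each side, so termination is
guaranteed. When the cuts are concentrated on a single fragment there is
nothing to merge with; **expand rules** then append the missing single-atom
fragment based on the boundary context — oxygen for acyl/ester/amide/ether
cuts, hydrogen for an amine boundary cut from a carbon. Both rule tables
are plain-text data files (`expand_rules.tsv`, `merge_rules.tsv`), matched
in declaration order; the default merge inserts a single bond, with a
specific rule creating a double bond at a phosphorus–oxygen pair whose cut
was a double bond. Fragments without cuts pass through as standalone
compounds.

```{r}
mcsRebalance(parseReaction("CC(=O)OCC>>CCO"))
```

A successful merge yields compounds $Z$ added to the $Y$ side; the result
is carbon-balanced by construction, and any residual non-carbon imbalance
(the water above) is delegated to the rule-based engine. Failure modes —
more than 6 molecules, a fragment with more than 2 boundaries, no boundary
at all, an unresolvable cut, post-merge carbon imbalance — all return the
unmodified input with a reason code. The compound and boundary ceilings are
configurable; their defaults mark the envelope within which graph
alignment is empirically trustworthy, and reactions that rearrange or
close rings are deliberately out of reach of this fragment model.

## Confidence model

MCS imputations vary in reliability with reaction complexity, so solved
MCS outcomes can be scored by a gradient-boosted tree classifier
(`xgboost`) over eight automatically computable features: total carbons,
bonds and rings of the rebalanced reaction (both sides summed; rings are
cyclomatic numbers), the fragment count and boundary count of the winning
alignment, the absolute carbon imbalance of the *input*, and the absolute
bond/ring total changes from input to output. Manually counted bond
changes are intentionally not a feature.

Training uses a stratified 80/20 split; the minority class of the
*training portion only* is balanced by synthetic-minority oversampling
followed by Tomek-link cleaning (both implemented in-package), and
held-out F1-micro, AUC and average precision are stored in the model
metadata. Everything is reproducible under one seed. Booster
hyperparameters are modest library defaults (depth 4, 60 rounds,
eta 0.3), all exposed.

Because no manually labeled corpus ships with the package, the model is
exercised on a planted-rule simulation: features are drawn from plausible
ranges, the label is `num_boundary <= 2`, and 10% of labels are flipped.
One subtlety is worth recording: with a hard threshold rule the
Bayes-optimal score takes only two values, and the resulting rank ties cap
the AUC measured against the *noisy* labels at about 0.90 regardless of
model quality. The meaningful question is whether the model recovers the
*planted rule*, so recovery is evaluated as the AUC of held-out scores
against the uncorrupted planted labels (training still sees only noisy
labels); a model that truly learns the rule reaches AUC ≈ 1 there.

```{r}
sim <- simulateConfidenceData(1000, seed = 42)
model <- trainConfidenceModel(sim$features, sim$labels, seed = 42)
model
```

`filterByThreshold()` keeps rule-based outcomes unconditionally (the
confidence model applies to the MCS branch only) and gates MCS outcomes at
`tau`; raising `tau` can only shrink the solved set.

## The synthetic fixture generator

`generateFixtureSet()` emits balanced reactions from six template families
— esterification, ester hydrolysis, amide coupling, halide elimination,
alcohol oxidation and a Grignard-like addition — instantiated over linear
alkyl substituents (C1–C6). Linear chains are used deliberately: a branched
substituent written as a SMILES prefix attaches at a different atom than
the same string as a suffix, which would make a template's ester
structurally inconsistent with its alcohol. Non-carbon co-products are
written in the dissociated-ion convention (`[H+].[Br-]` rather than HBr)
to match the ion-centric library; oxidations carry `[O]` as the oxidant
and the Grignard template is fully covalent (no removable co-product, so
it exercises the already-balanced path). Every emitted reaction is
verified balanced by composition arithmetic.

`unbalanceReaction()` reproduces the benchmark perturbation used for
balanced reference data: in reactions with exactly two products the
smaller product is removed (smallest total atom count including hydrogens;
ties by heavy atoms, then canonical SMILES — the quantity behind "smaller"
is a documented choice), and each distinct non-carbon compound is removed
once per side, never emptying a side. `closedLoopBenchmark()` then
perturbs, rebalances and scores **exact canonical equality** against the
ground truth: the whole-reaction canonical form (one fixed OpenBabel
canonical SMILES writer applied identically to predictions and
references, molecules sorted within sides) must match. Structurally
different but chemically valid alternatives count as wrong; the metric is
conservative by design.

```{r, eval = FALSE}
bench <- closedLoopBenchmark(n = 500, seed = 42,
                             removeSmallerProduct = FALSE)
bench$metrics
```

What passing these loops shows — and what it does not: the fixtures
exercise both engines, charges, duplicate removals and the redox
convention, but they are template chemistry over small acyclic molecules.
Real database entries bring aromatic systems, stereochemistry (ignored
here), salts written covalently, agents mixed into reactant lists, and
error modes (wrong structures) that this package, by assumption, does not
attempt to repair.

## Numerical and scale choices

The test suite and the evaluation scripts run the closed loop at 500
fixtures (seed 42), the DFS-versus-enumeration oracle over all deltas of
up to 6 atoms on {H, O, N, Cl, Br}, and the embedding-selection oracle on
molecule pairs up to 12 heavy atoms — sizes at which the brute-force
oracles are exact and the whole suite completes in well under a minute on
one core. MCS search budgets (2e5 nodes per component) are far from
binding on fixture-scale molecules; they exist for adversarial input.

## Known limitations

- One missing compound set per side: multi-step records and rearrangements
  are out of scope and fail closed.
- Formal charges are read from MDL charge codes, so per-atom charges
  beyond ±3 are not represented.
- Aromatic systems are handled in kekulized form; alternative kekulizations
  of the same ring can reduce match sizes under the order-respecting
  configurations (the ensemble's ignore-order members compensate).
- The free electron is modelled as a zero-atom pseudo-molecule with the
  token `[e-]`; it participates in balance arithmetic but has no structure.
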