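# RxnRebalance

Most entries in large reaction databases are stoichiometrically
incomplete: co-reactants and co-products such as water, HCl or the second
product of a hydrolysis are simply missing. `RxnRebalance` curates such
records by inferring the missing compounds, for anyone who needs balanced
reactions downstream — atom–atom mapping, synthesis planning, reaction
classification or metabolic-network analysis.

A reaction $\sum_i s_i^- X_i \rightarrow \sum_j s_j^+ X_j$ is balanced
when every element satisfies $n_a^- = n_a^+$ and the net charge satisfies
$q^- = q^+$. The package restores these identities with two engines routed
by carbon balance:

- **Rule-based** (carbon-balanced inputs): each side is collapsed into a
  composition dictionary `{element: count, Q: charge}`; the element-wise
  difference Δ is reduced to the empty dictionary by a depth-first search
  over an ion-centric rule library (`{O:1,H:1,Q:-1} ⇝ OH⁻`, …). All
  solutions are enumerated; ranking prefers the fewest distinct rules,
  then solutions containing an ion. Post-processing rejects implausible
  products (free halogens), rewrites imputed O/H₂ products as water, and a
  redox refinement renders imputed reducing/oxidizing agents as unbonded
  `[H]`/`[O]` atoms.
- **MCS-based** (carbon-imbalanced inputs): the carbon-rich side X is
  aligned against the carbon-poor side Y by an ensemble of five connected
  maximum-common-subgraph configurations (induced and edge-subgraph
  variants, ring and bond-order constraints). The unmatched residue
  fragments, with their cut bonds, are completed by expand rules (append a
  missing atom) and merge rules (insert a bond between boundary atoms of
  distinct fragments) into the missing compound Z; any residual non-carbon
  imbalance is handed back to the rule engine. Embeddings are chosen by
  the principle of minimum chemical distance (fewest residue fragments).
- **Confidence**: solved MCS outcomes can be scored by a gradient-boosted
  tree model over automatically computable complexity features
  (boundary count, fragment count, bond/ring changes, …), trained with
  stratified splitting and SMOTE+Tomek resampling of the training portion.

Molecules are parsed and canonicalized through OpenBabel
(ChemmineOB); graphs are igraph objects; the classifier is xgboost.

## Worked example

```r
library(RxnRebalance)

# an esterification recorded without its water by-product
rebalance("CC(=O)O.CCO>>CC(=O)OCC")
#> RebalanceOutcome [rule] solved
#>   in:   CC(=O)O.CCO>>CCOC(=O)C
#>   out:  CC(=O)O.CCO>>CCOC(=O)C.O
#>   + products:  O

# a de-esterification missing a carbon compound: the MCS engine rebuilds
# acetic acid from the unmatched acetyl fragment, the rule engine adds the
# water
rebalance("CC(=O)OCC>>CCO")
#> RebalanceOutcome [mcs] solved
#>   in:   CCOC(=O)C>>CCO
#>   out:  CCOC(=O)C.O>>CCO.CC(=O)O
#>   + reactants: O
#>   + products:  CC(=O)O

# a reduction: imputed H2 is rendered as the [H] reducing-agent convention
rebalance("CC(=O)O>>CCO")
#> RebalanceOutcome [rule] solved
#>   in:   CC(=O)O>>CCO
#>   out:  CC(=O)O.[H].[H].[H].[H]>>CCO.O
#>   + reactants: [H].[H].[H].[H]
#>   + products:  O
```

The first output reads: the product side gains one water molecule (`O`),
making every element count and the total charge equal across the arrow;
`method = "rule"` records which engine solved it. Unsolvable inputs come
back with `solved = FALSE`, the unmodified reaction and a reason code.

Batch processing and evaluation are available as functions
(`runBatch()`, `closedLoopBenchmark()`, `evaluateOutcomes()`) and as a
thin command line:

```sh
Rscript scripts/rebalance.R run --input reactions.smi --output out.csv
Rscript scripts/rebalance.R eval --pred pred.smi --ref ref.smi
```

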