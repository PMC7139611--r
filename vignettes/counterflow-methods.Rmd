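---
title: "Counter-expression analysis of miRNA/mRNA regulation: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Counter-expression analysis of miRNA/mRNA regulation: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(counterflow)
```

## The scientific problem

MicroRNAs repress their target mRNAs, so in a contrast where a miRNA goes
*up*, its true targets should go *down*. Computational target predictors
alone produce long, false-positive-heavy candidate lists; expression data
alone cannot say which regulator drives which transcript. Counter-expression
integration combines the two: keep a predicted (miRNA, mRNA) pair only when
the pair moves in opposite directions in the same experiment.

`counterflow` implements this integration as a staged, fully auditable
pipeline, built around a published atherosclerosis-progression (ATHp) study
design in the ApoE-deficient mouse:

1. **Reverse Gene Ontology gene set.** Instead of annotating a gene list,
   start from GO terms — "response to oxidative stress" (`GO:0006979`) and
   its regulation children (`GO:1902882/3/4`) — and collect every gene
   annotated to them ("Oxstress" genes). `parse_obo()`, `parse_gaf()`,
   `descendant_terms()` and `compile_gene_set()` implement this; symbols
   are uppercased for identity (murine `Ccr7` = human `CCR7`), deduplicated
   and sorted, with per-term counts kept as provenance.
2. **Consensus targets.** Per-algorithm prediction tables are pooled;
   `consensus_targets()` keeps a pair when at least `min_sources` *distinct*
   algorithms predict it (default 1, since the membership-only aggregation
   of the multi-algorithm web tools cannot be reconstructed more finely).
3. **Counter-expression validation.** `counter_expressed_pairs()` keeps a
   pair when the gene lies in the oxstress set, appears in the mRNA
   differential-expression (DE) table, and has direction opposite to its
   miRNA. Direction is an explicit column — published tables print absolute
   fold changes under "upregulated"/"downregulated" headers, so inferring
   sign from fold change would be wrong. DE tables are treated as already
   significant; an optional `p_max` exists but is off by default.
4. **Characterization.** Hypergeometric GO enrichment with
   Benjamini–Hochberg FDR (`enrich()`), and a bipartite miRNA–gene network
   (`build_bipartite()`) with degrees, shared regulators and a
   Barber-modularity community partition (`detect_communities()`).
5. **qPCR validation.** The comparative Ct method
   (`collapse_replicates()`, `delta_ct()`, `delta_delta_ct()`) with
   Mann–Whitney rank-sum tests and volcano/scatter tables, for the human
   PBMC follow-up contrast (10 coronary-artery-disease patients vs 12
   controls).

The packaged reference data (`athp_target_map()`, `athp_mrna_de()`,
`athp_mirna_de()`) hold the study's published core: 14 validated oxstress
transcripts, 13 upregulated miRNAs, 68 predicted targeting relationships.

```{r fixture}
map <- athp_target_map()
net <- build_bipartite(map)
net
shared_regulators(net, "Ccr7", "Foxo1")
```

## The statistical machinery

### Hypergeometric enrichment

For a query of $n$ genes from a universe of $N$, a category with $K$
members and $k$ query hits gets the one-sided over-representation p-value

$$p = P(X \ge k), \qquad X \sim \mathrm{Hypergeom}(N, K, n).$$

`hypergeom_tail()` evaluates the sum in log space (`lchoose` +
log-sum-exp) so deep tails at large $N$ do not underflow; it matches
term-by-term pmf enumeration to $<10^{-9}$ over the exhaustive grid
$N \le 60$ (and spot checks far beyond). FDR control uses the standard
step-up rule via `stats::p.adjust`. The universe defaults to every
annotated symbol in the loaded GAF, because the background used by
interactive enrichment servers is generally not recoverable; published FDR
values from such servers are therefore *not* reproduction targets, only
the $(k, K)$ count structure is. Term-to-gene mapping is direct annotation
by default; `propagate = TRUE` turns on is\_a ancestor propagation and
logs it, since tool behavior on this point varies.

### Rank-sum testing

`rank_sum_test()` is a thin, explicitly-contracted wrapper around
`stats::wilcox.test`: exact two-sided p (doubled smaller tail, capped at 1)
when the pooled size is ≤ `exact_max_n` (default 16) and there are no
ties; otherwise the normal approximation with midranks, tie correction and
continuity correction. A fully degenerate comparison (all values equal)
returns p = 1, flagged. The exact path is verified against complete
enumeration of all $\binom{n_x+n_y}{n_x}$ rank splits for all group sizes
up to 8, and the approximate path is calibrated by simulation: under a
Gaussian null at the study's group sizes (10 vs 12), the type-I error at
$\alpha = 0.05$ sits near 0.04 (conservative, as expected for a discrete
statistic with continuity correction).

### The comparative Ct method

With reference gene $r$ (here `ACTB`):
$\Delta Ct_{s,g} = Ct_{s,g} - Ct_{s,r}$ per sample,
$\Delta\Delta Ct_g = \overline{\Delta Ct}_{\text{case}} -
\overline{\Delta Ct}_{\text{control}}$, fold change $2^{-\Delta\Delta Ct}$.
A *positive* $\Delta\Delta Ct$ means the case group needs more cycles
relative to the reference — i.e., *down*regulation in cases. Groups are
independent patients, so the group-mean difference (not per-sample pairing)
is used, and the significance test runs on the per-sample $\Delta Ct$
values. Undetermined wells are treated as missing, never imputed to a
ceiling cycle: a transcript that fails to amplify supports no quantitative
claim. Normalization invariance (adding a constant to every Ct of a sample
changes nothing downstream) holds by construction and is tested.

**Replicate QC.** Duplicate wells are averaged; a well whose replicate
spread exceeds `max_spread` is excluded and logged. The default is 1.0
cycles: with per-well noise around 0.3 cycles the difference of duplicates
has standard deviation $0.3\sqrt{2} \approx 0.42$, so 1.0 (≈ 2.4 sd)
removes genuine outliers — pipetting failures, evaporation — without
discarding ordinary technical variation. A tighter limit (0.5 is sometimes
used on low-noise instruments) would reject about a quarter of honest
duplicates at this noise level.

### Bipartite communities

Modularity on a bipartite graph needs a bipartite null: only
(miRNA, gene) slots can hold edges. Barber's modularity

$$Q_B = \frac{1}{m} \sum_{i \in \text{genes}} \sum_{j \in \text{miRNAs}}
 \left(A_{ij} - \frac{d_i e_j}{m}\right) \delta(c_i, c_j)$$

is maximized by a deterministic three-phase procedure: greedy agglomeration
from singletons (best positive merge first, lexicographic tie-breaks), a
node-sweep refinement that moves single nodes to strictly better modules
(the alternating-reassignment idea of bipartite modularity maximization,
which repairs the local maxima plain agglomeration is prone to), and a
final coalescence that merges connected modules whose union leaves $Q_B$
unchanged — resolving ties toward fewer modules, so a lone edge is one
module, not two. No randomness enters; the `seed` argument is recorded in
the result purely for provenance. On the packaged 27-node study network the
partition is reported, not asserted: the published "two main networks"
reading is a visual claim, and hard assertions are reserved for planted
synthetic graphs.

## The synthetic-data generator

`generate_bundle()` writes every input the pipeline reads — OBO, GAF,
per-source prediction TSVs with a manifest, miRNA/mRNA DE tables, and a
long-format Ct table — with planted ground truth returned alongside. The
defaults *are* the study conditions the package targets: 13 upregulated
miRNAs; a funnel of 100 oxstress genes, 40 of them predicted targets, 10 of
those downregulated (the desk-scale stand-in for the study's 417 → 108 → 14
funnel, whose absolute numbers depend on a GO release and a prediction-server
snapshot and are deliberately not reproduction targets); a qPCR contrast of
10 cases vs 12 controls with a planted 2-cycle shift on `CCR7`/`FOXO1` and
0.3-cycle well noise. Murine-stage fixtures use title-case symbols and the
qPCR fixture uppercase ones, so the canonicalization path is exercised end
to end. Decoy (up-miRNA, up-gene) pairs are planted specifically to probe
the counter-expression exclusion rule.

Source behavior is Bernoulli per (pair, algorithm): true pairs are reported
with probability `source_sensitivity`, false ones with `source_fpr`, so at
sensitivity 0.8 and five sources the per-pair detection probability has the
closed form $1 - 0.2^5 = 0.99968$, which the tests check against observed
recovery. With sensitivity 1 and false-positive rate 0 the pipeline must
recover the planted pairs exactly (precision = recall = 1), and does, across
50 seeds.

`simulate_two_block_network()` plants two dense miRNA–gene blocks
(within-block edge probability 0.85) joined by 5% inter-block edges. The
density is an identifiability choice, not a convenience: at these block
sizes (8 genes + 7 miRNAs per block, the scale of the study's network),
sparser blocks frequently yield realizations whose modularity *optimum* is
not the planted bipartition — exact recovery would then be ill-posed for
any optimizer. At 0.85 the planted partition is the optimum in essentially
every realization, so adjusted-Rand-index-equals-1 recovery measures the
optimizer, not the benchmark's noise.

What the generator does **not** emulate: raw microarray intensities or
reads (DE tables are consumed as precompiled lists, as in the study),
correlated prediction errors between algorithms (sources err independently
here; real predictors share seed-match logic and fail together),
amplification-efficiency differences between qPCR assays, and annotation
incompleteness bias in GO. Passing tests therefore demonstrate correctness
of the integration logic and calibration of the statistics under these
idealized conditions — not robustness to correlated prediction bias or
array-level artifacts.

## Numerical and design choices

- **Determinism everywhere.** One integer seed drives each generator; C-
  collation (`radix`) sorting everywhere ordering matters; community
  detection has lexicographic tie-breaks; GML export strips the library's
  timestamp line. Two runs with equal config hash and input digests produce
  byte-identical outputs, and the JSON run manifest (tool version, config
  hash, md5 input digests, per-stage counts, failure record if any) is
  written even when a stage aborts.
- **Evidence codes.** All GAF evidence, including IEA, is kept by default
  (`exclude_evidence` is available): browser-style term queries do not
  document an evidence filter, so the inclusive choice is the reproducible
  one.
- **Descendant expansion off by default.** The four oxstress terms are
  passed as an explicit root list; the study design queried each term
  separately rather than traversing the ontology, and `descend = TRUE` is
  available where traversal is wanted.
- **miRNA identity.** Exact, case-insensitive matching after trimming;
  species prefixes (`mmu-`, `hsa-`) are never auto-translated — one of the
  study's miRNAs has no human homolog, so silent cross-species mapping
  would manufacture data.
- **Isoforms.** Multiple RefSeq rows of one gene collapse to the symbol;
  the first-printed Seqname is retained in the DE fixture.
- **Boundary conventions.** `significant` is `p < alpha` strictly; a fold
  change of exactly 1 reports direction `"down"` by documented tie-break;
  BH q-values may tie below their raw p; `k = 0` gives a hypergeometric
  tail of exactly 1.
- **Problem sizes in the checks.** The shipped verification uses the full
  hypergeometric grid to $N = 60$, 2000 null simulations for rank-sum
  calibration, 200 Ct simulations for effect recovery, 50 noiseless
  pipeline seeds and 20 planted networks — sizes at which every check is
  exact or has comfortable Monte-Carlo margin while the whole suite stays
  interactive.

## Known limitations

- The reported funnel counts are properties of the *inputs*, not universal
  constants: re-running the gene-set stage against a different GO release
  or prediction snapshot legitimately changes 417/108/14-style numbers.
  The package therefore validates structure (counts against planted ground
  truth, set identities on packaged fixtures), never live-database values.
- Enrichment FDRs from interactive servers are not reproducible without
  their background and propagation rules; only count structure is checked.
- The STRING protein–protein-interaction step of the original study is an
  external curated-database lookup, not a computation, and is out of scope.
- `delta_delta_ct()` assumes equal amplification efficiency across assays
  (the classical comparative-Ct assumption); standard-curve correction is
  not implemented.
- Community detection optimizes modularity, which at small block sizes can
  genuinely prefer a finer split than a planted structure; the package
  reports modularity alongside the partition so such cases are visible.
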