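---
title: "Combinatorial regulation of CRMs and miRNAs: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Combinatorial regulation of CRMs and miRNAs: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crmmir)
```

## The scientific problem

Transcription is controlled by cis-regulatory modules (CRMs) — combinations
of transcription-factor binding motifs acting together — while microRNAs
(miRNAs) repress their target transcripts post-transcriptionally.  Genes
targeted by the *same* CRM, or the same miRNA, tend to be co-expressed.
`crmmir` asks what happens when the two layers intersect: for each
(CRM, miRNA) pair it forms the **CRM–miRNA module** — the genes targeted by
both — and tests whether such doubly-regulated gene sets are more coherently
expressed than either regulator's targets alone, then assembles and
dissects the tripartite regulatory network of CRMs, miRNAs and genes.

The package covers five analyses, each usable on its own:

1. **Module construction** (`build_modules`): target-set intersections,
   dropping gene sets with fewer than two genes.
2. **Coherence and its significance** (`coherence`,
   `test_module_coherence`): mean pairwise Pearson correlation, tested
   against randomization backgrounds with empirical p-values and BH-FDR.
3. **CRM→miRNA edge prediction** (`predict_crm_mirna_edges`): PWM
   log-likelihood scanning of pri-miRNA upstream sequence with an
   empirical cutoff and a 200 bp site-clustering rule.
4. **Network pattern census** (`count_patterns`, `pattern_zscores`):
   exact counts of all connected ≤3-node regulation patterns, scored
   against degree-preserving edge-swap null networks.
5. **Knockdown co-regulation model** (`select_mirna_regulators`): a linear
   model of TF-depletion expression log-ratios with per-miRNA prescreening
   and stepwise-AIC selection.

A seeded synthetic-data generator produces every input with known ground
truth, so the full pipeline runs — and is tested — without any external
database.

## Coherence of a gene set

For genes $a, b$ measured by probesets, the gene-pair correlation is the
**maximum** Pearson correlation over all probeset pairs; probeset pairs
with a zero-variance member are skipped, and a pair where every probeset
combination is flat is *undefined* rather than zero.  The coherence of a
gene set $S$ is the mean over all unordered pairs:

$$\mathrm{coh}(S) = \binom{|S|}{2}^{-1} \sum_{\{a,b\} \subseteq S} r_{ab},$$

with undefined pairs excluded from the mean.  Excluding rather than
zeroing undefined pairs avoids biasing coherence toward 0 for flat
probesets; "all gene pairs" is read as unordered distinct pairs.

```{r coherence-example}
gen <- gen_expression(n_genes = 40, n_samples = 50,
                      blocks = list(list(size = 8, rho = 0.9)), seed = 1)
block <- gen$truth$planted_blocks[[1]]$genes
coherence(gen$expr, block)          # near the planted correlation
coherence(gen$expr, sample(names(gen$expr$gene_index), 8))
```

## Randomization backgrounds and empirical p-values

Two nulls isolate the two regulators' contributions:

* **Background 1** redraws the module's genes uniformly, size preserved,
  from the CRM target pool.  The package defaults to the module's *own*
  CRM target set and offers the union of all CRM target genes as an
  option (`bg1_pool = "union"`); both readings appear in descriptions of
  this procedure, and the single-CRM pool is the stricter null (it asks
  whether the miRNA adds coherence *beyond* the CRM).
* **Background 2** builds an artificial miRNA by sampling as many genes as
  the real miRNA targets from the union of all miRNA target genes — thus
  preserving the (heavy-tailed) distribution of miRNA target-set sizes —
  and intersects it with the CRM targets.  Intersections below two genes
  are redrawn (up to 1000 times; a rep that stays degenerate scores below
  any observed coherence), keeping set sizes comparable without
  fabricating signal.

The p-value over $R$ reps is the fraction of random sets with coherence
*equal or higher* than observed (ties count).  With 100 reps p-values live
on the grid $\{0, 0.01, \ldots, 1\}$; five-rep backgrounds are supported
for plotting background distributions.  Multiple testing is handled by
Benjamini–Hochberg FDR (`fdr_correct`).

One consequence of the discrete construction worth knowing: for a
continuous statistic, $\Pr(p \le \alpha)$ under the null is exactly
$(\lfloor \alpha R \rfloor + 1)/(R + 1)$ — about $0.059$ for
$\alpha = 0.05$, $R = 100$ — not $\alpha$ itself.  The calibration tests
check against this exact level.

Reproducibility: each run uses one seed, and every module gets its own
RNG stream derived from the run seed and the module index, so results do
not depend on evaluation order.

## PWM scanning and the 200 bp rule

A motif site of length $L$ is scored in natural-log units as

$$s = \sum_{j=1}^{L} \log \frac{p'_j(x_j)}{q(x_j)}, \qquad
  p'_j = (1 - w)\, p_j + w\, q,$$

where $p_j$ is the PWM column, $q$ the background base distribution, and
$w = 0.01$ a pseudocount blend that keeps zero-probability columns finite.
`N` bases contribute zero.  Both strands are scanned by default (reverse
hits reported in forward coordinates, 0-based internally, 1-based in TSV
output).

The per-motif cutoff is the empirical **99.99% quantile** (type-7
interpolation) of all window scores on a random i.i.d. background
sequence; one seeded calibration sequence of $10^6$ bases is shared by
all motifs of a background model.  By construction about one window in
$10^4$ of fresh background sequence exceeds the cutoff, which the tests
verify directly.

A CRM is predicted to regulate a miRNA when **every** motif of the CRM has
a binding site in the miRNA's upstream 5 kb and those sites fall within
one 200 bp span: there must exist one hit per motif with
$\max(\mathrm{start} + L) - \min(\mathrm{start}) \le 200$.  The span
reading (rather than all pairwise distances) matches how motif clusters
are delimited in CRM-discovery methods; it is evaluated by sliding an
anchor over hit positions, not by enumerating hit combinations.  Edge
calling is monotone in the window size and anti-monotone in the cutoff.

## The tripartite network and its patterns

The network has typed nodes (CRM, miRNA, gene) and four directed edge
types: CRM→gene and miRNA→gene from the target maps, CRM→miRNA from the
upstream scan, and miRNA→CRM whenever the miRNA targets a gene encoding a
TF whose motif belongs to the CRM.

The pattern catalog is the **exhaustive** set of weakly connected simple
typed digraphs on at most three nodes over these edge types — 31 patterns
after deduplication up to type-preserving node permutation.  The
heterotypic CRM–miRNA–gene family alone contains exactly ten patterns,
among them the two feed-forward-loop variants (CRM→miRNA→gene with
CRM→gene, and miRNA→CRM→gene with miRNA→gene), the co-regulation fork,
the two cascades, and their unions; named entries mark these.
Enumerating exhaustively rather than hand-picking topologies guarantees
coverage without guessing a published ordering.

Counting is **subgraph** (not induced) matching: an occurrence is an
injective, type-respecting node assignment in which every pattern edge is
present, extra edges allowed, divided by the pattern's automorphism
count.  A triangle therefore also contains its sub-fork and sub-cascades;
this combination-counting convention is what makes occurrence counts of
dense patterns astronomically large in genome-scale networks.  The census
is computed with closed-form adjacency-matrix expressions and is checked
exactly against brute-force enumeration in the tests.

Significance uses 100 degree-preserving random networks built by repeated
double-edge swaps **within each edge type** — $(a{\to}b, c{\to}d)
\mapsto (a{\to}d, c{\to}b)$, rejecting duplicates — so every node keeps
its per-type in/out degree and all edge-type counts are preserved.  The
two swapped edges are drawn with replacement (rejecting $i = j$), which
makes the number of accepted swaps random; with a fixed accepted count
the chain would be confined to one parity class of the target
permutation and could not reach half the state space.  Ten attempted
swaps per edge is the standard mixing heuristic.  For each pattern,

$$Z = \frac{N_{\mathrm{real}} - \overline{N}_{\mathrm{rand}}}
           {\mathrm{sd}(N_{\mathrm{rand}})},$$

reported to four decimals; when the null standard deviation is zero the
Z-score is undefined and reported as `NA` rather than forced.

```{r network-example}
gen <- gen_network(8, 8, 30,
                   edge_probs = list(c2g = 0.08, m2g = 0.08,
                                     c2m = 0.05, m2c = 0.05),
                   planted_ffl_count = 20, seed = 2)
zs <- pattern_zscores(gen$network, n_random = 50, seed = 3)
subset(zs, !is.na(name), c(name, observed, null_mean, null_sd, z))
```

## The knockdown co-regulation model

After depleting a TF, the expression log-ratio $g_k$ of gene $k$ (after
vs before) is modeled as

$$g_k = c + a_{TF}\, b_{TF,k} + \sum_i a_{mir_i}\, b_{mir_i,k}
        + \varepsilon_k,$$

with 0/1 target indicators $b$ and effects shared across genes — with a
single observation per gene, per-gene effects would be unidentifiable, so
the shared-effect reading is the only estimable one.  Replicates are
expected to be averaged upstream.

Selection is two-staged, mirroring how the model is used in practice:
each miRNA is first prescreened in a model with only the intercept, the
TF and that miRNA (two-sided t-test of the miRNA coefficient,
$p < 0.05$ by default; rank-deficient designs are excluded with a
warning), and the survivors enter a bidirectional stepwise search from
the TF-only model, minimizing $\mathrm{AIC} = n \log(\mathrm{RSS}/n) +
2k$ with the intercept and TF term always retained.  Bidirectional search
subsumes both forward and backward readings of "stepwise"; constant AIC
terms are omitted consistently, so comparisons are valid.  The final
model is refit and returned as a classed object with `print`, `summary`,
`coef`, `predict` and `residuals` methods.

```{r knockdown-example}
universe <- sprintf("g%04d", 1:1500)
set.seed(4)
mt <- target_map(setNames(lapply(1:8, function(i) sample(universe, 150)),
                          sprintf("mir%03d", 1:8)), "MIRNA")
kd <- gen_knockdown(sample(universe, 400), mt, a_tf = -0.8,
                    a_mir = c(mir002 = 0.6, mir005 = -0.7),
                    c = 0.1, noise_sd = 0.3, seed = 5, genes = universe)
select_mirna_regulators(kd$data)
```

## Host genes and clustering

Some miRNAs sit in introns of protein-coding host genes.
`shared_crm_hostgenes` reports, per hosted miRNA, the CRMs that both
regulate the miRNA (a CRM→miRNA edge) and target its host gene — the
configuration in which one CRM can simultaneously activate a gene and
the miRNA inside it, closing a feed-forward loop.

`cluster_genes` performs agglomerative clustering of module genes under
the distance $d = 1 - r$ ($d \in [0, 2]$).  Average linkage is the
default — a robust middle ground for correlation distances, with complete
and single linkage available; the linkage convention for this analysis
is not standardized.  Undefined correlations are assigned the maximal
distance 2 with a warning, keeping the matrix complete without
fabricating similarity.  Dendrograms export as Newick text.

## The synthetic-data generator

The generator is first-class, tested code; its defaults are the study
conditions of the test suite.

* **Expression** (`gen_expression`): planted blocks are equicorrelated
  Gaussians — genes in a block share a latent factor so every pair has
  correlation $\rho$; remaining genes are independent.  The pipeline
  consumes only pairwise Pearson correlations, so this is the minimal
  sufficient co-expression structure.  Default measurement noise
  (sd 0.1 on unit-variance profiles) attenuates a planted $\rho = 0.9$
  to about 0.89.  Optional extra probesets per gene carry larger noise
  (sd 0.5) to exercise the max-over-probesets rule.
* **Target maps** (`gen_target_maps`): miRNA out-degrees follow a
  discretized power law by default, because the degree-matched background
  of the significance test is only meaningful when the target-number
  distribution is non-trivial; overlap directives plant a shared gene set
  into chosen (CRM, miRNA) pairs so their module is genuinely coherent.
* **PWMs** (`gen_pwms`): per-column Dirichlet draws with one dominant
  base (expected probability about 0.97, roughly 1.7 bits per position).
  This matches curated TF motif collections, which are built from small
  aligned site sets and are close to consensus; it also makes planted
  sites reliably detectable at the stringent 99.99% cutoff, which is the
  regime the edge-prediction analysis assumes.
* **Upstream sequences** (`gen_upstream_sequences`): i.i.d. background
  with one site per planted motif, sampled from the PWM (consensus
  optional) and placed without overlap inside one cluster window; exact
  positions and strands are recorded.
* **Knockdown** (`gen_knockdown`) and **networks** (`gen_network`)
  follow the model equations above; planted FFLs occupy fresh node
  triples so the planted count is exactly the FFL census at zero
  background probability.

What the generator does **not** emulate: microarray normalization
artifacts, realistic genomic sequence composition (CpG islands, repeats),
correlated motif co-occurrence in background sequence, or miRNA target
prediction error.  Passing tests therefore demonstrate correctness of the
computations and calibration of the statistics under the stated models —
not robustness to the biases of real annotation pipelines.

## Numerical choices and degenerate inputs

* Pearson correlations via `stats::cor`; zero-variance probesets give
  undefined (skipped) pairs, never exceptions.
* Empirical quantiles are type-7 (the `stats::quantile` default).
* TRANSFAC-style matrices may hold counts or frequencies; columns are
  normalized by their own sums, and all-zero columns are rejected.
* Ties in the randomization test count toward the numerator ("same or
  higher").
* Stepwise ties are broken by candidate order; selection is invariant to
  gene row order.
* Empty module tables, empty networks and empty edge sets are valid
  results, not errors; parsers reject malformed input with line-numbered
  messages rather than truncating.

## Problem sizes

The bundled pipeline run uses 300 genes x 40 samples, 8 CRMs, 6 miRNAs,
3 planted blocks, 100-rep significance testing, a $10^6$-base scan
calibration and 100 random networks — small enough to run end to end in
well under a minute while exercising every stage; the test suite uses
comparable sizes (up to 3000 genes for the knockdown power study and
$10^6$ scan windows for cutoff calibration).

## Known limitations

* The pattern census covers at most three nodes; larger patterns are out
  of scope.
* Background 2 redraw handling (degenerate intersections) has no
  published reference behavior; the redraw-then-penalize rule is this
  package's documented choice.
* The scan assumes upstream sequences arrive as FASTA; genome extraction
  and de novo CRM discovery are out of scope.
* P-values are empirical only; no analytic approximations are provided.
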