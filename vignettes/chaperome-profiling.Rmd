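---
title: "Profiling chaperome deregulation: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Profiling chaperome deregulation: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chaperoscope)
```

chaperoscope quantifies how the human chaperome — the ensemble of chaperone
and co-chaperone genes organised into functional families (sHSP, HSP40,
HSP70, HSP90, HSP60, HSP100, PFD, TPR, ER, MITO) — shifts between tumor and
matched normal tissue in multi-cohort RNA-seq compendia, and places those
shifts in the context of the chaperome's physical interaction network. This
vignette explains the statistical machinery, the parameters that matter, and
the design decisions taken where the methods left room for choice.

## Expression preprocessing

Raw counts are transformed to log2 counts per million with the standard
small-count offsets,

$$\mathrm{logCPM}(g, s) = \log_2 \frac{(c_{gs} + 0.5)\cdot 10^6}{L_s + 1},$$

where $L_s$ is the library size (column sum). Precision weights are not
estimated: nothing downstream uses them, only the transformed matrix.
Expression is then centered gene-wise. The default centering scope is
**per tissue**, because both the gene-set test and the Meta-PCA fit operate
tissue-wise; global centering is available by flag for users who want
cross-cohort comparability of absolute levels. Genes with all-zero counts in
a tissue are retained (the offsets keep logCPM defined), so gene-set
membership is stable across cohorts. Only tissues providing both a tumor and
a normal arm (configurable minimum per arm) enter any analysis.

## Gene-set analysis and the signed ∆GSA score

The gene-level statistic is the pooled-variance two-sample t (tumor minus
normal; a Welch variant is available by flag). Genes with zero variance in
both arms score 0. The set-level statistic is **maxmean**: the mean of the
positive or of the negative gene scores in the set, whichever is larger in
absolute value; exact ties return the positive value (a documented,
measure-zero tie-break).

Significance comes from permuting condition labels (default 100
permutations; with tiny cohorts all distinct label assignments are
enumerated instead), combined with **restandardization**: the set statistic
is standardized by the mean and standard deviation of maxmean over random
gene sets of the same size drawn from all scored genes. This makes the test
*competitive* — a set is only called up if it stands out against what
arbitrary same-size sets do — which also means a global shift affecting all
genes is, by construction, invisible to it.

One numerical choice deserves emphasis. The random-set catalog can either be
pooled across permutations or computed per score vector. Pooling (one draw
per permutation) standardizes the observed and permuted statistics
*asymmetrically*, and in simulations this inflates the type-I error at
$\alpha = 0.05$ to roughly 0.08. chaperoscope therefore standardizes
**symmetrically**: the observed statistic and each permuted statistic are
standardized by a catalog of `n_draws_per_perm` (default 10) random sets
evaluated on their own score vector. The standardized values are then
exchangeable under the null, and the measured rejection rate matches the
nominal level. Permutations and catalog draws come from seed-derived
streams independent of the data labels, which makes label-swap antisymmetry
exact: exchanging the tumor/normal labels negates every score and swaps
$p_\mathrm{up}$ with $p_\mathrm{down}$.

P values use the add-one estimator $p = (1 + \#\{\tilde s_b \ge \tilde
s_\mathrm{obs}\})/(B + 1)$, avoiding impossible zeros; the floor is
$1/(B+1)$. The signed summary is

$$\Delta\mathrm{GSA} = (1 - p_\mathrm{up}) - (1 - p_\mathrm{down})
 = p_\mathrm{down} - p_\mathrm{up} \in [-1, +1],$$

with +1 meaning upregulation at the permutation floor. Note a structural
consequence: because $p_\mathrm{up} + p_\mathrm{down} \approx 1$, a *null*
set's ∆GSA is approximately uniform on $[-1, 1]$ — individual null values
of ±0.8 are unremarkable; it is the mean over tissues and the saturation
points that carry signal.

For the chaperome-versus-genome comparison, the package draws (by default)
100 random size-matched gene sets from the non-chaperome genome and uses
each background set's permutation distribution as the null reference for
the observed chaperome statistic, averaging the resulting signed scores
over draws. Background draws never contain chaperome genes.

## Meta-PCA and M-scores

Meta-PCA condenses each family's expression into a single per-sample score
while letting every tissue cohort contribute equally, regardless of its
sample count:

1. **Per-tissue PC1.** For family $x$ and tissue $t$, PC1 of the
   per-gene-centered samples-by-genes matrix gives a unit-norm loading
   vector $W_x^t$ (PCA on the covariance; genes are not scaled to unit
   variance since logCPM values share a scale — a `scale_genes` flag is
   available). Family genes missing from a cohort are masked.
2. **Separation filter.** PC1 captures the dominant variance, which need
   not be the disease axis. A Student t test on the PC1 sample scores keeps
   only tissues where tumor and normal separate at $p \le 10^{-4}$.
3. **Sign alignment and averaging.** PCA signs are arbitrary, so the
   retained loading vectors are made uni-directed: the tissue with the
   smallest separation p value serves as reference, and any vector with a
   negative dot product against it is flipped. The *global* orientation of
   the reference is anchored so that its entry sum is positive. This makes
   the M-score co-move with expression — a family whose genes rise in
   tumors gains score, a downregulated family loses score — rather than
   forcing every family's tumor scores upward, which would erase genuine
   downregulation (the sHSP signature). If the entry sum is essentially
   zero the fallback anchors on the tumor-minus-normal mean score in the
   reference tissue. The universal weight vector $W_x$ is the per-gene mean
   of the aligned loadings (denominators count only tissues where the gene
   was present) renormalized to unit norm, so M-score scales stay
   comparable across families with different numbers of contributing
   tissues.

The M-score of a sample is then $M_x = W_x \cdot G_x$ over centered
expression; families with no retained tissue carry no weight vector and are
absent downstream. Held-out validation (Step 3′) fits a random-forest
classifier on the per-family M-scores with a stratified 80/20
train/test split and reports overall and per-tissue held-out accuracy.

Polar summaries report, per family and arm, the sample mean and the
empirical 5%/95% quantiles (type-7 interpolation) — the mean lines and 90%
halos of the polar plots. M-scores are plotted raw (no additional
z-scoring).

## Differential expression and clustering

Per-gene testing uses the two-group linear model with empirical-Bayes
variance moderation (limma) by default; `moderation = "off"` gives the
ordinary pooled t, which the tests use as an independent cross-check.
Multiple testing is Benjamini–Hochberg; the per-subset summary is the
fraction of set genes with adjusted $p < 0.05$. Gene-level signed
significance is $\mathrm{sign}(\mathrm{effect})\cdot(1 - p)$.

Heatmap ordering uses Euclidean hierarchical clustering; the linkage is not
dictated by the underlying methods, so the default is average linkage with
complete and Ward available. Cancer-group separation is summarised by
best-of-50 k-means with the median silhouette width. Cluster stability uses
*ordinary* bootstrap support over feature columns — the fraction of
resamples reproducing each cluster's membership exactly. Multiscale (AU)
bootstrap p values are deliberately out of scope; ordinary support answers
the same qualitative question at a fraction of the machinery.

## Interactome curation

Evidence records (MITAB-like: node pair, PSI-MI detection-method id, PMID,
source database, interaction type) are mapped from UniProt to Entrez,
restricted to PSI-MI 'physical association' (MI:0915; descendants
includable by flag) and to pairs inside the chaperome universe.
Self-interactions are kept — homodimers are real physical edges — with a
`drop_self` option.

Databases annotate the same experiment at different depths of the PSI-MI
vocabulary, so method multiplicity is resolved by **up-propagation**: PSI-MI
is formally a DAG, a term's level is its minimum depth from the root, and a
deeper term is walked root-ward along a minimum-depth path (ties broken by
term id) to the shallower term's level. Two methods at the same level with
different ids count as different evidence; a term that lands on the other
term after up-propagation is a refinement of the same experiment class and
is dropped. The surviving set are the *effective methods*. A method is
*binary* when its lineage meets a configurable branch set (default: the
protein complementation assay branch MI:0090, which contains the two-hybrid
methods); the curation criteria mark methods "(binary)" without enumerating
ids, so this is deliberately configuration, not code.

Each unordered node pair is classified into one of eight curation levels
from (effective method count, binary membership, PMID count), and the
nested tiers follow: SE (every curated edge), ME (more than one PMID *or*
more than one effective method), MM (more than one effective method). Tier
nesting MM ⊆ ME ⊆ SE is structural.

The expert-curated chaperome gene lists and edge tables circulate as
spreadsheets and are not redistributed here. chaperoscope ships
deterministic **synthetic stand-ins** (`inst/extdata/*_synthetic.*`,
`synthetic_interactome_corpus()`) that reproduce their documented
structure — 332 genes = 88 chaperones (50 ATP-dependent + 38
ATP-independent) + 244 co-chaperones in 10 families; 43 proteasome genes;
curated tiers of 666 edges/220 nodes (SE), 222/128 (ME), 132/96 (MM) — with
synthetic identifiers. The evidence corpus is built so that the tier
composition emerges from raw records only after correct level-matched
deduplication, exercising every curation level class including nested
annotations that must collapse.

## Meta-networks and topographic surfaces

Collapsing the gene-level network onto families gives meta-nodes (size =
family member count among network nodes; intra-family edges recorded on the
node, not drawn as self-loops) and meta-edges weighted by the number of
bundled inter-family edges. Edge conservation — meta-edge weights plus
intra-family counts equal the source edge count — is asserted at
construction. Families without edges remain as isolated meta-nodes.

The layout is Kamada–Kawai with target distances set to the inverse
meta-edge weight (strong coupling pulls families together; the weight →
distance mapping is a presentation choice, not part of the statistics), and
a deterministic circular initialisation so coordinates reproduce without
reference to RNG state. The topographic surface is a Gaussian radial-basis
mixture over the layout,

$$z(x, y) = \sum_f v_f \exp\!\big(-\lVert (x,y)-(x_f,y_f)\rVert^2 / 2b^2\big),$$

linear in the family values $v_f$ (M-score shifts or signed set scores),
with bandwidth defaulting to 0.25 × the median inter-node distance. The
surface interpolation and colour scales are presentation detail; the
symmetric colour scale about zero keeps up- and downregulation visually
comparable.

## The synthetic cohort generator

`simulate_cohort()` draws negative-binomial counts (gene-level dispersion,
default size 10 — typical RNA-seq overdispersion) around log-uniform
per-gene baselines, with per-sample library-size factors, mild
per-(gene, tissue) baseline wobble, and programmed family effects: tumor
samples of tissue $t$ shift every gene of family $f$ by
$\delta(f, t)$ log2 units (optional per-gene jitter tests the robustness of
PC1 extraction). The reference conditions are 5 tissues × 30+30 samples,
10 families × 12 genes with $\delta \in \{-2, -1, 0, +1, +2\}$ (two
families per level), and 4,880 null background genes.

The background size is a deliberate realism choice: family genes make up
roughly 2% of the simulated transcriptome, mirroring the chaperome's small
share of the genome. With a much smaller background, strong programmed
effects measurably shift tumor library sizes and the logCPM normalisation
leaks a composition artifact into *null* genes — strong enough, when
aggregated by PC1 over a family, to defeat the $10^{-4}$ separation filter.
At the chosen proportions the artifact is below detectability, which is the
regime real chaperome data occupy.

What the generator does *not* emulate: tumor purity and subclonal
heterogeneity, batch effects, gene–gene correlation beyond the shared
family effect, and microarray noise models. Tests passing on these cohorts
demonstrate that the algorithms recover the structure they are designed
for; they do not certify performance under confounding the generator never
produces.

`simulate_ppi_corpus()` draws per-pair evidence profiles whose expected
SE/ME/MM membership is known analytically from the profile definitions, so
tier construction can be checked against generator bookkeeping exactly.
`simulate_mi_ontology()` builds balanced term trees with an optional
multi-parent cross-link for the DAG up-propagation rule.

## Problem sizes and numerical conventions

The automated checks run the reference simulation at 20 seeds for effect
recovery (rank correlation between programmed $\delta$ and M-score shift),
200 null repeats at 100 permutations for calibration, 100 null tissues for
the Step-2 specificity bound, and ≥1000 random instances against
brute-force oracles for maxmean, Benjamini–Hochberg, silhouette widths and
meta-network collapse — sizes chosen so the full suite completes in about a
minute while keeping Monte-Carlo error well inside the asserted bands.
Other conventions: all RNG flows from one user seed through fixed derived
streams (permutations, catalog draws, background sampling, splits are
mutually independent); degenerate cases (zero-variance genes, single-sample
scopes, empty arms, orphan ontology terms, constant matrices) are either
defined by rule or rejected with named errors, never silently propagated.

## Known limitations

- The family partition ("level 1" here) is taken from the shipped table's
  shallowest fully-labelled column; circulating chaperome annotations label
  the 10-family partition inconsistently as level 1 or level 2, so the
  level is a parameter rather than a constant.
- The competitive gene-set test cannot flag a shift common to the whole
  transcriptome, and the signed score of a single null set is nearly
  uniform on $[-1, 1]$; interpretation should rest on group means and
  replication across tissues.
- The sign-alignment anchor (positive entry sum) assumes the PC1 loadings
  of a deregulated family are predominantly single-signed; a family whose
  disease axis is a true contrast (half up, half down) would be oriented by
  the fallback rule instead.
- Bootstrap support values are not p values; they are resampling
  frequencies, and the multiscale correction that would turn them into
  approximately unbiased p values is intentionally not implemented.
- The shipped ontology/interactome fixtures are synthetic stand-ins with
  the documented structure, not the curated gene lists themselves; analyses
  of real data should load the user's own tables through the same
  interfaces.
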