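---
title: "Reconstructing clonal evolution from serial samples: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reconstructing clonal evolution from serial samples}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cloneforest)
```

# Scope

cloneforest turns longitudinal tumour/germline read counts from
myelodysplastic syndrome (MDS) patients — typically 2–8 bone-marrow or
peripheral-blood samples over 2.5–11 years, genotyped by targeted
amplicon sequencing near 10,000× on top of ~110× whole-exome discovery
— into a quantitative clonal history: which mutations travel together
(clones), how the clones nest (tree or forest), whether genetically
unrelated clones are present, and how each clone's share of the marrow
changes over time. Alignment and primary variant calling are upstream
of the package; the inputs are per-variant alt/ref counts, a sample
sheet, copy-number segments and, optionally, single-colony VAF tables.

# From VAF to cancer cell fraction

The quantity that is actually clustered and constrained is the cancer
cell fraction (CCF), not the raw variant allele frequency (VAF). The
two are linked by the standard two-population mixture: if a fraction
$c$ of nucleated cells is tumour with total copy number $CN_t$ at the
locus, of which $m$ copies carry the variant, and normal cells carry
$n_p$ copies (1 on the male X/Y, else 2), then

$$v = \frac{m\,c}{n_p(1-c) + CN_t\,c}, \qquad
  c = \frac{n_p\,v}{m - v\,(CN_t - n_p)}.$$

For a heterozygous diploid mutation this is the usual doubling rule
$c = 2v$. The same formula covers hemizygous deletions such as del(5q)
($CN_t = 1$), monosomies, trisomies, copy-neutral LOH ($CN_t = 2$,
$m \in \{1, 2\}$) and male X-linked loci ($n_p = 1$). Inversion is
exact; raw values above 1 are clipped and flagged when they exceed
$1 + 3\,se$.

Uncertainty is propagated by the delta method from the binomial VAF
standard error $\sqrt{v(1-v)/\text{depth}}$; for the het-diploid case
the map is linear and $se(c) = 2\,se(v)$.

**Multiplicity under CN-LOH.** Whether a mutation in a copy-neutral
LOH segment sits on the duplicated haplotype ($m = 2$) or on the
remaining single copy ($m = 1$) is not observable from the segment
alone. When read counts and a candidate CCF (from co-clustered
mutations) are available, the multiplicity maximising the binomial
likelihood is chosen; ties and missing evidence default to $m = 2$,
the mutation-before-LOH order that dominates somatic data.

**Detection floor.** All variants with VAF ≥ 0.2% enter the
reconstruction; entries below that floor are recorded as explicit CCF
zeros (not missing data) so that a mutation absent early and present
late cannot silently merge with a founder cluster. A censored entry's
uncertainty is $\sqrt{se_\text{binom}^2 + (c_\text{floor}/2)^2}$: a
value known only to be *below* the floor is uncertain on the scale of
the floor itself, and using the binomial error alone would make two
censored-or-barely-detected measurements look spuriously
distinguishable.

# Clustering trajectories

Two mutations belong to the same clone only if their corrected VAFs
agree at every timepoint. The distance is therefore a worst-sample z
statistic,

$$d_{ij} = \max_t \frac{|c_{it} - c_{jt}|}{\sqrt{se_{it}^2 + se_{jt}^2}},$$

fed into average-linkage agglomeration that stops when the smallest
inter-cluster linkage reaches $z^\ast = 3$ pooled standard errors — the
conventional bound for "statistically indistinguishable". Both the
metric and $z^\ast$ are exposed in `cluster_mutations()`.

A consolidation pass then merges clusters whose precision-weighted
*centroid* trajectories are still within $z^\ast$. This step exists
because the stop rule applies a per-comparison convention to a maximum
over samples and over many mutation pairs: at 10,000× a patient
contributes on the order of $10^4$ binomial draws, so isolated ≥3σ
count fluctuations are expected, and without consolidation they strand
single mutations in spurious singleton clusters. The centroid is the
actual estimate of the clone trajectory and averages such noise out;
genuinely distinct clones (separated by ≥ 0.15 CCF anywhere, i.e.
tens of standard errors at this depth) are unaffected.

Clusters are reported in descending mean-CCF order, so cluster 1 is
the putative founding clone.

# Building the clone forest

Every assignment of a parent (or root status) to each cluster is
enumerated exhaustively — determinism and auditability are preferred
over stochastic search for a reconstruction artifact; the enumeration
is capped at 12 clusters, far above the ≤8 clusters seen in practice.
A forest is admissible when, within tolerance $\varepsilon$:

* **pigeonhole rule** — a child's CCF never exceeds its parent's;
* **sum rule** — children's CCFs cannot jointly exceed their parent,
  and root CCFs cannot jointly exceed 1;
* **temporal precedence** — a parent is first detected no later than
  its child;
* **colony constraints** — mutation pairs proven mutually exclusive by
  single-colony genotypes may not share a root path, and evidenced
  ancestor orders may not be inverted.

$\varepsilon = \max(0.05,\ 2 \cdot \text{pooled centroid } se)$ per
comparison: the floor absorbs biological noise (sampling site, cell
composition) that binomial errors at 10,000× cannot represent, and the
$se$ term lets sparse WES-only timepoints relax the constraint.

Among admissible forests the winner minimises a parsimony score:
squared positive sum-rule slack in pooled-$se$ units (zero for strictly
admissible forests), plus $\lambda = 1$ per root beyond the first and
$\mu = 0.25$ per branching node; ties prefer fewer roots, then fewer
branch nodes, then the lexicographically smallest parent vector. When
*no* forest is admissible the package never fails silently: it relaxes
only the CCF rules (colony evidence and temporal order are hard), scores
total violation, and returns the least-violating forest together with a
violation table — mirroring the manual-inspection workflow such data
ultimately require.

**Unrelated clones.** Non-primary roots are labelled unrelated clones
with an evidence grade: *colony-proven* (an exclusive mutation pair
straddles the trees) outranks *pigeonhole* (root CCFs sum above 1
somewhere, so the clones cannot nest) outranks *topology-only* (the
root merely could not be attached).

**Colony genotyping.** A single-progenitor CFU-GEMM colony is
heterozygous for every founder mutation, so presence requires VAF
> 40% and absence VAF < 5%; anything between flags a possibly mixed
colony, which is excluded from constraints. Pairwise co-occurrence
patterns over unambiguous colonies yield nesting (1,1 with 1,0),
exclusivity (1,0 and 0,1 without 1,1) or a perfect-phylogeny violation
(all three patterns), which is reported rather than resolved.

# The synthetic cohort generator

`simulate_patient()` produces ground-truthed patients that emulate the
statistical structure of a longitudinal MDS study: ~8–27 somatic
mutations (median ~17) on 1–8 clones, 0–6 of them drivers drawn from a
bundled myeloid gene panel; serial samples (default five over ~5.5
years) at Poisson-distributed depth around 10,000× (targeted) or 110×
(WES); symmetric per-alt-base sequencing error of 5×10⁻⁴
(Ion-Torrent-like; the platform error rate is configurable);
del(5q)/monosomy 7/CN-LOH segment scenarios; treatment windows that
multiply a chosen root's tree by a suppression factor (lenalidomide-like
responses down to fractions of a percent); germline controls with
optional tumour contamination; and single-colony VAF tables at a fixed
colony depth of 200 reads.

**Growth model.** Clone growth uses competitive replacement: each
clone has fitness weight $w_i(t) = e^{r_i (t - t_{0i})}$ and occupies a
fraction $L_i\,w_i / (1 + \sum_j w_j)$ of its parent, where the sum
runs over its sibling group. A lone clone follows an ordinary logistic
curve (two interpretable parameters: rate and midpoint); competing
siblings displace one another. Competing lineages exchange dominance at
a crossover time drawn inside the sampling window, with at least one
sample after the crossover. This encodes two facts about observed
clonal evolution: a subclone seen rising against an established
competitor must carry a fitness advantage, and serial studies resolve
branching precisely because divergent subclones visibly trade places
within follow-up. An earlier design with independent logistic curves
per sibling was abandoned: non-crossing siblings are *in principle*
indistinguishable from a nested chain under the pigeonhole/sum rules,
so ground truth in such draws is unknowable to any reconstruction
method — a property of the simulation, not of the biology being
emulated.

Colonies are sampled at the timepoint where the root populations
coexist best (the sample maximising the minimum root-tree CCF),
emulating the investigator's choice to genotype colonies when a rising
clone coexists with residual disease.

The generator does **not** emulate: overdispersed (non-binomial)
sequencing noise, mapping artefacts, sample swaps, subclonal
copy-number states (CN events apply to whole clones), spatial
heterogeneity between marrow sites, or germline CNV noise in the
segment tables. A green end-to-end test therefore establishes that the
pipeline recovers the truth under ideal binomial noise at the study's
depths and separations — not robustness to artefacts outside this
noise model.

# Numerical and degenerate-input choices

* Boundary inclusivity follows the rule texts exactly: p ≤ 0.001,
  VAF ≥ 0.07, VAF ≥ 0.2%, difference ≥ 5 percentage points, colony
  present > 40%, absent < 5%, CNA > 5 Mb, CN-LOH > 10 Mb.
* "5% difference" is 5 percentage points of VAF, not a ratio.
* The Fisher test is one-sided (tumour-enriched); a two-sided variant
  is exposed but is not the filtering default.
* A tie between the variant base and another non-reference base still
  counts as second-highest (the call stands, flagged as a tie); a
  variant count above the reference trivially passes the ranking rule.
* Clustering and enumeration are deterministic: sorted mutation ids,
  documented tie-breaks, no randomised initialisation.
* Empty inputs (zero mutations, zero-depth samples, < 2 FISH controls,
  no unambiguous colony) raise typed errors or return empty structures
  as documented, never NA-laden results.

# Known limitations

* **Flat-attachment ambiguity.** When a grandchild clone's CCF fits
  under both its true parent and the grandparent at every timepoint,
  the admissible set contains both attachments and the parsimony score
  prefers the flatter tree (fewer branching nodes). On simulated
  cohorts this costs roughly a tenth of exact-topology recoveries while
  leaving the pattern classification (linear vs branching) intact. The
  data contain a soft signal the score ignores — the child's collapse
  co-occurring with its true parent's collapse — and a likelihood-based
  score over fraction-within-parent trajectories would be the natural
  extension.
* Tumour purity is not modelled separately from CCF: the CCF is the
  fraction of all nucleated cells, matching marrow-population
  percentages reported in such studies.
* The 0.07 WES VAF floor is interpreted as "in at least one tumour
  sample" (configurable to per-sample), since serial designs would
  otherwise discard every late-arising subclone.
* Exhaustive enumeration is exponential in cluster count; the cap of
  12 keeps worst cases tractable but pathological inputs with many
  near-identical clusters should be pre-merged (raise `z_threshold`).
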