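---
title: "Methods: models, statistics and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, statistics and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The assay this package models

A randomized double-stranded DNA library — 76-bp ligands carrying a 30-bp
uniform random core between fixed adaptors — is incubated with a nuclear
extract. Ligands bound by the transcription factors (TFs) present and
active in that extract are separated, amplified, and carried into the next
round; after 3–5 rounds the library is dominated by sequences the active
TFs prefer. Sequencing the enriched library and comparing it against
controls reveals the *active cistrome*: the set of cis-regulatory elements
(CREs) recognized by the TFs of that tissue, without antibodies and
without prior knowledge of which TFs are present.

`seaati` implements the computational half of such an experiment —
pre-processing, signal detection, motif discovery and curation, dimer
analysis — plus the genomic context analyses (open-chromatin enrichment,
Tn5 footprints, expression association) and a simulator that generates
fully ground-truthed synthetic experiments so every claim in the pipeline
can be tested at desk scale.

# Signal detection by mutual information

A TF bound to a ligand contacts two nearby 3-bp patches, so an enriched
library shows statistical dependence between the 3-mer distributions at
close position pairs. For positions $p_1, p_2$ (non-overlapping 3-bp
windows) let $P(x,y)$ be the joint probability of observing 3-mers $x$ at
$p_1$ and $y$ at $p_2$, with marginals $P_1, P_2$. The pointwise
contribution of a pair is

$$c(x,y) = P(x,y)\,\log_2 \frac{P(x,y)}{P_1(x)\,P_2(y)}.$$

* **E-MI** sums the ten largest contributions — sensitive to any strong
  binding mode while robust to the noise of the 4 086 other cells.
* **D-MI** sums $c$ over the 128 pairs with $y = x$ or
  $y = \mathrm{revcomp}(x)$ — exactly the cells where head-to-tail or
  head-to-head *dimeric* CREs deposit their signal.
* `full_mi()` (the complete sum) is kept as the analytic oracle: it is the
  plug-in MI estimate and bounds E-MI from above.

Numerical conventions: $0 \log 0 = 0$; no pseudocounts inside MI (a
pseudocount biases the null upward, which would inflate the triangle of a
signal-free library); the plug-in estimator is used without small-sample
correction since all uses are comparative. "Most enriched pairs" is read
as *largest contribution*; ranking by the ratio $P/(P_1P_2)$ instead is
available (`emi(..., ranking = "ratio")`) but is dominated by rare cells.

# Motif discovery

Discovery is seed-and-extend in the style of randomized-library motif
callers:

1. **Seeds.** For k = 8, 9, 10, k-mers are counted on the sequenced strand
   and pooled with their reverse complements under the lexicographically
   smaller representative. A k-mer is a seed iff its count is at least the
   local-max cutoff (40) and *strictly* greater than every neighbour's
   count. The neighbourhood is all Hamming-1 substitutions plus
   single-base left/right shifts. This is a deliberate simplification of
   the Huddinge-distance neighbourhood of the original autoseed program;
   it preserves the property that matters and is tested: planted k-mer
   pairs at Hamming distance ≥ 2 yield two seeds, distance 1 collapses to
   one. Ties disqualify both k-mers, which prevents duplicated
   near-identical models.
2. **Multinomial-1 PFMs.** Column $j$ of the PFM counts base frequencies
   over read windows (both strands) matching the seed at every position
   *except* $j$; windows matching the seed exactly contribute to every
   column. Flank columns (2 per side by default) are counted from exact
   windows only and trimmed back while a terminal flank column carries
   < 0.1 bits — the extension rule is not specified by the assay
   literature, so it is a documented package choice.
3. **Information content.** Per column,
   $IC = \sum_N p(N) \log_2 (p(N)/0.25)$; total IC sums columns, per-base
   IC divides by width.

No background-round subtraction is applied to PFM counts by default (the
upstream protocol is silent on it); shuffled-control subtraction exists
behind the activity analysis instead.

# Curation, deduplication, classification

Curation retains motifs with consensus IC < 1.8, total IC strictly inside
(2, 30), and per-base IC > 0.2 bits. "IC of the consensus" is implemented
as the mean per-position IC contributed by the consensus base,
$\frac1L \sum_j p_j(c_j)\log_2(p_j(c_j)/0.25)$ — the reading that makes
the filter do its stated job of removing homonucleotide runs (a run of
97 % A columns scores ≈ 1.9 and is rejected; a mixed-base motif of the
same total IC passes). Because the wording is genuinely ambiguous
(consensus IC vs per-base IC may have been bounds on one statistic), an
explicit homopolymer flag (≥ 90 % of consensus positions share a base) is
also reported, and both statistics are exposed.

Deduplication aligns every motif pair over all ungapped offsets and both
orientations, scoring the Pearson correlation of the overlapping PPM
cells (minimum overlap 4 columns — unspecified upstream, chosen here);
pairs with best r strictly above 0.90 are connected, and each connected
component keeps its highest-total-IC member.

Classification against a reference motif library was done *manually* in
the assay literature; this package substitutes transparent numeric
thresholds (reported: r ≥ 0.85; similar: 0.70 ≤ r < 0.85; otherwise
distinct, named `n_seaATId`). The thresholds are arguments, not claims.

# Dimeric binding landscapes

For a monomer core $C$ (default the W-box, `TTGAC`) with reverse
complement $R$, scanning the given strand left to right:

* `DR` (direct repeat): `C…C` — and `R…R`, which is the same arrangement
  seen from the other strand, canonicalized to DR;
* `IR` (inverted, head-to-head): `C…R`;
* `ER` (everted, tail-to-tail): `R…C`.

**Spacing is the number of bases strictly between the two cores**
(adjacent cores have spacing 0). This convention is stated prominently
because an off-by-one here silently shifts the whole landscape, and the
upstream description never fixes its origin. Overlapping cores are
excluded (fused-core motifs belong to motif discovery); a run of three
cores contributes all three pairs; landscapes are exactly invariant under
reverse-complementing the input, which is tested.

# Genome scanning and context

PWMs are $\log_2(\mathrm{PPM}/\mathrm{background})$, integer-scaled at
1000 units/bit (floored, so thresholds err conservative). The match
threshold at p-value $10^{-4}$ is **exact**: the null score distribution
is built by dynamic-programming convolution over columns and the
threshold is the smallest achievable score whose tail probability is at
most the p-value — verified against exhaustive enumeration of all $4^L$
sequences for widths ≤ 8. Coordinates are 0-based half-open (BED)
internally; GFF3 is converted on read.

Context statistics follow their plain definitions: THS enrichment is the
pseudocounted hit-density ratio inside/outside peak intervals; metagene
profiles rescale gene bodies to 2 kb with 1-kb actual-scale flanks (flank
width is a package choice, stated here); the expression contrast counts
hits within ±300 bp of TSSs of the top vs bottom 15 % of genes by TPM
(ties broken by gene id); TPM is
$10^6 (c_g/l_g)/\sum(c/l)$ and conserves $10^6$ exactly.

Footprint depth is *flank mean − core mean* of the aggregated per-base
cut profile (121-bp windows centered on CRE midpoints, minus-strand sites
flipped), minus the same quantity on a protein-free control profile —
residual footprints survive bias correction in real controls, and the
simulator reproduces that. Flank width 25 bp and core = motif width are
configuration, not claims. The bound/unbound split (site depth > control
mean + 1 SD) is an invented, documented rule standing in for TOBIAS's
internal thresholding. Tn5 sequence-bias correction is out of scope: the
package consumes corrected (or synthetic) cut tracks.

# The simulator: a stated world

Defaults state the simulated experiment once: 76-bp ligands, 30-bp
uniform random cores, 4 rounds (assay range 3–5), 20 % of molecules
recovered per round, PCR regrowth to constant library size (duplication
factor 5, i.e. `pcr_duplication_rate = 0.8`), monomeric occupancy
$\mathrm{plogis}(\beta(s - s_{max}))$ per window encounter and dimeric
per-occurrence occupancies from an orientation × spacing table; a read's
selection weight is $1-\prod(1-\mathrm{occ})$ over all its sites.

Two choices deserve emphasis:

* **Selection draws the bound pool with replacement.** A desk-scale
  library (10⁴–10⁵ molecules vs the real 10¹²) cannot hold enough
  distinct binders for without-replacement selection to express affinity
  differences across rounds; with-replacement sampling reproduces the
  concentration dynamics of amplify-and-reselect, so consensus sites
  out-compound 1-mismatch sites at the correct $(occ_1/occ_2)^{rounds}$
  rate. Survival weights are accumulated in log space so weak binders do
  not underflow to zero.
* **What a green test establishes.** The simulator emulates affinity
  selection, PCR duplication, planted genomic CREs, Poisson cut tracks
  with occupancy-dependent dips, and multiplicative CRE→expression
  coupling. It does not model sequencing error, TF competition for
  limiting protein, chemical potentials, or Tn5 sequence bias — so green
  end-to-end tests establish correctness of the *computational* pipeline
  on a faithful-but-idealized world, not biological completeness.

Dimeric-TF simulations in the tests use a 3-bp core: with a 5-bp core at
desk-scale n, essentially no random ligand carries a correctly spaced
pair, which is a library-complexity limit of the stated world, not of the
method.

Every stochastic operation takes a single integer seed and restores the
caller's RNG state; child streams are derived arithmetically, so whole
experiments are byte-reproducible.

# Known limitations

* The seed neighbourhood is substitution+shift, not Huddinge; gapped
  (spaced-dyad) seeds are not discovered — dimers surface through D-MI
  and the landscape instead.
* Curation thresholds for classification replace a manual step; their
  defaults are package choices.
* Desk-scale selection collapses library diversity after deduplication;
  headline counts of the original genome-scale study (41 curated motifs,
  15 distinct models, 45 WRKY dimers) are not reproducible without the
  original accession data and are out of scope by design.
* A mononucleotide per-read shuffle is the only control generator; a
  dinucleotide-preserving shuffle (Eulerian-path construction) was
  considered and deliberately omitted — for 30-bp uniform random cores
  the two controls are statistically indistinguishable at the statistics
  used here.
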