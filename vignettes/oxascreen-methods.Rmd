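---
title: "Methods: combinatorial amino-oxazole design and screening post-processing"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: combinatorial amino-oxazole design and screening post-processing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(oxascreen)
```

## The scientific problem

Bacterial acetyl-CoA carboxylase commits acetyl-CoA to fatty acid synthesis;
its biotin carboxylase (BC) component is a validated antibacterial target.
Amino-oxazole inhibitors occupy the ATP site of BC through a fixed
2-amino-oxazole-5-carboxamide anchor, but are potent only against
Gram-negative organisms. The redesign idea implemented here is to decorate
the anchor's amide nitrogen with two substituents, R1 and R2, drawn from a
large space of small organic fragments, and to select substituents whose
predicted binding is consistently good across BC isoforms from **both**
Gram-negative (*E. coli*, *H. influenzae*, *P. aeruginosa*,
*M. catarrhalis*) and Gram-positive (*E. faecalis*, *S. pneumoniae*,
*S. aureus*) species.

`oxascreen` covers every computational stage around the docking engine:
library construction, conservation profiling, post-docking consensus
analysis, chemotype enrichment, and contact profiling. Docking itself (and
conformer generation, homology modeling, force-field refinement) is out of
scope; a synthetic-data module emulates its outputs with known planted
structure, which is what makes the pipeline testable end to end.

## Library construction

Building blocks are retained if they have 6–12 heavy atoms (inclusive) and
deduplicated by a greedy leader pass in input order: a block is kept iff its
Tanimoto similarity to every previously kept block is < 0.95. The kept set
is therefore pairwise sub-threshold and the pass is idempotent. The same
leader logic at threshold 0.7 performs chemotype clustering for the
enrichment stage; leader methods are deterministic given input order, which
we prefer here to optimization-based clustering because reproducibility of
the cluster inventory matters more than marginal cluster quality.

Coupling attaches both blocks to the scaffold's amide nitrogen through any
hydrogenated C, N, O or S atom. Because both R-groups bond to the *same*
nitrogen, a block pair is unordered; enumeration walks unordered pairs and
attachment-point pairs (with a combined R-group budget of 18 heavy atoms),
and canonicalization plus the 0.95 leader dedupe removes coincident
products, e.g. the two attachments of a symmetric para-xylene block.
Combination numbers are assigned zero-based in deterministic enumeration
order and zero-padded to four digits; the identifier scheme is
`ao-<R1 id>-<R2 id>-<combination>` and the parser also accepts the
three-digit form. Self-pairing (R1 = R2) is allowed — the dibenzylamide
prototype inhibitor uses two identical benzyl groups.

Subsets are drawn by reservoir sampling (Algorithm R) over the deduplicated
compound stream, so the full library is never materialized; a fixed seed
reproduces the sample bit for bit.

Chemistry primitives are delegated to OpenBabel through ChemmineOB:
canonical SMILES, molecular weight, logP and TPSA, and the FP2 fingerprint —
hashed linear paths of length 1–7 folded to 1024 bits. A path-type
("topological") fingerprint is the conventional choice at the thresholds
used here, and we use FP2 at its native width rather than reimplementing a
hashed-path fingerprint beside it. Donor/acceptor counts are computed from
the package's own atom table with a stated convention: a donor is an N or O
bearing ≥ 1 H; an acceptor is an N or O excluding pyrrole-type aromatic NH
and amide nitrogens. Rule-of-five bounds are inclusive. logP is an additive
atom-contribution estimate used only for profiling, never as a ranked
quantity.

Two Tanimoto conventions are fixed deliberately: all-zero vs all-zero
fingerprints compare as 1.0 (featureless single-atom fragments are treated
as mutually redundant), and zero vs non-zero as 0.0.

## Conservation profiling

Per-position variability is the Shannon entropy
$H = -\sum_a p_a \log_2 p_a$ (bits; $0\log 0 = 0$), computed from
PSI-BLAST-style sequence profiles which this package consumes, not
generates. The bundled generic protein-like background composition
(Swiss-Prot-era residue frequencies) gives the reference maximum,
`r round(background_max_entropy(), 2)` bits; the exact value depends on the
database release, which is why the package treats values in the 4.14–4.19
band as equivalent. The 21 bundled ATP-site positions average
`r round(entropy_summary(load_binding_site_table()$entropy)$mean, 2)` bits —
strong conservation. The standard deviation uses the sample ($n-1$)
convention; with 21 positions the population convention differs in the
second decimal (0.766 vs 0.747), so only the mean is treated as a sharp
quantity.

Each position is classified as `conserved_all` (one residue everywhere),
`gram_specific` (uniform within each Gram group, different between groups —
positions 169, 204, 287, 437), or `variable`. The substitution lists from
the *E. coli* reference to any isoform (`mutated_binding_site()`) are the
recipe for building that isoform's structural model by side-chain
replacement.

## Post-docking consensus

A docking record is one compound × isoform row: anchor RMSD, predicted
affinity (ln *K*i), fitness and binding probabilities, and an interaction
energy. The anchor-consistency filter keeps compounds whose amino-oxazole
substructure stayed within 2 Å (inclusive) of the reference anchor pose in
*every* isoform; a compound missing any isoform fails. Treating the seven
docking calculations as independent, a joint pass fraction $f$ implies a
per-docking accuracy $p = f^{1/7}$; the campaign's printed counts
(1,246,716 of 8,898,942) give $p = 0.755$, reported as 76%.

Ranking uses SUM-rule data fusion, nested as in the screening protocol:
within each isoform the four score rankings are fused by summing ranks
(ties get average ranks; final ordering breaks ties by compound id), then
the per-isoform fused lists are fused again within a group (Gram-negative,
Gram-positive, all). Because fusion is rank-based it is invariant under any
strictly monotone transformation of the underlying scores — asserted by
test. An exact arithmetic identity follows from the nesting: the all-species
rank-sum equals the sum of the two group rank-sums compound by compound.

Score directions are configurable with documented defaults: affinity
(ln *K*i) lower-is-better; fitness, binding and the interaction energy
higher-is-better. The energy direction follows the bundled top-compound
table, where the best-ranked derivatives carry large positive energies.

Agreement between group rankings is the Pearson correlation of relative
ranks (i.e., Spearman on the fused lists). For a bivariate-normal latent
quality with correlation $\rho$, rank correlation converges to
$(6/\pi)\arcsin(\rho/2)$ — 0.786 at $\rho = 0.8$ — so recovery tests expect
values slightly below the planted $\rho$; the synthetic generator keeps
score noise small enough that this analytic value dominates.

## BEDROC enrichment of R-groups

For each block cluster and position (R1 or R2), the "actives" are the
compounds carrying a member block at exactly that position, located by
parsing the compound identifiers of a group's consensus ranking. Enrichment
is the BEDROC score with $\alpha = 20$ (the conventional early-recognition
setting; the weight parameter is exposed):

$$RIE = \frac{\sum_i e^{-\alpha r_i/N}}
{\tfrac{n}{N}\,\tfrac{1-e^{-\alpha}}{e^{\alpha/N}-1}},\qquad
BEDROC = RIE\,\frac{R_a \sinh(\alpha/2)}
{\cosh(\alpha/2)-\cosh(\alpha/2-\alpha R_a)}
+ \frac{1}{1-e^{\alpha(1-R_a)}}$$

with $R_a = n/N$. Degenerate cases ($n = 0$ or $n = N$) are errors, not
limit values. Discrete evaluation of this continuous-limit formula can land
a few parts in $10^9$ outside $[0,1]$ at extreme active placements, so the
returned score is clamped to the defined range. ΔBEDROC =
BEDROC(Gram-negative) − BEDROC(Gram-positive) per cluster and position,
flagged when |Δ| > 0.05.

One practical effect is worth knowing: boosting a planted cluster displaces
every other compound downward in the boosted group's ranking, so unplanted
clusters acquire a small *negative* ΔBEDROC in proportion to the planted
cluster's library share. With thousands of clusters each covering a tiny
share — the regime the generator emulates — the displacement is negligible;
the package's planted-recovery tests therefore plant a small (~3% share)
cluster.

## Contact classification

Contacts are protein–ligand atom pairs classified by heavy-atom distance
with fixed precedence hbond > halogen bond > aromatic > hydrophobic >
destabilizing, one class per qualifying pair. Default cutoffs (all
configurable): hydrogen bond donor–acceptor ≤ 3.5 Å with no angle term
(hydrogens are often absent from PDB inputs); ligand halogen to protein
N/O/S ≤ 3.6 Å; aromatic–aromatic ≤ 5.0 Å; apolar–apolar ≤ 4.5 Å;
hydrophilic–hydrophobic ≤ 4.0 Å. These are declared operating definitions
of this package, not reconstructions of any surface-based contact program;
the aromatic class is defined on atom pairs (both atoms aromatic) because
the contact record itself is atom–atom. Halogen contacts are a first-class
category here — consistent with treating them as weak hydrogen-bonding
interactions — rather than being folded into hydrophilic–hydrophobic
contacts.

Atom roles follow stated rules (donor = N/O with H; acceptor = N/O not
positively charged; hydrophobic = C/S bonded only to C/S/H; hydrophilic =
N/O; halogen = F/Cl/Br/I, excluded from hydrophobic). Protein atoms get
roles from a residue/atom-name dictionary of the standard amino acids;
ligand atoms from elements plus distance-guessed connectivity, with
aromaticity approximated as membership in a 5- or 6-ring of the bonded
graph. Classification depends only on inter-atomic distances and is
therefore invariant under rigid motions, which the tests verify with random
rotations.

Per-residue profiles report the fraction of compounds touching the residue
and the class composition of its contacts; halogen shares report each
residue's fraction of all halogen bonds.

## The synthetic-data generator

The generator produces every input the pipeline consumes, with planted
statistical structure:

* **Blocks** come from a bundled pool of 236 curated fragments in 40
  structural families (6–12 heavy atoms). Family mode decorates a base
  fragment with methyl/fluoro variants at successive attachment points,
  planting similarity structure for dedupe and clustering tests.
  Attachment points are capped at two per block — vendor fragments are
  typically coupled through one or two reactive sites — which also keeps
  enumeration tractable.
* **Docking records** follow a latent-quality model. Per compound, a shared
  standard-normal factor and group-specific factors combine as
  $q_g = \sqrt{\rho}\,z_{\text{common}} + \sqrt{1-\rho}\,z_g$, giving the
  two Gram groups correlation $\rho$ (default 0.8). Each isoform's four
  scores are monotone maps of its group quality plus Gaussian noise
  (sd 0.1 by default) oriented to honour the default score directions;
  anchor RMSDs make the pass event Bernoulli(0.755 by default),
  independent per isoform, mirroring the joint-probability model used for
  the accuracy estimate. Planted clusters add an effect (latent-quality
  units) to one group's quality for compounds carrying a member block at a
  stated position.
* **Profiles** draw Dirichlet(concentration × background) frequencies with
  optional near-point-mass conserved positions.
* **Complexes** place one protein probe per prescribed residue 15 Å apart
  along an axis with a ligand atom (or stacked six-ring, for the aromatic
  class) at a geometry realizing exactly the prescribed contact class under
  the default cutoffs and no others.

All generators thread explicit seeds and restore the caller's RNG state.
What passing tests show — and what they do not: the generator reproduces
the *statistical* structure of the screening stage (correlated consensus
ranks, independent anchor events, enrichment signals), not docking physics,
real protein geometry, or real vendor chemistry. Recovery of planted
parameters demonstrates the post-processing mathematics is right, not that
the docking scores themselves would be.

## Problem sizes and numerical choices

The test suite exercises the study's statistical checks at reduced but
statistically meaningful sizes, chosen as the package's own trade-off
between resolution and turnaround: anchor-pass recovery at
$n = 100{,}000 \times 7$ isoforms (tolerance ±0.01), rank-correlation
recovery at $n = 5{,}000$ (±0.03), planted-enrichment detection over 20
seeds at $n = 2{,}000$ (≥ 90% detection), BEDROC bounds over 10,000 random
instances, and a full synthetic end-to-end run at 2,000 compounds × 7
isoforms. Frequency-vector validation uses a $10^{-6}$ sum tolerance;
profile rows must sum to 1 within $10^{-9}$. Ties are always resolved
deterministically (average ranks inside fusion, id tie-breaks in final
orderings, lowest-id cluster representatives), so repeated runs are
byte-identical.

## Known limitations

* The published library counts (9,411 blocks; 127,751,751 derivatives;
  8,898,942 screened; 3,550 clusters) depend on 2014 vendor catalogues and
  an unspecified fingerprint, and are not reproducible from first
  principles; the package reproduces the *procedures* and checks them
  against oracles and planted structure instead.
* Docking, conformer ensembles, homology modeling and force-field
  refinement are consumed as data (real or synthetic), never computed.
* Contact classification is distance-only; no angular terms, solvent
  accessibility, or surface complementarity.
* The affinity sign convention (ln *K*i) is configurable because the
  bundled score table and a nanomolar-range reading of affinities admit
  either direction; no shipped result depends on it.
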