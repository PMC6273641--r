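---
title: "From gene cluster to compound: methods behind pksline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From gene cluster to compound: methods behind pksline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pksline)
```

`pksline` turns a set of modular type I polyketide synthase (PKS) protein
sequences, in declared gene order, into a predicted polyketide structure,
and provides the genome-level screens used to shortlist candidate clusters.
This vignette explains the model each stage implements, the parameters that
matter, what the synthetic-data generator does and does not emulate, and the
design decisions taken where the design was genuinely open.

## Domain annotation by anchored motif scanning

Professional domain annotation normally runs profile HMMs. `pksline`
deliberately replaces that with anchored regular-expression motifs, for two
reasons: the biological calls the pipeline needs (loading-KS vs condensing
KS, AT specificity residue, DH auxiliary-motif integrity, KR catalytic set
and stereotype) are all *motif-level* statements about a handful of
active-site residues, and a motif config keeps the package free of model
downloads and exactly reproducible. The config
(`inst/extdata/motif_config.yaml`, loaded by `default_motif_config()`) maps
each domain type to an ordered motif list; each motif carries a pattern, a
`block_offset` inside a canonical domain block, a `required` flag, and
optionally the offset of an extractable active-site residue. Exactly one
required motif per type is the *anchor*: every anchor match seeds a
candidate hit, the remaining motifs are searched inside the block implied by
the anchor position (± a `slack` of 30 residues), and the hit's extent is
the matched-motif span padded by a 10-residue `flank`.

Overlapping candidates are resolved deterministically: more matched required
motifs win, then the leftmost start, then a fixed domain-type priority
(KS > AT > DH > ER > KR > ACP > TE > Dock). A pattern matching more than
1000 sites on one protein is treated as a configuration error (a degenerate
pattern would otherwise silently distort resolution).

Two motif families are taken from the catalytic-site literature on modular
PKSs: the AT active-site serine motif, matched as `GHS.[GH]` so that the
noncanonical GHSQH variant still yields a specificity residue (with a
`noncanonical_fifth_residue` flag), and the DH motif set — catalytic
`HxxxGxxxxP` core plus the GYxYGPxF, LPFxW and Dxxx(Q/H) auxiliaries. The
KS/ACP/TE/Dock/ER anchors and the KR catalytic-triad and A/B fingerprint
regexes are package defaults standing in for profile-HMM coordinates; users
with HMMER-derived positions can substitute their own patterns in the YAML
without touching code.

**Activity rules.** A DH is called inactive when its core is absent or at
least two of the three auxiliary motifs fail (`max_aux_failures = 1`). The
threshold is the weakest rule consistent with two constraints: a domain
with an intact core but all auxiliaries altered must call inactive, while a
single benign substitution must not flip the call. It is exposed as an
argument because that boundary is genuinely uncertain. KR sequence-level
activity requires the catalytic-triad pattern; the A/B stereotype is read
from mutually exclusive fingerprints and reported `unknown` (flagged) when
both or neither match. These calls are pure functions of motif-match
booleans and are tested exhaustively over all combinations.

## Module segmentation

Modules are cut at each KS: a module runs from its KS to the residue before
the next KS on the same protein, proteins are concatenated in declared gene
order, and terminal docking domains attach to proteins, not modules. This
boundary rule is the one that reproduces every printed module group of the
worked example's architecture. Module 0 is the loading module when its KS
is decarboxylative (KSQ) or when it is first and carries no reductive
domains; ACP-first or AT-only loading architectures seen in other systems
are out of scope and surface as `malformed` flags rather than silent drops.
Docking-domain pairing is recorded but never used to reorder proteins —
gene order is authoritative, because dock compatibility rules are not
modeled. A thioesterase anywhere but the final module is kept and flagged
`internal_te`.

## Extender classification and compound reconciliation

The classification decision table is deliberately two-stage. Stage one is
pure motif evidence: x ∈ {L,V,I,F,A,M} → malonyl; x = Q → methylmalonyl;
any noncanonical secondary motif (anything other than HAFH or YASH) or a
flagged core motif → *provisional* ethylmalonyl with evidence
`motif_flagged`. HAFH is paired with malonyl and YASH with methylmalonyl —
the standard specificity-motif pairing; both are config-level choices. An
unrecognized x falls back to malonyl with an `unrecognized_x` flag (malonyl
being by far the most common extender), and a missing core motif yields
`unknown`, which downstream product prediction refuses to consume.

Stage two, `reconcile_with_compound()`, is the authoritative step for
flagged ATs: candidate units from methylmalonyl to hexylmalonyl (the
longest unit with literature precedent in polyene pathways) are enumerated
— jointly, if several ATs are flagged — the full product pipeline predicts
a mass for each combination, and the combination minimizing the absolute
error against the target mass wins, ties going to fewer total side-chain
carbons. The acceptance tolerance is 0.5 Da: adjacent candidates differ by
a CH2 (14.016 Da), so any tolerance below 7 Da discriminates perfectly and
0.5 merely absorbs rounding in target masses quoted at integer precision.
Reconciliation never touches an assignment whose evidence is plain `motif`,
and a failed reconciliation keeps the motif call with an `unreconciled`
flag. The presence of a crotonyl-CoA carboxylase/reductase gene — detected
by annotation-text substring match — is recorded as supporting evidence for
elongated units but never required, since the enzyme can act from outside
the cluster boundary.

## Product prediction on an atom/bond graph

Backbone numbering starts at the thioester carbonyl (C1); extension module
m of M contributes carbonyl 2(M−m)+1 and alpha 2(M−m)+2, and its beta
carbon 2(M−m)+3 is the previous unit's carbonyl. The three printed position
anchors of the worked example (C15 hydroxyl from module 7, C13 keto from
module 8, C2 side chain from module 13, with M = 13) pin this convention
uniquely. The beta state follows the reductive-domain rule: keto without an
active KR; hydroxyl with KR only; enoyl with KR+DH; methylene with
KR+DH+ER. `overrides` force individual domains on or off — the standard
recourse when the isolated compound shows that a sequence-intact domain is
skipped in vivo (the worked example's module-8 KR).

The product is a molecular graph over C and O with implicit
valence-completing hydrogens, so formula, monoisotopic mass (C 12.000,
H 1.0078250319, O 15.9949146), average mass (C 12.011, H 1.008, O 15.999)
and degrees of unsaturation all derive from one structure. Every feature
computation re-checks that formula-derived unsaturation equals rings plus
double bonds counted on the graph; a mismatch is a hard error, not a
warning. Tailoring steps:

* **Macrolactonization** (`auto`): C1 esterifies the most distal free
  β-hydroxyl; the released product is modeled as the lactone directly, and
  the free-acid form (`off`) differs by exactly H2O — a tested invariant.
  Ring member count is the esterified carbon index + 1 bridging oxygen.
* **Hemiketal** (`auto`): each retained keto Cj pairs with a free hydroxyl
  at j−4, then j+4, then j−3, then j+3 — 6-membered tetrahydropyran
  preferred over 5-membered, N-terminal partner preferred — and never spans
  the lactone oxygen. The transform conserves atoms exactly (keto O becomes
  the hemiketal hydroxyl, the attacking O becomes the ring ether), another
  tested invariant. Epoxide-mediated hydroxyl transfer and oxa-Michael
  pyran formation are alternative *mechanisms* for the same outcome; only
  the outcome is modeled.
* **Hydroxylation** positions are config inputs, not predictions: which
  P450 hydroxylates which carbon is not derivable from the cluster sequence
  alone.
* **Glycosylation** replaces the H of a free hydroxyl with a structurally
  modeled rhamnosyl (net C6H10O4, monoisotopic 146.0579). Only rhamnose is
  supported: a bare formula delta cannot be placed on the atom graph
  without breaking the unsaturation check, so other sugars error rather
  than degrade the bookkeeping.

Two counting conventions deserve a note. *Conjugated double bonds* is the
longest run of enoyl units in adjacent modules — the polyene chromophore
length. *Methyl count* counts only single-carbon substituents on
macrolactone ring atoms (the ω-methyl on the last ring carbon plus
methylmalonyl branches); multi-carbon side chains are reported separately.
This is the unique convention under which the worked example's "two methyl
groups" is reproduced while its C4 chain at C2 counts as a side chain; the
compound literature does not map the methyls to positions, so the positions
themselves are a convention, not a verified claim. Whether the tailoring
C26 hydroxyl belongs among the compound's counted free hydroxyls is
likewise implicit in the literature; the shipped compound spec counts it.

## Genome screens

`gc_windows()` uses 500-bp windows in 250-bp steps (the resolution of the
standard circular GC track); trailing partial windows are dropped to match
the fixed-fragment convention, `N` bases leave the denominator, and windows
over 50% `N` are dropped so scaffold gaps cannot distort the reported
range. `region_gc()` counts bases exactly over an interval — never window
averages — and `gc_contrast()` reports region-vs-genome deltas plus the
min/max of windows fully inside the region. GC contrast is reported
alongside cluster rankings but not scored: in practice all serious
candidates exceed the genome background, so it describes rather than
discriminates. `rank_clusters()` scores |module count − backbone/2|, with
open-ended counts (clusters truncated by scaffold ends) scored at their
lower bound plus 0.5 — a truncated cluster could still match, but the
evidence is weaker. Ranking is deterministic under input permutation by
construction (tie-breaks end at cluster id).

All coordinates are 0-based, half-open, everywhere.

## What the synthetic generator emulates — and what it does not

`generate_cluster()` renders each planned module as a series of
realistically sized domain blocks (KS 420, AT 310, DH 280, KR 450, ACP 80,
TE 250, Dock 60 aa — config values chosen for realistic spacing, not
biology claims) separated by 10–60 aa linkers. Motifs are planted at fixed
block offsets; filler and linkers are drawn from an alphabet lacking D, H,
W and Q — the letters the anchored patterns hinge on — and every assembled
protein is rejection-sampled against the *active* motif config until its
only pattern matches are the planted ones. Ground truth is therefore exact
by construction, and the truth tables record what the scanner should
recover (a DH planted without its core anchor is, by design, expected to be
invisible). The same seed yields byte-identical sequences.

`generate_genome()` draws i.i.d. bases at a target GC and overwrites
cluster regions at their own targets, redrawing regions of ≥ 2 kb until
realized GC is within 0.002 of target so planted contrasts are recovered
tightly.

Passing the recovery tests therefore shows the pipeline is *internally
consistent* — annotation, segmentation and classification invert the
generative model exactly. It does not show robustness to real sequences:
real domains diverge from anchor motifs, linkers contain chance matches,
domain lengths vary, and genomes have codon structure, repeats and gaps
that i.i.d. bases lack. On real data the motif config is the contract: the
pipeline is only as good as the patterns supplied to it.

## Problem sizes and determinism in the test suite

The shipped suite runs the worked example end to end (4 proteins, ~22,000
aa total), 100 seeded random plans for recovery (plus smaller per-module
recovery loops), 50 fuzzed architecture strings, 50 random products for the
atom-conservation and unsaturation invariants, exhaustive rule tables
(16 DH combinations; 26 × 4 extender inputs), and synthetic genomes of
5 kb–400 kb for the GC oracles and planted-delta checks. Every stochastic
step is seeded; `generate_cluster()` and `generate_genome()` use
`withr::with_seed`, so no test perturbs the session RNG.

## Known limitations

* Stereochemistry: KR A/B types are recorded but no 3D configuration is
  assigned or rendered.
* Trans-AT PKSs, iterative modules, module skipping and trans-acting
  complementation are not modeled.
* Docking-domain compatibility is recorded, never used to infer protein
  order.
* The product graph covers C/H/O only — adequate for polyketide aglycones
  and neutral sugars, not for amino-sugar or halogenated decorations.
* Cluster detection itself (antiSMASH and kin) is upstream: `pksline`
  consumes interval tables, it does not produce them.
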