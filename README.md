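# pksline

Annotation of modular type I polyketide synthase (PKS) assembly lines and
prediction of their polyketide products, in R.

## The problem

Modular type I PKSs are bacterial megaenzymes organized as an assembly line:
each module extends the growing polyketide chain by one malonyl-derived C2
unit and sets the redox state of the new β-carbon. Genome mining routinely
produces candidate PKS gene clusters; connecting a cluster to a concrete
compound means (i) annotating each PKS protein at the catalytic-domain level,
(ii) reading extender-unit specificity out of acyltransferase (AT)
active-site motifs, (iii) predicting the product's backbone, rings,
substituents, formula and mass, and (iv) checking the prediction against the
compound actually isolated. `pksline` implements that cluster-to-compound
inference as a reusable, fully testable pipeline, together with the genome-
level screens (windowed GC content, module-count triage) used to shortlist
candidate clusters in the first place.

The package is aimed at natural-product genome miners who have protein and
DNA FASTA plus cluster calls (e.g. antiSMASH interval tables) in hand and
want a deterministic, scriptable route from gene order to a predicted
structure — without any network access or profile-HMM dependencies: all
domain calls are anchored active-site motif matches, configurable via a YAML
file.

## The model

**Domains and modules.** Catalytic domains (KS, AT, DH, ER, KR, ACP, TE,
docking) are located by anchored regular-expression motifs. Modules are cut
at each ketosynthase (KS): one module = KS–AT–(DH/ER/KR)–ACP. A
glutamine replacing the KS catalytic cysteine ("KSQ") marks a
decarboxylative loading module.

**Extender units.** The residue x in the AT's GHSxG active-site motif and a
downstream secondary motif encode specificity: x ∈ {L,V,I,F,A,M} reads
malonyl-CoA, x = Q methylmalonyl-CoA; a noncanonical secondary motif (e.g.
AAGH) flags an unusual AT, provisionally classed ethylmalonyl-CoA. Flagged
ATs are *reconciled* against the target compound: candidate side-chain
lengths C1–C6 are enumerated, the product mass is predicted for each, and
the best match to the target mass wins (a crotonyl-CoA
carboxylase/reductase gene in the cluster is recorded as supporting
evidence for elongated units).

**Backbone and product.** Numbering from the thioester carbonyl C1,
extension module m of M contributes carbonyl 2(M−m)+1 and α-carbon 2(M−m)+2;
its β-carbon 2(M−m)+3 is set to keto / hydroxyl (−OH) / enoyl (C=C) /
methylene by the module's active reductive domains. The released product is
built as an explicit atom/bond graph: thioesterase macrolactonization onto
the most distal β-hydroxyl, hemiketal (tetrahydropyran) closure of a
retained keto group with a hydroxyl four carbons away, tailoring
hydroxylations, and O-glycosylation. Formula, monoisotopic and average
masses, ring sizes, free hydroxyls, conjugated-double-bond runs and methyl
counts all derive from that one graph, with an internal degrees-of-
unsaturation consistency check.

**Genome screens.** `gc_windows()` computes GC over 500-bp windows in
250-bp steps, `gc_contrast()` compares candidate regions against the genome
background (a horizontal-transfer signal), and `rank_clusters()` ranks
candidates by |module count − backbone carbons / 2|.

A synthetic-data module (`generate_cluster()`, `generate_genome()`)
generates proteins with planted motifs and genomes with planted regional GC,
with exact ground truth, so every stage is tested end to end without
downloads.

## Worked example

The package ships the thailandin assembly line of *Actinokineospora
bangkokensis* (four PKS proteins, ThaBI–ThaBIV) as a worked example: the
printed architecture string, the target-compound constraints, the tailoring
configuration, and a module plan for the synthetic generator.

```r
library(pksline)

# the published architecture parses to 4 proteins / 14 module groups
thailandin_architecture()
#> <pks_architecture> 4 proteins, 14 module groups
#> ThaBI [(KS-AT-ACP)-(KS-AT-KR-ACP)-(KS-AT-DH-KR-ACP)-...] ...

# a synthetic cluster with the published motif evidence, annotated fresh
sim  <- generate_cluster(thailandin_plan(), seed = 1)
line <- segment_modules(annotate_proteins(sim$proteins))
glance(line)
#> # A tibble: 1 × 6
#>   n_proteins n_modules n_extension n_loading has_te n_malformed
#> 1          4        14          13         1 TRUE             0

asg <- assign_extenders(line) |>
  reconcile_with_compound(
    line = line, compound_spec = thailandin_compound(),
    post_pks = thailandin_post_pks(), overrides = thailandin_overrides(),
    ccr_present = detect_ccr_gene(thailandin_genes())
  )
asg[asg$module_index %in% c(0, 6, 13), c(1, 3:5, 7)]
#>   module_index x_residue secondary_motif unit          evidence
#> 1            0 L         HAFH            malonyl       motif
#> 2            6 Q         YASH            methylmalonyl motif
#> 3           13 Q         AAGH            butylmalonyl  reconciled

prod <- walk_assembly(line, asg, overrides = thailandin_overrides()) |>
  apply_post_pks(thailandin_post_pks())
prod
#> <polyketide_product> C33H52O10  monoisotopic 608.3560 Da
#>   macrolactone ring, 28 members
#>   hemiketal ring, 6 members
#>   free OH at C3, C5, C7, C11, C13, C15, C26
```

Module 13's AT carries the noncanonical GHSQH/AAGH motif pair; the motif
table alone would call ethylmalonyl-CoA (predicted mass 580.33), but
reconciliation against the 608 Da target selects butylmalonyl-CoA — the C4
side chain at C2. The module-8 ketoreductase has an intact type-A catalytic
set yet is overridden inactive (`thailandin_overrides()`): the retained C13
keto then closes the 6-membered hemiketal with the C9 hydroxyl. The
predicted aglycone matches every compound constraint:

```r
match_spec(prod, thailandin_compound())
#>                constraint target observed deviation pass
#> 1               ring_size     28   28.000 0.000     TRUE
#> 2          hydroxyl_count      7    7.000 0.000     TRUE
#> 3 conjugated_double_bonds      5    5.000 0.000     TRUE
#> 4            methyl_count      2    2.000 0.000     TRUE
#> 5              side_chain      4    4.000 0.000     TRUE
#> 6       monoisotopic_mass    608  608.356 0.356     TRUE
#> 7        backbone_carbons     28   28.000 0.000     TRUE
```

Rhamnosylation at the module-7-derived C15 hydroxyl
(`thailandin_post_pks(rhamnosylation = TRUE)`) adds C6H10O4 and gives the
parent glycoside at 754 Da.

`autoplot()` methods draw the assembly-line domain map and the backbone
state map; `plot_gc_profile()` draws the windowed GC track with candidate
regions shaded. `write_report()` serializes any line or product
deterministically to JSON/TSV.

## Scope and limits

Stereochemistry (KR A/B types are recorded, not rendered), trans-AT
systems, iterative modules, NMR/UV prediction, and running antiSMASH itself
are out of scope. See the methods vignette (`vignettes/pksline-methods.Rmd`)
for the model's assumptions, tunable parameters, and the design decisions
behind the defaults.
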