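# Default motif configuration for PKS catalytic-domain scanning.
#
# Each domain type carries an ordered list of motifs. Exactly one motif per
# type is the `anchor`: its matches seed candidate domain hits, and
# `block_offset` places every motif inside a canonical domain block of
# `block_length` residues (used both to reconstruct a hit's extent when
# scanning and to lay out planted motifs when simulating).
#
# The AT active-site (GHSxG family) and the DH core/auxiliary motifs follow
# the published catalytic-site descriptions for modular PKS domains; the AT
# core is deliberately relaxed to GHS.[GH] so that the noncanonical GHSQH
# variant still yields an x residue (with a flag). The KS/ACP/TE/Dock/ER
# anchors and the KR catalytic/fingerprint regexes are package defaults
# standing in for profile-HMM coordinates; substitute your own patterns here
# if you have HMMER-derived ones.
#
# `extract_offset` is the 0-based offset of the extracted active-site residue
# inside the matched window. `plant` is the canonical realization used by the
# synthetic-cluster generator.

flank: 10
slack: 30
max_matches_per_pattern: 1000

domains:
  KS:
    priority: 1
    block_length: 420
    motifs:
      - motif_id: ks_box
        pattern: "HGTGT"
        block_offset: 170
        required: true
        anchor: true
        plant: "HGTGT"
      - motif_id: ks_active_site
        pattern: "TA.SSG"
        block_offset: 80
        required: true
        extract_offset: 2
        plant: "TACSSG"
  AT:
    priority: 2
    block_length: 310
    motifs:
      - motif_id: at_anchor
        pattern: "GQG.Q"
        block_offset: 12
        required: true
        anchor: true
        plant: "GQGAQ"
      - motif_id: at_core
        pattern: "GHS.[GH]"
        block_offset: 95
        required: false
        extract_offset: 3
        plant: "GHSLG"
      - motif_id: at_secondary
        pattern: "HAFH|YASH|AAGH"
        block_offset: 190
        required: false
        plant: "HAFH"
  DH:
    priority: 3
    block_length: 280
    motifs:
      - motif_id: dh_core
        pattern: "H...G....P"
        block_offset: 40
        required: true
        anchor: true
        plant: "HAAAGAAAAP"
      - motif_id: dh_aux_gyxygpxf
        pattern: "GY.YGP.F"
        block_offset: 110
        required: false
        plant: "GYAYGPAF"
      - motif_id: dh_aux_lpfxw
        pattern: "LPF.W"
        block_offset: 160
        required: false
        plant: "LPFAW"
      - motif_id: dh_aux_dxxxqh
        pattern: "D...[QH]"
        block_offset: 210
        required: false
        plant: "DAAAQ"
  ER:
    priority: 4
    block_length: 300
    motifs:
      - motif_id: er_anchor
        pattern: "GGVG..A"
        block_offset: 55
        required: true
        anchor: true
        plant: "GGVGMAA"
  KR:
    priority: 5
    block_length: 450
    motifs:
      - motif_id: kr_anchor
        pattern: "GG.G.[LI]G"
        block_offset: 25
        required: true
        anchor: true
        plant: "GGAGALG"
      - motif_id: kr_triad
        pattern: "S.{4}Y.{3}N"
        block_offset: 150
        required: false
        plant: "SAAAAYAAAN"
      - motif_id: kr_type_a
        pattern: "GR.{4}W"
        block_offset: 250
        required: false
        plant: "GRAAAAW"
      - motif_id: kr_type_b
        pattern: "LDD"
        block_offset: 300
        required: false
        plant: "LDD"
  ACP:
    priority: 6
    block_length: 80
    motifs:
      - motif_id: acp_ppant
        pattern: "G.DSL"
        block_offset: 32
        required: true
        anchor: true
        plant: "GADSL"
  TE:
    priority: 7
    block_length: 250
    motifs:
      - motif_id: te_catalytic
        pattern: "G[WY]S.G"
        block_offset: 70
        required: true
        anchor: true
        plant: "GWSAG"
  Dock:
    priority: 8
    block_length: 60
    motifs:
      - motif_id: dock_helix
        pattern: "LAEQLAEQ"
        block_offset: 15
        required: true
        anchor: true
        plant: "LAEQLAEQ"
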