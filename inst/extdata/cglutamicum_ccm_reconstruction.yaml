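# Central carbon metabolism of Corynebacterium glutamicum ATCC 13032 --
# synthetic reconstruction of the flux-fitting network from the published
# pathway inventory and dimension counts (glycolysis, PPP, TCA cycle,
# anaplerosis, glyoxylate shunt, protocatechuate degradation, amino acid
# synthesis, lumped biomass drain). Atom transitions use the letter-string
# convention; scrambling variants for the C-symmetric pools (SUC, FUM,
# meso-DAP) are generated by expansion, not listed here.
#
# Units: biomass demand coefficients in umol/gCDW; fluxes in umol/gCDW/h.

metabolites:
  # --- non-balanced pools ---
  - {id: GLC_ext, carbons: 6, role: input}
  - {id: PCA_ext, carbons: 7, role: input}
  - {id: CO2_ext, carbons: 1, role: input}
  - {id: BM, carbons: 0, role: output}
  # --- glycolysis ---
  - {id: G6P, carbons: 6}
  - {id: F6P, carbons: 6}
  - {id: FBP, carbons: 6}
  - {id: DHAP, carbons: 3}
  - {id: GAP, carbons: 3}
  - {id: PG3, carbons: 3}
  - {id: PEP, carbons: 3}
  - {id: PYR, carbons: 3}
  # --- pentose phosphate pathway ---
  - {id: PG6, carbons: 6}
  - {id: RU5P, carbons: 5}
  - {id: R5P, carbons: 5}
  - {id: X5P, carbons: 5}
  - {id: S7P, carbons: 7}
  - {id: E4P, carbons: 4}
  # --- TCA cycle / glyoxylate ---
  - {id: ACCOA, carbons: 2}
  - {id: OAA, carbons: 4}
  - {id: CIT, carbons: 6}
  - {id: ICIT, carbons: 6}
  - {id: AKG, carbons: 5}
  - {id: SUCCOA, carbons: 4}
  - {id: SUC, carbons: 4, symmetric: true}
  - {id: FUM, carbons: 4, symmetric: true}
  - {id: MAL, carbons: 4}
  - {id: GLX, carbons: 2}
  # --- one-carbon / CO2 / aromatics feed ---
  - {id: CO2, carbons: 1}
  - {id: PCA, carbons: 7}
  - {id: MTHF, carbons: 1}
  - {id: DAP, carbons: 7, symmetric: true}
  # --- amino acids ---
  - {id: ALA, carbons: 3}
  - {id: VAL, carbons: 5}
  - {id: LEU, carbons: 6}
  - {id: ASP, carbons: 4}
  - {id: ASN, carbons: 4}
  - {id: LYS, carbons: 6}
  - {id: THR, carbons: 4}
  - {id: ILE, carbons: 6}
  - {id: MET, carbons: 5}
  - {id: SER, carbons: 3}
  - {id: GLY, carbons: 2}
  - {id: GLU, carbons: 5}
  - {id: GLN, carbons: 5}
  - {id: ARG, carbons: 6}
  - {id: PRO, carbons: 5}
  - {id: TYR, carbons: 9}
  - {id: PHE, carbons: 9}

reactions:
  # transport
  - {id: glc_upt, equation: "GLC_ext#abcdef + PEP#ghi -> G6P#abcdef + PYR#ghi"}
  - {id: pca_upt, equation: "PCA_ext#abcdefg -> PCA#abcdefg"}
  - {id: co2_out, equation: "CO2#a -> CO2_ext#a"}
  - {id: co2_in,  equation: "CO2_ext#a -> CO2#a"}
  # glycolysis
  - {id: pgi,   equation: "G6P#abcdef <-> F6P#abcdef"}
  - {id: pfk,   equation: "F6P#abcdef -> FBP#abcdef"}
  - {id: fbp,   equation: "FBP#abcdef -> F6P#abcdef"}
  - {id: fda,   equation: "FBP#abcdef <-> DHAP#cba + GAP#def"}
  - {id: tpi,   equation: "DHAP#abc <-> GAP#cba"}
  - {id: gapdh, equation: "GAP#abc <-> PG3#abc"}
  - {id: eno,   equation: "PG3#abc <-> PEP#abc"}
  - {id: pyk,   equation: "PEP#abc -> PYR#abc"}
  - {id: pdh,   equation: "PYR#abc -> ACCOA#bc + CO2#a"}
  # pentose phosphate pathway
  - {id: zwf,  equation: "G6P#abcdef -> PG6#abcdef"}
  - {id: gnd,  equation: "PG6#abcdef -> RU5P#bcdef + CO2#a"}
  - {id: rpe,  equation: "RU5P#abcde <-> X5P#abcde"}
  - {id: rpi,  equation: "RU5P#abcde <-> R5P#abcde"}
  - {id: tkt1, equation: "X5P#abcde + R5P#fghij <-> S7P#abfghij + GAP#cde"}
  - {id: tal,  equation: "S7P#abcdefg + GAP#hij <-> E4P#defg + F6P#abchij"}
  - {id: tkt2, equation: "X5P#abcde + E4P#fghi <-> F6P#abfghi + GAP#cde"}
  # TCA cycle
  - {id: gltA,  equation: "OAA#abcd + ACCOA#ef -> CIT#dcbfea"}
  - {id: acn,   equation: "CIT#abcdef <-> ICIT#abcdef"}
  - {id: icd,   equation: "ICIT#abcdef -> AKG#abcde + CO2#f"}
  - {id: akgdh, equation: "AKG#abcde -> SUCCOA#bcde + CO2#a"}
  - {id: sucCD, equation: "SUCCOA#abcd -> SUC#abcd"}
  - {id: sdh,   equation: "SUC#abcd <-> FUM#abcd"}
  - {id: fumh,  equation: "FUM#abcd <-> MAL#abcd"}
  - {id: mqo,   equation: "MAL#abcd <-> OAA#abcd"}
  # anaplerosis and glyoxylate shunt
  - {id: pyc,  equation: "PYR#abc + CO2#d -> OAA#abcd"}
  - {id: ppc,  equation: "PEP#abc + CO2#d -> OAA#abcd"}
  - {id: pck,  equation: "OAA#abcd -> PEP#abc + CO2#d"}
  - {id: mez,  equation: "MAL#abcd <-> PYR#abc + CO2#d"}
  - {id: aceA, equation: "ICIT#abcdef -> GLX#ab + SUC#cdef"}
  - {id: aceB, equation: "GLX#ab + ACCOA#cd -> MAL#abdc"}
  # protocatechuate (beta-ketoadipate pathway, lumped)
  - {id: pca_deg, equation: "PCA#abcdefg -> ACCOA#ab + SUCCOA#cdef + CO2#g"}
  # amino acid synthesis
  - {id: gdh,     equation: "AKG#abcde <-> GLU#abcde"}
  - {id: ala_ta,  equation: "PYR#abc + GLU#defgh <-> ALA#abc + AKG#defgh"}
  - {id: asp_ta,  equation: "OAA#abcd + GLU#efghi <-> ASP#abcd + AKG#efghi"}
  - {id: gln_syn, equation: "GLU#abcde -> GLN#abcde"}
  - {id: pro_syn, equation: "GLU#abcde -> PRO#abcde"}
  - {id: arg_syn, equation: "GLU#abcde + CO2#f -> ARG#abcdef"}
  - {id: asn_syn, equation: "ASP#abcd -> ASN#abcd"}
  - {id: thr_syn, equation: "ASP#abcd -> THR#abcd"}
  - {id: met_syn, equation: "ASP#abcd + MTHF#e -> MET#abcde"}
  - {id: ile_syn, equation: "THR#abcd + PYR#efg -> ILE#abfcdg + CO2#e"}
  - {id: val_syn, equation: "PYR#abc + PYR#def -> VAL#abecf + CO2#d"}
  - {id: leu_syn, equation: "ACCOA#ab + PYR#cde + PYR#fgh -> LEU#abdgeh + CO2#c + CO2#f"}
  - {id: ser_syn, equation: "PG3#abc + GLU#defgh -> SER#abc + AKG#defgh"}
  - {id: glyA,    equation: "SER#abc <-> GLY#ab + MTHF#c"}
  - {id: gcv,     equation: "GLY#ab <-> CO2#a + MTHF#b"}
  - {id: lys1,    equation: "ASP#abcd + PYR#efg -> DAP#abcdgfe"}
  - {id: lys2,    equation: "DAP#abcdefg -> LYS#abcdef + CO2#g"}
  - {id: tyr_syn, equation: "PEP#abc + PEP#def + E4P#ghij -> TYR#abcefghij + CO2#d"}
  - {id: phe_syn, equation: "PEP#abc + PEP#def + E4P#ghij -> PHE#abcefghij + CO2#d"}

# lumped biomass equation: growth-scaled unidirectional drains, umol/gCDW
biomass:
  sink: BM
  fixed_uptakes: [glc_upt, pca_upt]
  demand:
    ALA: 830
    VAL: 400
    LEU: 460
    ASP: 330
    ASN: 220
    LYS: 330
    THR: 290
    ILE: 270
    MET: 150
    SER: 280
    GLY: 560
    GLU: 558
    GLN: 220
    ARG: 270
    PRO: 200
    TYR: 130
    PHE: 170
    G6P: 205
    R5P: 700
    E4P: 70
    PG3: 130
    PEP: 100
    PYR: 250
    ACCOA: 2330
    OAA: 220
    AKG: 180
    MTHF: 380

nadph_coefficient: 14849

# NADH-equivalents (respiratory electrons) produced per unit flux; used for
# the electron-balance oxygen uptake estimate. nadh_biomass is the net
# NADH-equivalent consumed per gCDW formed.
nadh_biomass: 0
cofactors:
  gapdh: {nadh: 1}
  pdh:   {nadh: 1}
  akgdh: {nadh: 1}
  sdh:   {nadh: 1}
  mqo:   {nadh: 1}
  gcv:   {nadh: 1}
  pca_deg: {o2: 2}

# NADPH sources (mol NADPH per unit flux) for the redox accounting
nadph_sources:
  zwf: 1
  gnd: 1
  icd: 1
  mez: 1

preferred_free: [zwf, pck, ppc, mez, aceA, gcv, co2_in, fbp]

tracer_inputs:
  glucose: GLC_ext
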