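# Monomer templates for converting macromolecular mass fractions into
# biomass-equation coefficients (mmol per gDCW).
#
# For a polymeric component with mass fraction w, monomer mole fractions x_m
# and residue (polymerised) molar masses M_m, the coefficient of monomer m is
#   1000 * w * x_m / sum_m(x_m * M_m).
# Formulas are the polymerised residue formulas, CHONPS elements only
# (the Mg of chlorophyll a is excluded from elemental bookkeeping; its
# residue mass still includes it). Protein mole fractions follow a typical
# bacterial amino-acid usage; nucleotides are equimolar; the acyl profile is
# C16:0/C18:1 dominated. All entries are replaceable via user YAML.
protein:
  monomers:
    - {id: ala, mole_fraction: 0.096, formula: C3H5NO,    residue_mass: 71.079,  metabolite: ala__L_c}
    - {id: arg, mole_fraction: 0.055, formula: C6H12N4O,  residue_mass: 156.188, metabolite: arg__L_c}
    - {id: asn, mole_fraction: 0.045, formula: C4H6N2O2,  residue_mass: 114.104, metabolite: asn__L_c}
    - {id: asp, mole_fraction: 0.045, formula: C4H5NO3,   residue_mass: 115.088, metabolite: asp__L_c}
    - {id: cys, mole_fraction: 0.017, formula: C3H5NOS,   residue_mass: 103.143, metabolite: cys__L_c}
    - {id: gln, mole_fraction: 0.049, formula: C5H8N2O2,  residue_mass: 128.131, metabolite: gln__L_c}
    - {id: glu, mole_fraction: 0.049, formula: C5H7NO3,   residue_mass: 129.115, metabolite: glu__L_c}
    - {id: gly, mole_fraction: 0.115, formula: C2H3NO,    residue_mass: 57.052,  metabolite: gly_c}
    - {id: his, mole_fraction: 0.018, formula: C6H7N3O,   residue_mass: 137.141, metabolite: his__L_c}
    - {id: ile, mole_fraction: 0.054, formula: C6H11NO,   residue_mass: 113.160, metabolite: ile__L_c}
    - {id: leu, mole_fraction: 0.084, formula: C6H11NO,   residue_mass: 113.160, metabolite: leu__L_c}
    - {id: lys, mole_fraction: 0.064, formula: C6H12N2O,  residue_mass: 128.174, metabolite: lys__L_c}
    - {id: met, mole_fraction: 0.029, formula: C5H9NOS,   residue_mass: 131.196, metabolite: met__L_c}
    - {id: phe, mole_fraction: 0.035, formula: C9H9NO,    residue_mass: 147.177, metabolite: phe__L_c}
    - {id: pro, mole_fraction: 0.041, formula: C5H7NO,    residue_mass: 97.117,  metabolite: pro__L_c}
    - {id: ser, mole_fraction: 0.040, formula: C3H5NO2,   residue_mass: 87.078,  metabolite: ser__L_c}
    - {id: thr, mole_fraction: 0.047, formula: C4H7NO2,   residue_mass: 101.105, metabolite: thr__L_c}
    - {id: trp, mole_fraction: 0.011, formula: C11H10N2O, residue_mass: 186.213, metabolite: trp__L_c}
    - {id: tyr, mole_fraction: 0.026, formula: C9H9NO2,   residue_mass: 163.176, metabolite: tyr__L_c}
    - {id: val, mole_fraction: 0.079, formula: C5H9NO,    residue_mass: 99.133,  metabolite: val__L_c}
glycogen:
  monomers:
    - {id: glucosyl, mole_fraction: 1.0, formula: C6H10O5, residue_mass: 162.141, metabolite: glycogen_c}
carbohydrate_other:
  monomers:
    - {id: glucosyl, mole_fraction: 1.0, formula: C6H10O5, residue_mass: 162.141, metabolite: carbohydrate_c}
lipid:
  monomers:
    - {id: palmitoyl, mole_fraction: 0.6, formula: C16H32O2, residue_mass: 256.424, metabolite: palm_c}
    - {id: oleoyl,    mole_fraction: 0.4, formula: C18H34O2, residue_mass: 282.462, metabolite: ocdcea_c}
rna:
  monomers:
    - {id: amp, mole_fraction: 0.25, formula: C10H12N5O6P, residue_mass: 329.206, metabolite: amp_c}
    - {id: gmp, mole_fraction: 0.25, formula: C10H12N5O7P, residue_mass: 345.205, metabolite: gmp_c}
    - {id: cmp, mole_fraction: 0.25, formula: C9H12N3O7P,  residue_mass: 305.181, metabolite: cmp_c}
    - {id: ump, mole_fraction: 0.25, formula: C9H11N2O8P,  residue_mass: 306.166, metabolite: ump_c}
dna:
  monomers:
    - {id: damp, mole_fraction: 0.25, formula: C10H12N5O5P, residue_mass: 313.207, metabolite: damp_c}
    - {id: dgmp, mole_fraction: 0.25, formula: C10H12N5O6P, residue_mass: 329.206, metabolite: dgmp_c}
    - {id: dcmp, mole_fraction: 0.25, formula: C9H12N3O6P,  residue_mass: 289.182, metabolite: dcmp_c}
    - {id: dtmp, mole_fraction: 0.25, formula: C10H13N2O7P, residue_mass: 304.194, metabolite: dtmp_c}
chlorophyll_a:
  monomers:
    - {id: chla, mole_fraction: 1.0, formula: C55H72N4O5, residue_mass: 893.490, metabolite: chla_c}
carotenoids:
  monomers:
    - {id: caro, mole_fraction: 1.0, formula: C40H56, residue_mass: 536.873, metabolite: caro_c}
phycobiliproteins:
  use_profile_of: protein
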