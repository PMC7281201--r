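# Minimal heterologous production pathways for the synthetic photoautotroph
# (metabolite ids refer to the toy model; replace for other models).
ethanol:
  metabolites:
    - {id: acald_c, name: acetaldehyde, compartment: cytosol, formula: C2H4O}
    - {id: etoh_c, name: ethanol, compartment: cytosol, formula: C2H6O}
  reactions:
    - id: PDC
      name: pyruvate decarboxylase
      stoichiometry: {pyr_c: -1, acald_c: 1, co2_c: 1}
    - id: ADH
      name: alcohol dehydrogenase (NADPH)
      stoichiometry: {acald_c: -1, nadph_c: -1, etoh_c: 1, nadp_c: 1}
lactate:
  metabolites:
    - {id: lac_c, name: D-lactate, compartment: cytosol, formula: C3H6O3}
  reactions:
    - id: LDH
      name: lactate dehydrogenase (NADPH)
      stoichiometry: {pyr_c: -1, nadph_c: -1, lac_c: 1, nadp_c: 1}
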