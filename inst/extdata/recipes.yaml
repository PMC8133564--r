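# Nutrient solution recipes for the multiple ion-uptake assay workflow.
# Salt concentrations in uM; ion stoichiometries resolved from the package
# salt library unless given inline. Hydration water ignored.
recipes:
  - label: growth
    ph: 6
    salts:
      - {name: KH2PO4, conc_uM: 500}
      - {name: KNO3, conc_uM: 5700}
      - {name: NH4NO3, conc_uM: 300}
      - {name: CaCl2, conc_uM: 2000}
      - {name: MgSO4, conc_uM: 1000}
      - {name: H3BO3, conc_uM: 46}
      - {name: ZnSO4.7H2O, conc_uM: 7}
      - {name: MnCl2.4H2O, conc_uM: 9}
      - {name: CuSO4.5H2O, conc_uM: 0.32}
      - {name: (NH4)6Mo7O24.4H2O, conc_uM: 0.114}
      - {name: Fe(III)-EDTA, conc_uM: 150}
  - label: deprivation
    ph: 6
    salts:
      - {name: CaCl2, conc_uM: 500}
      - {name: H3BO3, conc_uM: 46}
      - {name: ZnSO4.7H2O, conc_uM: 7}
      - {name: MnCl2.4H2O, conc_uM: 9}
      - {name: CuSO4.5H2O, conc_uM: 0.32}
      - {name: (NH4)6Mo7O24.4H2O, conc_uM: 0.114}
      - {name: Fe(III)-EDTA, conc_uM: 150}
  - label: high
    ph: 6
    salts:
      - {name: KNO3, conc_uM: 1000}
      - {name: NH4Cl, conc_uM: 1000}
      - {name: Ca(H2PO4)2.H2O, conc_uM: 125}
      - {name: MgSO4, conc_uM: 250}
      - {name: CaCl2, conc_uM: 375}
      - {name: MES, conc_uM: 1000}
  - label: low
    ph: 6
    salts:
      - {name: KNO3, conc_uM: 100}
      - {name: NH4Cl, conc_uM: 100}
      - {name: Ca(H2PO4)2.H2O, conc_uM: 12.5}
      - {name: MgSO4, conc_uM: 25}
      - {name: CaCl2, conc_uM: 487.5}
      - {name: MES, conc_uM: 1000}
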