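# THY1773 study configuration: published compound parameters, animal iv PK
# summary, HLM phenotyping data and observed human oral PK.
compound:
  name: THY1773
  molecular_weight: 483.99   # g/mol
  log_p: 3.17
  pka: 6.85
  compound_type: monoprotic_base
  fu_plasma:                 # unbound fraction in plasma
    rat: 0.108
    dog: 0.104
    human: 0.017
  blood_plasma_ratio:
    rat: 0.822
    dog: 0.846
    human: 0.55
  clint_microsomal:          # uL/min/mg microsomal protein
    rat: 22.0
    dog: 32.2
    human: 11.2
  fu_mic: 0.714              # unbound fraction in HLM incubation
  fm_by_enzyme:
    CYP3A4: 0.911
    CYP2D6: 0.089
  ec50_free: 3.51            # nmol/L, free plasma EC50 for receptor occupancy
  emax: 100                  # % maximal occupancy
  ka: 3.10                   # 1/h
  fa: 0.998
  fu_gut: 1
phenotyping:                 # HLM CLint with selective inhibitors, uL/min/mg
  clint_control: 11.2
  clint_with_inhibitor:
    CYP3A: 0.961
    CYP2D6: 10.2
animal_pk:                   # single-dose iv NCA summary
  rat: {cl_total: 1330, vdss: 2220, fe_urine: 0.046}   # mL/h/kg, mL/kg
  dog: {cl_total: 785, vdss: 2020, fe_urine: 0.020}
esf:                         # empirical scaling factors from the iv studies
  rat: 6.5
  dog: 3.6
observed_human:              # phase 1 oral PK, body-weight normalised
  cl_over_f: 17.2            # mL/h/kg
  vdz_over_f: 528            # mL/kg
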