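# Reduced kinetic network of cardiac central energy metabolism, v1.
#
# One lumped reaction per pathway segment. Concentrations mM, rates
# mM/min per g wet tissue. Plasma species are clamped boundary conditions
# (defaults = overnight-fasted state). Redox is carried by a single
# NAD/NADH pool; FADH2-derived reducing equivalents are folded in as 0.6
# NADH so that the network's stoichiometric ATP yields land at textbook
# values (glucose 32, palmitate 106 ATP per molecule) with a uniform
# P/O of 2.5 at the lumped respiratory chain.
#
# Vmax values are calibrated so that the reference (control) heart
# reproduces fasted fatty-acid dominance (~80% of ATP production), the
# postprandial shift toward carbohydrate use, and a maximal ATP
# production capacity of 3-4x the resting demand.
schema_version: 1
name: cardiac_reduced_v1
parameters:
  km_atp: 0.5        # mM; affinity of the hyperbolic ATP demand law
  load_rest: 10.0    # mM/min; resting ATP demand (calibration constant)
  insulin: {a_ins: 1.0, k_ins: 200.0}   # vmax multiplier 1 + a*I/(I+K), I in pM

metabolites:
  - {id: glc_e,  name: glucose,            compartment: plasma, conc0: 5.8,  boundary: true,  carbons: 6}
  - {id: ffa_e,  name: fatty acids (NEFA), compartment: plasma, conc0: 0.5,  boundary: true,  carbons: 16}
  - {id: lac_e,  name: lactate,            compartment: plasma, conc0: 0.8,  boundary: true,  carbons: 3}
  - {id: val_e,  name: valine,             compartment: plasma, conc0: 0.2,  boundary: true,  carbons: 5}
  - {id: leu_e,  name: leucine,            compartment: plasma, conc0: 0.15, boundary: true,  carbons: 6}
  - {id: ile_e,  name: isoleucine,         compartment: plasma, conc0: 0.06, boundary: true,  carbons: 6}
  - {id: bhb_e,  name: beta-hydroxybutyrate, compartment: plasma, conc0: 0.08, boundary: true, carbons: 4}
  - {id: acac_e, name: acetoacetate,       compartment: plasma, conc0: 0.04, boundary: true,  carbons: 4}
  - {id: o2_e,   name: oxygen,             compartment: plasma, conc0: 0.05, boundary: true,  carbons: 0}
  - {id: g6p,    name: glucose 6-phosphate, compartment: cytosol, conc0: 0.2,  carbons: 6}
  - {id: pyr,    name: pyruvate,           compartment: cytosol, conc0: 0.05, carbons: 3}
  - {id: accoa,  name: acetyl-CoA,         compartment: mitochondria, conc0: 0.05, carbons: 2}
  - {id: bcaa_i, name: intracellular BCAA, compartment: cytosol, conc0: 0.1,  carbons: 5}
  - {id: atp,    name: ATP,                compartment: cytosol, conc0: 6.7,  carbons: 0}
  - {id: adp,    name: ADP,                compartment: cytosol, conc0: 1.3,  carbons: 0}
  - {id: nadh,   name: NADH,               compartment: mitochondria, conc0: 0.1, carbons: 0}
  - {id: nad,    name: NAD,                compartment: mitochondria, conc0: 0.9, carbons: 0}

pools:
  - {id: adenine,      members: [atp, adp],  total: 8.0}
  - {id: nicotinamide, members: [nad, nadh], total: 1.0}

substrate_classes:
  glucose: [glc_e]
  ffa:     [ffa_e]
  lactate: [lac_e]
  ketones: [bhb_e, acac_e]
  bcaa:    [val_e, leu_e, ile_e]

reactions:
  # glucose transport + hexokinase (insulin-stimulated)
  - id: glut
    pathway: transport
    insulin_regulated: true
    stoich: {glc_e: -1, atp: -1, g6p: 1, adp: 1}
    law:
      form: irreversible-MM
      vmax: 0.27
      km: {glc_e: 8.0, atp: 0.2}
      modifiers:
        - {id: g6p, type: inhibitor, k_eff: 0.4}
    proteins: [Slc2a4, Slc2a1, Hk2]

  # glycolysis from G6P to pyruvate (net +2 ATP per glucose incl. the
  # hexose kinase ATP spent at glut)
  - id: glyc
    pathway: glycolysis
    stoich: {g6p: -1, adp: -3, nad: -2, pyr: 2, atp: 3, nadh: 2}
    law:
      form: irreversible-MM
      vmax: 1.5
      km: {g6p: 0.3, adp: 0.1, nad: 0.05}
    proteins: [Pfkm, Aldoa, Gapdh, Pgk1, Pkm, Eno1]

  # monocarboxylate transport + lactate dehydrogenase, reversible
  - id: ldh
    pathway: lactate-exchange
    stoich: {lac_e: -1, nad: -1, pyr: 1, nadh: 1}
    law:
      form: reversible-MM
      vmax: 1.30
      keq: 2.0
      km: {lac_e: 2.0, nad: 0.1, pyr: 0.15, nadh: 0.01}
    proteins: [Slc16a1, Ldha, Ldhb]

  # pyruvate dehydrogenase; acetyl-CoA inhibition carries the
  # glucose/fatty-acid (Randle) competition
  - id: pdh
    pathway: tca
    stoich: {pyr: -1, nad: -1, accoa: 1, nadh: 1}
    law:
      form: irreversible-MM
      vmax: 2.0
      km: {pyr: 0.05, nad: 0.05}
      modifiers:
        - {id: accoa, type: inhibitor, k_eff: 0.04}
    proteins: [Pdha1, Pdhb, Dlat]

  # fatty-acid uptake + activation (2 ATP) + beta-oxidation of a C16 FA;
  # 7 NADH + 7 FADH2 folded in as 11.2 NADH-equivalents
  - id: fao
    pathway: fao
    stoich: {ffa_e: -1, atp: -2, nad: -11.2, accoa: 8, adp: 2, nadh: 11.2}
    law:
      form: irreversible-MM
      vmax: 1.07
      km: {ffa_e: 0.4, nad: 0.05, atp: 0.2}
      modifiers:
        - {id: accoa, type: inhibitor, k_eff: 0.15}
    proteins: [Cd36, Cpt1b, Cpt2, Acadvl, Acadl, Hadha, Hadhb, Etfa]

  # beta-hydroxybutyrate uptake + oxidation to 2 acetyl-CoA (the
  # succinyl-CoA diverted by SCOT is booked as 1 ATP)
  - id: ket_bhb
    pathway: ketolysis
    stoich: {bhb_e: -1, nad: -1, atp: -1, accoa: 2, nadh: 1, adp: 1}
    law:
      form: irreversible-MM
      vmax: 0.5
      km: {bhb_e: 0.15, nad: 0.05}
      modifiers:
        - {id: accoa, type: inhibitor, k_eff: 0.15}
    proteins: [Bdh1, Oxct1]

  # acetoacetate uptake + activation to 2 acetyl-CoA
  - id: ket_acac
    pathway: ketolysis
    stoich: {acac_e: -1, atp: -1, accoa: 2, adp: 1}
    law:
      form: irreversible-MM
      vmax: 0.3
      km: {acac_e: 0.1}
      modifiers:
        - {id: accoa, type: inhibitor, k_eff: 0.15}
    proteins: [Oxct1, Acat1]

  # BCAA transport (shared L-type carrier) into a common intracellular pool
  - id: val_t
    pathway: bcaa
    stoich: {val_e: -1, bcaa_i: 1}
    law:
      form: facilitated-transport
      vmax: 0.0625
      km: {val_e: 0.5}
      modifiers:
        - {id: bcaa_i, type: inhibitor, k_eff: 0.5}
    proteins: [Slc7a5]
  - id: leu_t
    pathway: bcaa
    stoich: {leu_e: -1, bcaa_i: 1}
    law:
      form: facilitated-transport
      vmax: 0.0625
      km: {leu_e: 0.5}
      modifiers:
        - {id: bcaa_i, type: inhibitor, k_eff: 0.5}
    proteins: [Slc7a5]
  - id: ile_t
    pathway: bcaa
    stoich: {ile_e: -1, bcaa_i: 1}
    law:
      form: facilitated-transport
      vmax: 0.0625
      km: {ile_e: 0.5}
      modifiers:
        - {id: bcaa_i, type: inhibitor, k_eff: 0.5}
    proteins: [Slc7a5]

  # lumped BCAA oxidation to acetyl-CoA equivalents
  - id: bcaa_ox
    pathway: bcaa
    stoich: {bcaa_i: -1, nad: -2, accoa: 2, nadh: 2}
    law:
      form: irreversible-MM
      vmax: 0.8
      km: {bcaa_i: 0.3, nad: 0.05}
      modifiers:
        - {id: accoa, type: inhibitor, k_eff: 0.15}
    proteins: [Bcat2, Bckdha, Bckdhb, Ivd, Acadsb]

  # citric acid cycle per acetyl-CoA: 3 NADH + 1 FADH2 (0.6 NADH-eq) + 1 GTP
  - id: tca
    pathway: tca
    stoich: {accoa: -1, nad: -3.6, adp: -1, nadh: 3.6, atp: 1}
    law:
      form: irreversible-MM
      vmax: 5.08
      km: {accoa: 0.01, nad: 0.08, adp: 0.05}
    proteins: [Cs, Aco2, Idh3a, Ogdh, Sdha, Fh1, Mdh2, Sucla2]

  # respiratory chain + ATP synthase + adenine nucleotide translocator,
  # uniform P/O 2.5
  - id: resp
    pathway: oxphos
    stoich: {nadh: -1, o2_e: -0.5, adp: -2.5, nad: 1, atp: 2.5}
    law:
      form: irreversible-MM
      vmax: 21.6
      km: {nadh: 0.02, adp: 0.05, o2_e: 0.01}
    proteins: [Ndufs1, Ndufv1, Sdhb, Uqcrc1, Uqcrc2, Cox4i1, Cox5a, Atp5f1a, Atp5f1b, Slc25a4]

  # hyperbolic ATP demand v = load * ATP / (ATP + km_atp); the load scale
  # is set by the load-scan machinery (vmax here is a 1.0 placeholder)
  - id: atp_demand
    pathway: atp-demand
    stoich: {atp: -1, adp: 1}
    law:
      form: load-hyperbolic
      vmax: 1.0
      km: {atp: 0.5}
    proteins: []
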