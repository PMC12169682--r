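# Aloe-emodin photophysics dataset (published worked example).
# All values are the printed ones from the source study except where a line
# is marked "synthetic placeholder": those fields are not printed anywhere
# and carry plausible stand-ins so that optional stages (Jablonski assembly,
# anion yield scenarios) are exercisable. Nothing quantitative is asserted
# against placeholders.
conditions:
  temperature: 298.15
  pH: 7.4
species:
  - label: AE            # neutral form
    net_charge: 0
    pka: 9.20            # first deprotonation (C1 hydroxyl)
    states:
      - {multiplicity: singlet, index: 1, vertical_energy: 2.7255264,  # 454.9 nm
         adiabatic_energy: 2.44, oscillator_strength: 0.354}
      - {multiplicity: triplet, index: 1, vertical_energy: 1.80,       # vertical: synthetic placeholder (= adiabatic)
         adiabatic_energy: 1.80}                                       # T1-S0 gap, printed
      - {multiplicity: triplet, index: 2, vertical_energy: 2.10,       # vertical: synthetic placeholder
         adiabatic_energy: 2.10}                                       # = S1 - 0.34 eV
      - {multiplicity: triplet, index: 3, vertical_energy: 2.39,       # vertical: synthetic placeholder
         adiabatic_energy: 2.39}                                       # = S1 - 0.05 eV
    soc: []
    rates:
      isc:
        - {singlet_index: 1, triplet_index: 2, rate: 1.32e+10}
        - {singlet_index: 1, triplet_index: 3, rate: 2.15e+09}
        - {singlet_index: 1, triplet_index: 1, rate: 3.59e+08}
      k_F: 1.53e+08
      k_IC: 1.47e+10
      k_P: 3.8461538e-02   # inverted from the printed 26.0 s lifetime
    tpa:
      - {state_index: 1, excitation_energy: 2.7255264,
         photon_wavelength_nm: 909.8, sigma_corrected_GM: 1.3}
      - {state_index: 3, excitation_energy: 3.0899489,
         photon_wavelength_nm: 802.5, sigma_corrected_GM: 93.7}
    fedam: []
    reactions:           # printed table block for the neutral triplet
      - {label: 10a,  delta_E_vertical: 26.1,  delta_G_adiabatic: 13.2,
         lambda_reorg: 13.0, delta_G_activation: 13.2, rate_k: 1.38e+03}
      - {label: 10b,  delta_E_vertical: -12.7, delta_G_adiabatic: -25.0,
         lambda_reorg: 12.3, delta_G_activation: 3.3,  rate_k: 2.53e+10}
      - {label: 10c,  delta_E_vertical: 34.3,  delta_G_adiabatic: 19.9,
         lambda_reorg: 14.4, delta_G_activation: 20.4, rate_k: 7.00e-03}
      - {label: 10d,  delta_E_vertical: 14.5,  delta_G_adiabatic: -5.7,
         lambda_reorg: 20.1, delta_G_activation: 2.6,  rate_k: 7.71e+10}
      - {label: 2dG,  delta_E_vertical: 13.7,  delta_G_adiabatic: 0.3,
         lambda_reorg: 13.5, delta_G_activation: 3.5,  rate_k: 1.67e+10}
      - {label: Cys,  delta_E_vertical: 32.8,  delta_G_adiabatic: 8.3,
         lambda_reorg: 24.5, delta_G_activation: 11.0, rate_k: 5.66e+04}
      - {label: His+, delta_E_vertical: 39.7,  delta_G_adiabatic: 17.7,
         lambda_reorg: 22.0, delta_G_activation: 17.9, rate_k: 4.46e-01}
      - {label: Met,  delta_E_vertical: 21.8,  delta_G_adiabatic: 8.3,
         lambda_reorg: 13.5, delta_G_activation: 8.8,  rate_k: 2.11e+06}
      - {label: Trp,  delta_E_vertical: 7.3,   delta_G_adiabatic: -5.3,
         lambda_reorg: 12.6, delta_G_activation: 1.1,  rate_k: 1.04e+12}
      - {label: Tyr,  delta_E_vertical: 17.3,  delta_G_adiabatic: 3.9,
         lambda_reorg: 13.4, delta_G_activation: 5.6,  rate_k: 4.89e+08}
      - {label: Lin,  delta_E_vertical: 39.6,  delta_G_adiabatic: 17.4,
         lambda_reorg: 22.2, delta_G_activation: 17.7, rate_k: 6.89e-01}
    binding_sites:       # MMPBSA intercalation energies; printed K_b kept as reference
      - {label: CG-GC, delta_G_binding: -6.6,  K_b: 7.1e+04}
      - {label: AT-TA, delta_G_binding: -8.2,  K_b: 1.0e+06}
      - {label: TC-AG, delta_G_binding: -11.6, K_b: 2.1e+08}
  - label: AE-           # monoanion (C1 hydroxyl deprotonated)
    net_charge: -1
    pka: 11.41           # second deprotonation (C8 hydroxyl)
    states:
      - {multiplicity: singlet, index: 1, vertical_energy: 2.1314114,  # 581.7 nm, dark
         adiabatic_energy: 1.85,                                       # adiabatic: synthetic placeholder
         oscillator_strength: 1.414e-05}
      - {multiplicity: singlet, index: 2, vertical_energy: 2.3265753,  # 532.9 nm, bright
         adiabatic_energy: 2.05,                                       # adiabatic: synthetic placeholder
         oscillator_strength: 0.30}                                    # oscillator strength: synthetic placeholder
      - {multiplicity: triplet, index: 1, vertical_energy: 1.32,       # vertical: synthetic placeholder
         adiabatic_energy: 1.32}                                       # T1-S0 gap, printed
      - {multiplicity: triplet, index: 2, vertical_energy: 1.70,       # synthetic placeholder (below S1)
         adiabatic_energy: 1.70}
      - {multiplicity: triplet, index: 3, vertical_energy: 1.95,       # synthetic placeholder (above S1)
         adiabatic_energy: 1.95}
    soc:                 # printed magnitudes; components not stored (see docs)
      - {singlet_index: 2, triplet_index: 1, zeta_magnitude: 29.54}
      - {singlet_index: 1, triplet_index: 2, zeta_magnitude: 33.35}
    rates:
      isc:
        - {singlet_index: 1, triplet_index: 2, rate: 1.18e+11}
        - {singlet_index: 2, triplet_index: 1, rate: 1.90e+10}
        - {singlet_index: 2, triplet_index: 3, rate: 2.16e+07}
      k_F: 1.0e+08       # synthetic placeholder (unprinted)
      k_IC: 1.599091e+10 # synthetic placeholder consistent with the reported scenario-1 yield 0.88
      k_P: 1.5151515     # inverted from the printed 0.66 s lifetime
    tpa:
      - {state_index: 1, excitation_energy: 2.1199145,
         photon_wavelength_nm: 1169.7, sigma_corrected_GM: 17.1}
      - {state_index: 3, excitation_energy: 3.0899489,
         photon_wavelength_nm: 802.5, sigma_corrected_GM: 176.3}
    fedam: []
    reactions:           # printed table block for the anionic triplet / radical
      - {label: 10a,  delta_E_vertical: 17.7,  delta_G_adiabatic: 11.7,
         lambda_reorg: 6.0,  delta_G_activation: 13.1, rate_k: 1.51e+03}
      - {label: 10b,  delta_E_vertical: -11.9, delta_G_adiabatic: -17.2,
         lambda_reorg: 5.3,  delta_G_activation: 6.6,  rate_k: 9.17e+07}
      - {label: 10c,  delta_E_vertical: 20.7,  delta_G_adiabatic: 7.8,
         lambda_reorg: 12.9, delta_G_activation: 8.3,  rate_k: 5.04e+06}
      - {label: 10d,  delta_E_vertical: 5.0,   delta_G_adiabatic: -14.6,
         lambda_reorg: 19.6, delta_G_activation: 0.3,  rate_k: 3.64e+12}
      - {label: 2dG,  delta_E_vertical: 28.1,  delta_G_adiabatic: 20.1,
         lambda_reorg: 7.9,  delta_G_activation: 24.8, rate_k: 4.16e-06}
      - {label: Cys,  delta_E_vertical: 47.1,  delta_G_adiabatic: 28.1,
         lambda_reorg: 19.0, delta_G_activation: 29.2, rate_k: 2.36e-09}
      - {label: His+, delta_E_vertical: 54.0,  delta_G_adiabatic: 37.6,
         lambda_reorg: 16.5, delta_G_activation: 44.3, rate_k: 2.06e-20}
      - {label: Met,  delta_E_vertical: 36.2,  delta_G_adiabatic: 28.2,
         lambda_reorg: 8.0,  delta_G_activation: 40.9, rate_k: 6.28e-18}
      - {label: Trp,  delta_E_vertical: 21.6,  delta_G_adiabatic: 14.6,
         lambda_reorg: 7.1,  delta_G_activation: 16.6, rate_k: 4.27e+00}
      - {label: Tyr,  delta_E_vertical: 31.6,  delta_G_adiabatic: 23.8,
         lambda_reorg: 7.8,  delta_G_activation: 31.9, rate_k: 2.76e-11}
      - {label: Lin,  delta_E_vertical: 54.0,  delta_G_adiabatic: 37.3,
         lambda_reorg: 16.7, delta_G_activation: 43.6, rate_k: 7.10e-20}
    binding_sites: []    # the anion does not intercalate (electrostatic repulsion)
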