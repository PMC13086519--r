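vial:
  liquid_volume: 50.0
  headspace_volume: 70.0
  temperature: 20.0
  pressure: 1.0
  sample_volume: 1.0
  gas_table:
    O2:
      henry_cc: 0.033
      kla: equilibrium
    'NO':
      henry_cc: 0.047
      kla: equilibrium
    N2O:
      henry_cc: 0.632
      kla: equilibrium
    N2:
      henry_cc: 0.016
      kla: equilibrium
    He:
      henry_cc: 0.0086
      kla: equilibrium
phenotype:
  has_nap: yes
  has_nar: yes
  induction_o2_threshold: 14.0
  delay_h:
    nap: 0.1
    nar: 1.0
    nir: 1.0
    nor: 0.5
    nos: 0.0
  synthesis_rate:
    nap: 3.0
    nar: 2.0
    nir: 0.01
    nor: 2.0
    nos: 2.0
  second_synthesis_rate: 0.25
  vmax_e:
    o2: 250.0
    nap: 25.0
    nar: 100.0
    nir: 30.0
    nor: 800.0
    nos: 800.0
  km:
    o2: 30.0
    no3: 1000.0
    no2: 5.0
    'no': 0.3
    n2o: 3.0
  nir_no3_inhibition_ki: 20.0
  competition_weight:
    o2: 5.0
    nap: 1.0
    nar: 1.0
    nir: 1.0
    nor: 5.0
    nos: 5.0
  nir_subpop_fraction: 0.3
  second_induction: yes
  v_supply: 80.0
  yield: 0.0015
protocol:
  duration: 60.0
  initial_o2_percent: 1.0
  initial_no3: 100.0
  initial_no2: 0.0
  inoculum_biomass: 0.075
  preinduced: no
  spike_events: []
  sampling_gas:
  - 1.0
  - 2.0
  - 3.0
  - 4.0
  - 5.0
  - 6.0
  - 7.0
  - 8.0
  - 9.0
  - 10.0
  - 11.0
  - 12.0
  - 13.0
  - 14.0
  - 15.0
  - 16.0
  - 17.0
  - 18.0
  - 19.0
  - 20.0
  - 21.0
  - 22.0
  - 23.0
  - 24.0
  - 25.0
  - 26.0
  - 27.0
  - 28.0
  - 29.0
  - 30.0
  - 31.0
  - 32.0
  - 33.0
  - 34.0
  - 35.0
  - 36.0
  - 37.0
  - 38.0
  - 39.0
  - 40.0
  - 41.0
  - 42.0
  - 43.0
  - 44.0
  - 45.0
  - 46.0
  - 47.0
  - 48.0
  - 49.0
  - 50.0
  - 51.0
  - 52.0
  - 53.0
  - 54.0
  - 55.0
  - 56.0
  - 57.0
  - 58.0
  - 59.0
  - 60.0
  sampling_no2:
  - 0.0
  - 2.0
  - 4.0
  - 6.0
  - 8.0
  - 10.0
  - 12.0
  - 14.0
  - 16.0
  - 18.0
  - 20.0
  - 22.0
  - 24.0
  - 26.0
  - 28.0
  - 30.0
  - 32.0
  - 34.0
  - 36.0
  - 38.0
  - 40.0
  - 42.0
  - 44.0
  - 46.0
  - 48.0
  - 50.0
  - 52.0
  - 54.0
  - 56.0
  - 58.0
  - 60.0
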