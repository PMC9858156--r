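n_ambient: 1.0
wavelengths:
- 450.0
- 550.0
- 650.0
- 750.0
- 850.0
- 950.0
- 1050.0
layers:
- name: stratum_corneum
  thickness: 0.02
  mus:
  - 60.61
  - 41.74
  - 22.33
  - 15.05
  - 13.32
  - 9.5
  - 7.52
  g: 0.9
  'n': 1.37
  v_blood: 0.0
  v_water: 0.05
  v_mel: 0.0
  oxygen_saturation: 0.75
- name: epidermis
  thickness: 0.25
  mus:
  - 60.61
  - 41.74
  - 22.33
  - 15.05
  - 13.32
  - 9.5
  - 7.52
  g: 0.9
  'n': 1.37
  v_blood: 0.0
  v_water: 0.2
  v_mel: 0.2
  oxygen_saturation: 0.75
- name: papillary_dermis
  thickness: 0.1
  mus:
  - 60.61
  - 41.74
  - 22.33
  - 15.05
  - 13.32
  - 9.5
  - 7.52
  g: 0.9
  'n': 1.37
  v_blood: 0.04
  v_water: 0.5
  v_mel: 0.0
  oxygen_saturation: 0.75
- name: upper_blood_net_dermis
  thickness: 0.08
  mus:
  - 60.61
  - 41.74
  - 22.33
  - 15.05
  - 13.32
  - 9.5
  - 7.52
  g: 0.9
  'n': 1.37
  v_blood: 0.3
  v_water: 0.6
  v_mel: 0.0
  oxygen_saturation: 0.75
- name: reticular_dermis
  thickness: 0.2
  mus:
  - 60.61
  - 41.74
  - 22.33
  - 15.05
  - 13.32
  - 9.5
  - 7.52
  g: 0.9
  'n': 1.37
  v_blood: 0.04
  v_water: 0.7
  v_mel: 0.0
  oxygen_saturation: 0.75
- name: deep_blood_net_dermis
  thickness: 0.3
  mus:
  - 60.61
  - 41.74
  - 22.33
  - 15.05
  - 13.32
  - 9.5
  - 7.52
  g: 0.9
  'n': 1.37
  v_blood: 0.1
  v_water: 0.7
  v_mel: 0.0
  oxygen_saturation: 0.75
- name: subcutaneous_tissue
  thickness: 2.0
  mus:
  - 60.61
  - 41.74
  - 22.33
  - 15.05
  - 13.32
  - 9.5
  - 7.52
  g: 0.9
  'n': 1.37
  v_blood: 0.05
  v_water: 0.7
  v_mel: 0.0
  oxygen_saturation: 0.75
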