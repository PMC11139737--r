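{
  "name": "Rb-82",
  "half_life_s": 76,
  "positron_yield": 0.954,
  "mean_energy_per_decay_MeV": 1.41,
  "photon_fraction": 0,
  "comment": "Half-life per the imaging protocol; emission-energy fields are nuclear-data configuration (ICRP 107 class): mean positron energy ~1.48 MeV at 95.4% yield, folded into mean_energy_per_decay_MeV as the locally deposited component. Annihilation and prompt photons are excluded from local deposition (photon_fraction refers to kernel transport)."
}
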