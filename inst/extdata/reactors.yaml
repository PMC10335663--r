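# Reactor library: nominal liquid volumes and measured whole-tube oxygen
# permeabilities (mg/(min*bar)); wall area and thickness are absorbed into r.
plastic_centrifuge_50ml:
  volume_L: 0.050
  permeability_r: 3.02e-03
glass_voa_40ml:
  volume_L: 0.040
  permeability_r: 1.75e-03
double_ended_voa_40ml:
  volume_L: 0.040
  permeability_r: 9.44e-04
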