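# Tissue parameter presets for the synthetic generator.
#
# potato: calibrated to published summary measurements of russet potato
#   tissue under 1 us and 10 us bipolar pulses (bulk 0.13 / 0.04 S/m,
#   electroporated plateaus 0.55 / 0.67 S/m); the transition field (500
#   V/cm) is the midpoint of the bracketing 250-750 V/cm observations and
#   the width (150 V/cm) spans that bracket.
# cardiac: SYNTHETIC qualitative stand-in for ventricular myocardium
#   (higher bulk conductivity); values are placeholders, not measurements.
potato:
  sigma_bulk_by_pw: {"1": 0.13, "10": 0.04}
  sigma_max_by_pw: {"1": 0.55, "10": 0.67}
  E_th: 500.0          # V/cm
  transition_width: 150.0  # V/cm
  tau_mem: 1.0         # us, membrane-charging time constant (0.7-1.4 us range)
  cap_transient_frac: 0.1
  cap_transient_tau: 0.2   # us
  noise_rel: 0.01
cardiac:
  sigma_bulk_by_pw: {"1": 0.35, "10": 0.20}
  sigma_max_by_pw: {"1": 0.75, "10": 0.85}
  E_th: 500.0
  transition_width: 150.0
  tau_mem: 1.0
  cap_transient_frac: 0.1
  cap_transient_tau: 0.2
  noise_rel: 0.01
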