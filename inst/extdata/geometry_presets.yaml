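# Electrode geometry presets.
# Units: plate thickness/diameter and needle radius/insertion in mm;
# needle spacing and exposure in cm.
#
# cardiac_needle follows the methods text (4 mm exposure, 8 mm insertion);
# cardiac_needle_caption carries the alternative figure-caption values
# (5 mm exposure, 10 mm insertion) reported for the same setup.
potato_plate:
  kind: plate
  thickness: 6.0
  diameter: 6.0
  thickness_sd: 0.2
potato_needle_1.0cm:
  kind: needle_pair
  spacing: 1.0
  radius: 0.5
  exposure: 1.0
  insertion: 25.0
potato_needle_1.5cm:
  kind: needle_pair
  spacing: 1.5
  radius: 0.5
  exposure: 1.0
  insertion: 25.0
cardiac_needle:
  kind: needle_pair
  spacing: 1.0
  radius: 0.225
  exposure: 0.4
  insertion: 8.0
cardiac_needle_caption:
  kind: needle_pair
  spacing: 1.0
  radius: 0.225
  exposure: 0.5
  insertion: 10.0
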