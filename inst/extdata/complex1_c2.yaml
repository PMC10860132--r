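# Three-spin transfer system of the pyruvate complex 1: the two hydride
# protons and the ketone carbon (2-13C label), at 9.4 T.
field_proton_mhz: 400.0
spins:
  - label: Ha
    isotope: H1
    shift_ppm: -29.10
  - label: Hb
    isotope: H1
    shift_ppm: -27.20
  - label: C2
    isotope: C13
    shift_ppm: 206.59
j_couplings:
  - {a: Ha, b: Hb, j_hz: -10.48}
  - {a: Ha, b: C2, j_hz: 0.93}
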