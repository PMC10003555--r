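# 8-step PLOR schedule for the adenine riboswitch template.
# Step 1 uses an explicit (non-stoichiometric) NTP excess to drive initiation;
# steps 2-7 are stoichiometric at fold 1; step 4 carries the Cy3-UTP label.
dna_uM: 5
rnap_uM: 5
steps:
  - included: [A, G, U]
    explicit: {A: 400, G: 600, U: 64}
    condition: {temperature_C: 37, duration_min: 15}
  - included: [A, C, U]
    fold: 1
  - included: [A, G, U]
    fold: 1
  - included: [A, C, U]
    fold: 1
    label: {base: U, name: Cy3}
  - included: [A, C, G]
    fold: 1
  - included: [A, C, U]
    fold: 1
  - included: [A, G, U]
    fold: 1
  - included: [A, C, G, U]
    fold: 1
    condition: {Mg_mM: 6, adenine_mM: 0}
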