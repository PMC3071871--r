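# Association-study scoring table: score in 0..4 from the number of
# studies for a gene crossed with the proportion reporting positive
# association.  Bands are lower-edge inclusive; the matrix must be
# monotone non-decreasing along both axes (validated at load).
# A single positive study scores 1: extreme positive proportions are
# damped when the study count is small.
study_bands: [0, 1, 3, 6, 11]
proportion_bands: [0.0, 0.25, 0.5, 0.75]
scores:
  - [0, 0, 0, 0]
  - [1, 1, 1, 1]
  - [1, 2, 2, 2]
  - [1, 2, 3, 3]
  - [1, 2, 3, 4]
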