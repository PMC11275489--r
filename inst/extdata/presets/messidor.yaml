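# MESSIDOR-like cohort preset: per-grade stratum sizes and per-quadrant
# lesion count distributions (mean, sd) for microaneurysms (MA) and
# hemorrhages (HEM). Quadrants: superior (up), temporal, nasal,
# inferior (down).
name: messidor
grades:
  Mild:
    n_images: 182
    MA:
      superior: {mean: 1.25, sd: 0.71}
      temporal: {mean: 1.01, sd: 1.08}
      nasal:    {mean: 0.38, sd: 0.62}
      inferior: {mean: 0.86, sd: 0.92}
    HEM:
      superior: {mean: 1.07, sd: 0.27}
      temporal: {mean: 1.53, sd: 0.77}
      nasal:    {mean: 1.12, sd: 0.48}
      inferior: {mean: 1.17, sd: 0.64}
  Moderate:
    n_images: 162
    MA:
      superior: {mean: 1.64, sd: 0.92}
      temporal: {mean: 1.50, sd: 2.07}
      nasal:    {mean: 0.65, sd: 1.13}
      inferior: {mean: 1.01, sd: 1.27}
    HEM:
      superior: {mean: 1.26, sd: 0.50}
      temporal: {mean: 1.69, sd: 0.98}
      nasal:    {mean: 1.29, sd: 0.55}
      inferior: {mean: 1.31, sd: 0.58}
  Severe:
    n_images: 261
    MA:
      superior: {mean: 2.47, sd: 2.80}
      temporal: {mean: 5.50, sd: 6.52}
      nasal:    {mean: 1.86, sd: 2.22}
      inferior: {mean: 3.10, sd: 3.23}
    HEM:
      superior: {mean: 2.08, sd: 3.44}
      temporal: {mean: 4.98, sd: 6.55}
      nasal:    {mean: 1.96, sd: 2.66}
      inferior: {mean: 2.18, sd: 3.22}
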