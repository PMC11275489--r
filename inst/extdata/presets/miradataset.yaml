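# MIRADATASET-like cohort preset: 300 images sampled per DR grade, with
# per-quadrant lesion count distributions (mean, sd).
name: miradataset
grades:
  Mild:
    n_images: 300
    MA:
      superior: {mean: 1.65, sd: 1.10}
      temporal: {mean: 1.18, sd: 1.51}
      nasal:    {mean: 1.86, sd: 1.16}
      inferior: {mean: 1.01, sd: 1.25}
    HEM:
      superior: {mean: 1.34, sd: 0.76}
      temporal: {mean: 1.39, sd: 0.80}
      nasal:    {mean: 1.24, sd: 0.56}
      inferior: {mean: 1.29, sd: 0.64}
  Moderate:
    n_images: 300
    MA:
      superior: {mean: 1.04, sd: 1.33}
      temporal: {mean: 2.23, sd: 2.85}
      nasal:    {mean: 1.47, sd: 1.72}
      inferior: {mean: 1.76, sd: 2.05}
    HEM:
      superior: {mean: 1.52, sd: 0.85}
      temporal: {mean: 1.76, sd: 1.25}
      nasal:    {mean: 1.55, sd: 0.88}
      inferior: {mean: 1.45, sd: 0.85}
  Severe:
    n_images: 300
    MA:
      superior: {mean: 4.72, sd: 4.19}
      temporal: {mean: 7.51, sd: 7.72}
      nasal:    {mean: 5.16, sd: 4.78}
      inferior: {mean: 7.46, sd: 7.67}
    HEM:
      superior: {mean: 2.28, sd: 3.25}
      temporal: {mean: 3.13, sd: 4.81}
      nasal:    {mean: 2.47, sd: 3.79}
      inferior: {mean: 3.19, sd: 5.30}
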