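{
  "name": "paper_like",
  "comment": "Synthetic stand-in for the FIA-grid study landscape. rows*cols approximates the 13,820-cell grid; invaded_fraction 0.027 of cells with the heavy-tailed occupancy mixture gives ~0.4% of total area initially invaded (the 2003-snapshot analog). r_range calibrated so uncontrolled 20-year invaded area grows roughly exponentially with expansion on the order of 18x.",
  "rows": 118,
  "cols": 117,
  "side_m": 4927,
  "forest_fraction": 0.9,
  "r_range": [0.2, 0.8],
  "autocorr_m": 15000,
  "class_probs": [0.08, 0.12, 0.18, 0.22, 0.20, 0.12, 0.08],
  "invaded_fraction": 0.027,
  "band_fraction": 0.25,
  "tail_fraction": 0.15,
  "body_mean": 5,
  "tail_min": 50
}
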