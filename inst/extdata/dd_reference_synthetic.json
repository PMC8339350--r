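{
  "name": ["DDref77_synthetic"],
  "note": ["Synthetic family-typical reference profile; not derived from any deposited entry or database sequence. Regions are 0-based half-open."],
  "regions": {
    "nflank": [0, 10],
    "helix1": [10, 22],
    "loop": [22, 27],
    "helix2": [27, 40],
    "cflank": [40, 77]
  },
  "dimer_positions": [12, 13, 16, 17, 20, 28, 31, 34, 35],
  "docking_positions": [3, 14, 24, 30, 33],
  "motif_positions": {
    "DPY30": [],
    "R1D2": [22, 25],
    "R2D2": [10, 22, 25, 30, 31]
  }
}
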