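{
  "chrom": "chrX",
  "scale": 1,
  "extent": [99000000, 103500000],
  "families": {
    "C": "CD",
    "A1a": "A",
    "A2": "inner",
    "A3": "inner",
    "A1b": "A",
    "D": "CD"
  },
  "approximate": ["A2", "A3"],
  "pairs": [
    {
      "left": "C",
      "right": "D",
      "family": "CD",
      "identity": 0.93,
      "inverted": true
    },
    {
      "left": "A1a",
      "right": "A1b",
      "family": "A",
      "identity": 0.99,
      "inverted": true
    },
    {
      "left": "A2",
      "right": "A3",
      "family": "inner",
      "identity": 0.87,
      "inverted": true
    }
  ],
  "anchors": {
    "trp_end": 103223670,
    "dup_end": 103324334
  },
  "digest": {
    "enzyme": "BssSI",
    "engineered_to_band_sizes": true,
    "sites": [103219670, 103244670, 103319684, 103348684],
    "probe": [103220170, 103220670]
  },
  "qpcr": {
    "black": [
      [103232670, 103232820],
      [103335534, 103335684]
    ],
    "red": [
      [103220670, 103220820]
    ],
    "red_black": [
      [103223590, 103223740]
    ]
  }
}
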