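{
  "taxon_profile": "julidan",
  "k": 4,
  "P": 2,
  "t": 5,
  "markers": [
    {
      "ps": 1,
      "depth": 2,
      "index": 3
    },
    {
      "ps": 2,
      "depth": 2,
      "index": 3
    }
  ],
  "anterior_marker_positions": 8
}
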