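{
  "id": "minimal-example",
  "format": "Biological Observation Matrix 1.0.0",
  "format_url": "http://biom-format.org",
  "type": "OTU table",
  "generated_by": "mbstates-fixture",
  "date": "2026-01-01T00:00:00",
  "matrix_type": "dense",
  "matrix_element_type": "int",
  "shape": [3, 2],
  "rows": [
    {"id": "OTU1", "metadata": {"taxonomy": ["k__Bacteria", "p__Firmicutes", "c__Clostridia", "o__Clostridiales", "f__Lachnospiraceae", "g__Blautia", "s__sp1"]}},
    {"id": "OTU2", "metadata": {"taxonomy": ["k__Bacteria", "p__Firmicutes", "c__Clostridia", "o__Clostridiales", "f__Lachnospiraceae", "g__Roseburia", "s__sp2"]}},
    {"id": "OTU3", "metadata": {"taxonomy": ["k__Bacteria", "p__Bacteroidetes", "c__Bacteroidia", "o__Bacteroidales", "f__Bacteroidaceae", "g__Bacteroides", "s__sp3"]}}
  ],
  "columns": [
    {"id": "SampleA", "metadata": null},
    {"id": "SampleB", "metadata": null}
  ],
  "data": [[5, 20], [3, 0], [2, 80]]
}
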