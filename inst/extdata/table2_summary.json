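{
  "edition_totals": {
    "2010_GM_SE": 1478,
    "2011_GM_SE": 1248,
    "2012_GM_SE": 1220
  },
  "superset_total": 3007,
  "classified_phyla_per_edition": {
    "2010_GM_SE": 9,
    "2011_GM_SE": 16,
    "2012_GM_SE": 11
  },
  "tr_printed": {
    "2010_GM_SE": 39.51,
    "2011_GM_SE": 54.3,
    "2012_GM_SE": 28.1
  },
  "tr_max_printed": 101.85,
  "census": {
    "singletons": 2164,
    "doubletons": 747,
    "tripletons": 96
  },
  "tripleton_phyla": {
    "Proteobacteria": 55,
    "Bacteroidetes": 11,
    "Cyanobacteria": 3,
    "Unclassified Bacteria": 27
  }
}
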