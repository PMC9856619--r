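[
  {
    "name": "NR METASTATIC LN",
    "vtype": "ordinal",
    "levels": 10,
    "codes": [0, 1, 2, 3, 4, 5, 6, 7, 8, 9],
    "labels": ["0", "1", "2", "3", "4", "5", "6", "7", "8", "9"]
  },
  {
    "name": "TOTAL NR DISSECTED LN",
    "vtype": "ordinal",
    "levels": 10,
    "codes": [0, 1, 2, 3, 4, 5, 6, 7, 8, 9],
    "labels": ["0", "1", "2", "3", "4", "5", "6", "7", "8", "9"]
  },
  {
    "name": "RT TYPE",
    "vtype": "categorical",
    "levels": 4,
    "codes": [0, 1, 2, 3],
    "labels": ["0", "1", "2", "3"]
  },
  {
    "name": "HR DRUG",
    "vtype": "categorical",
    "levels": 7,
    "codes": [0, 1, 2, 3, 4, 5, 6],
    "labels": ["0", "1", "2", "3", "4", "5", "6"]
  },
  {
    "name": "HISTOTYPE",
    "vtype": "categorical",
    "levels": 4,
    "codes": [0, 1, 2, 3],
    "labels": ["0", "1", "2", "3"]
  },
  {
    "name": "G",
    "vtype": "ordinal",
    "levels": 3,
    "codes": [1, 2, 3],
    "labels": ["1", "2", "3"]
  },
  {
    "name": "T",
    "vtype": "ordinal",
    "levels": 4,
    "codes": [1, 2, 3, 4],
    "labels": ["1", "2", "3", "4"]
  },
  {
    "name": "N",
    "vtype": "ordinal",
    "levels": 4,
    "codes": [0, 1, 2, 3],
    "labels": ["0", "1", "2", "3"]
  },
  {
    "name": "MOLECULAR SUBTYPE",
    "vtype": "categorical",
    "levels": 4,
    "codes": [0, 1, 2, 3],
    "labels": ["0", "1", "2", "3"]
  },
  {
    "name": "AGE",
    "vtype": "continuous"
  },
  {
    "name": "BMI",
    "vtype": "continuous"
  },
  {
    "name": "BREAST SURGERY",
    "vtype": "binary",
    "levels": 2,
    "codes": [0, 1],
    "labels": ["0", "1"]
  },
  {
    "name": "SIDE",
    "vtype": "binary",
    "levels": 2,
    "codes": [1, 2],
    "labels": ["1", "2"]
  },
  {
    "name": "Ki67",
    "vtype": "binary",
    "levels": 2,
    "codes": [0, 1],
    "labels": ["0", "1"]
  },
  {
    "name": "TAXANE BASED CT",
    "vtype": "binary",
    "levels": 2,
    "codes": [0, 1],
    "labels": ["0", "1"]
  },
  {
    "name": "HT",
    "vtype": "binary",
    "levels": 2,
    "codes": [0, 1],
    "labels": ["0", "1"]
  },
  {
    "name": "TTZ",
    "vtype": "binary",
    "levels": 2,
    "codes": [0, 1],
    "labels": ["0", "1"]
  },
  {
    "name": "LVI",
    "vtype": "binary",
    "levels": 2,
    "codes": [0, 1],
    "labels": ["0", "1"]
  },
  {
    "name": "ECE",
    "vtype": "binary",
    "levels": 2,
    "codes": [0, 1],
    "labels": ["0", "1"]
  },
  {
    "name": "ER",
    "vtype": "binary",
    "levels": 2,
    "codes": [0, 1],
    "labels": ["0", "1"]
  },
  {
    "name": "HER2",
    "vtype": "binary",
    "levels": 2,
    "codes": [0, 1],
    "labels": ["0", "1"]
  },
  {
    "name": "NCD",
    "vtype": "binary",
    "levels": 2,
    "codes": [0, 1],
    "labels": ["0", "1"]
  },
  {
    "name": "PR",
    "vtype": "binary",
    "levels": 2,
    "codes": [0, 1],
    "labels": ["0", "1"]
  }
]
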