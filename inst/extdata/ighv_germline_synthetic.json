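{
  "version_tag": "ighvrep-synthetic-1.0",
  "alleles": {
    "IGHV1-2*01": {
      "family": "IGHV1",
      "gene": "IGHV1-2",
      "gap_positions": [31, 32, 33, 61],
      "region_bounds": {
        "FR1": [0, 78],
        "CDR1": [78, 105],
        "FR2": [105, 156],
        "CDR2": [156, 183],
        "FR3": [183, 300]
      },
      "motif_sites": {}
    },
    "IGHV1-18*01": {
      "family": "IGHV1",
      "gene": "IGHV1-18",
      "gap_positions": [31, 32, 33, 61],
      "region_bounds": {
        "FR1": [0, 78],
        "CDR1": [78, 105],
        "FR2": [105, 156],
        "CDR2": [156, 183],
        "FR3": [183, 300]
      },
      "motif_sites": {}
    },
    "IGHV1-46*01": {
      "family": "IGHV1",
      "gene": "IGHV1-46",
      "gap_positions": [31, 32, 33, 61],
      "region_bounds": {
        "FR1": [0, 78],
        "CDR1": [78, 105],
        "FR2": [105, 156],
        "CDR2": [156, 183],
        "FR3": [183, 300]
      },
      "motif_sites": {}
    },
    "IGHV1-69*01": {
      "family": "IGHV1",
      "gene": "IGHV1-69",
      "gap_positions": [31, 32, 33, 61],
      "region_bounds": {
        "FR1": [0, 78],
        "CDR1": [78, 105],
        "FR2": [105, 156],
        "CDR2": [156, 183],
        "FR3": [183, 300]
      },
      "motif_sites": {}
    },
    "IGHV1-69*02": {
      "family": "IGHV1",
      "gene": "IGHV1-69",
      "gap_positions": [31, 32, 33, 61],
      "region_bounds": {
        "FR1": [0, 78],
        "CDR1": [78, 105],
        "FR2": [105, 156],
        "CDR2": [156, 183],
        "FR3": [183, 300]
      },
      "motif_sites": {}
    },
    "IGHV2-5*01": {
      "family": "IGHV2",
      "gene": "IGHV2-5",
      "gap_positions": [32, 33, 60, 61, 62],
      "region_bounds": {
        "FR1": [0, 78],
        "CDR1": [78, 108],
        "FR2": [108, 159],
        "CDR2": [159, 180],
        "FR3": [180, 297]
      },
      "motif_sites": {}
    },
    "IGHV2-70*01": {
      "family": "IGHV2",
      "gene": "IGHV2-70",
      "gap_positions": [32, 33, 60, 61, 62],
      "region_bounds": {
        "FR1": [0, 78],
        "CDR1": [78, 108],
        "FR2": [108, 159],
        "CDR2": [159, 180],
        "FR3": [180, 297]
      },
      "motif_sites": {}
    },
    "IGHV3-7*01": {
      "family": "IGHV3",
      "gene": "IGHV3-7",
      "gap_positions": [31, 32, 33, 60, 61, 62],
      "region_bounds": {
        "FR1": [0, 78],
        "CDR1": [78, 105],
        "FR2": [105, 156],
        "CDR2": [156, 177],
        "FR3": [177, 294]
      },
      "motif_sites": {}
    },
    "IGHV3-23*01": {
      "family": "IGHV3",
      "gene": "IGHV3-23",
      "gap_positions": [31, 32, 33, 60, 61, 62],
      "region_bounds": {
        "FR1": [0, 78],
        "CDR1": [78, 105],
        "FR2": [105, 156],
        "CDR2": [156, 177],
        "FR3": [177, 294]
      },
      "motif_sites": {}
    },
    "IGHV3-23*02": {
      "family": "IGHV3",
      "gene": "IGHV3-23",
      "gap_positions": [31, 32, 33, 60, 61, 62],
      "region_bounds": {
        "FR1": [0, 78],
        "CDR1": [78, 105],
        "FR2": [105, 156],
        "CDR2": [156, 177],
        "FR3": [177, 294]
      },
      "motif_sites": {}
    },
    "IGHV3-30*01": {
      "family": "IGHV3",
      "gene": "IGHV3-30",
      "gap_positions": [31, 32, 33, 60, 61, 62],
      "region_bounds": {
        "FR1": [0, 78],
        "CDR1": [78, 105],
        "FR2": [105, 156],
        "CDR2": [156, 177],
        "FR3": [177, 294]
      },
      "motif_sites": {}
    },
    "IGHV3-48*01": {
      "family": "IGHV3",
      "gene": "IGHV3-48",
      "gap_positions": [31, 32, 33, 60, 61, 62],
      "region_bounds": {
        "FR1": [0, 78],
        "CDR1": [78, 105],
        "FR2": [105, 156],
        "CDR2": [156, 177],
        "FR3": [177, 294]
      },
      "motif_sites": {}
    },
    "IGHV4-4*01": {
      "family": "IGHV4",
      "gene": "IGHV4-4",
      "gap_positions": [31, 32, 33, 73],
      "region_bounds": {
        "FR1": [0, 78],
        "CDR1": [78, 105],
        "FR2": [105, 156],
        "CDR2": [156, 186],
        "FR3": [186, 300]
      },
      "motif_sites": {}
    },
    "IGHV4-34*01": {
      "family": "IGHV4",
      "gene": "IGHV4-34",
      "gap_positions": [31, 32, 33, 73],
      "region_bounds": {
        "FR1": [0, 78],
        "CDR1": [78, 105],
        "FR2": [105, 156],
        "CDR2": [156, 186],
        "FR3": [186, 300]
      },
      "motif_sites": {
        "AVY": [69, 78],
        "NHS": [159, 168]
      }
    },
    "IGHV4-34*02": {
      "family": "IGHV4",
      "gene": "IGHV4-34",
      "gap_positions": [31, 32, 33, 73],
      "region_bounds": {
        "FR1": [0, 78],
        "CDR1": [78, 105],
        "FR2": [105, 156],
        "CDR2": [156, 186],
        "FR3": [186, 300]
      },
      "motif_sites": {
        "AVY": [69, 78],
        "NHS": [159, 168]
      }
    },
    "IGHV4-39*01": {
      "family": "IGHV4",
      "gene": "IGHV4-39",
      "gap_positions": [31, 32, 33, 73],
      "region_bounds": {
        "FR1": [0, 78],
        "CDR1": [78, 105],
        "FR2": [105, 156],
        "CDR2": [156, 186],
        "FR3": [186, 300]
      },
      "motif_sites": {}
    },
    "IGHV4-59*01": {
      "family": "IGHV4",
      "gene": "IGHV4-59",
      "gap_positions": [31, 32, 33, 73],
      "region_bounds": {
        "FR1": [0, 78],
        "CDR1": [78, 105],
        "FR2": [105, 156],
        "CDR2": [156, 186],
        "FR3": [186, 300]
      },
      "motif_sites": {}
    },
    "IGHV5-51*01": {
      "family": "IGHV5",
      "gene": "IGHV5-51",
      "gap_positions": [32, 33, 61, 62],
      "region_bounds": {
        "FR1": [0, 78],
        "CDR1": [78, 108],
        "FR2": [108, 159],
        "CDR2": [159, 183],
        "FR3": [183, 300]
      },
      "motif_sites": {}
    },
    "IGHV5-51*02": {
      "family": "IGHV5",
      "gene": "IGHV5-51",
      "gap_positions": [32, 33, 61, 62],
      "region_bounds": {
        "FR1": [0, 78],
        "CDR1": [78, 108],
        "FR2": [108, 159],
        "CDR2": [159, 183],
        "FR3": [183, 300]
      },
      "motif_sites": {}
    },
    "IGHV6-1*01": {
      "family": "IGHV6",
      "gene": "IGHV6-1",
      "gap_positions": 73,
      "region_bounds": {
        "FR1": [0, 78],
        "CDR1": [78, 114],
        "FR2": [114, 165],
        "CDR2": [165, 195],
        "FR3": [195, 309]
      },
      "motif_sites": {}
    },
    "IGHV7-4-1*01": {
      "family": "IGHV7",
      "gene": "IGHV7-4-1",
      "gap_positions": [31, 32, 61],
      "region_bounds": {
        "FR1": [0, 78],
        "CDR1": [78, 108],
        "FR2": [108, 159],
        "CDR2": [159, 186],
        "FR3": [186, 303]
      },
      "motif_sites": {}
    },
    "IGHV7-81*01": {
      "family": "IGHV7",
      "gene": "IGHV7-81",
      "gap_positions": [31, 32, 61],
      "region_bounds": {
        "FR1": [0, 78],
        "CDR1": [78, 108],
        "FR2": [108, 159],
        "CDR2": [159, 186],
        "FR3": [186, 303]
      },
      "motif_sites": {}
    }
  },
  "j_genes": {
    "IGHJ4*01": {
      "nt": "TGGGGCCAAGGAACCCTGGTCACCGTCTCCTCA"
    },
    "IGHJ6*01": {
      "nt": "TGGGGGCAAGGGACCACGGTGACCGTGAGCTCA"
    }
  },
  "c_primers": {
    "IgG": "GCTTCCACCAAGGGCCCATC",
    "IgM": "GGGAGTGCATCCGCCCCAAC"
  }
}
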