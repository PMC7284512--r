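{
  "format": "liriopogon-panel-1",
  "comment": "rbcL haplotype key for Liriope/Ophiopogon barcode verification. Coordinates are 1-based in the packaged rbcL reference below (rbcLa = 1-500, rbcLb = 501-900). Cell values reconstruct the published per-type SNP counts; the ITS triplet orientation is a synthetic, internally consistent choice (see package vignette).",
  "reference_sequences": {
    "rbcL": "AAGGCTTTCTTACAGCGACTCACTGCGTCAAATGCGCGGATAAATTCAATAGAGCAGGACATCCTTTTGCCTAATGTAGGAAACGGGCCAGGACCAAGGGGGGTAACATCGAGTGAGAACAACATGATAAATGTTATGCTCTTTCCGAACCTCCGCGTCGAATCACGTGACATGGCGCCAGAAGTACACACTTTACTACAGCTCCAAGCTTAAACCGCGGTTAACTTCGGGTCGCCAAAAGAAAGTTGTAAGAAGTAATTCACGGTGCAAGTAAAGCGACGCCTGGAATGCAATGATTTTTCGGGTATTCTTACAATCCACGGTGAATACCATTCTCCTTATGCTGCTATTCACTATCCATTAATAGGAAGTTAGAAAGGAGGTCAGGATTGGTAGTTTCCCACCGGGCCACATAATTGTCTAGAATATAGGTGACCTGATAGGTCGTAGCGTTGACCTTGAAACCACCCAAAGGATGTTTTGGCGTGGAGGACACGAATGTGTTAAGACAACTCTACCAATTGTTAGCTGACGACAGTACTTATAGCTCGCGTACGTATCGCGACACCAACTGAATTGGGAATTATGCAAAAAGGACTGTGACTCGAAGGATCAGTATCCGTTCGCGCTAACCGTTTCATGTATTTGATGGCTATAAAACGCCTTGGCAATCCCTTACTGGCATGAATGTGTTCGAGTCGGTCGTTGACCACTGAATTCTATCATATCCAAATCGTCCTTTCAAAGCATTATGATACTCGTCTTCAACGGCACGTTGCCCATATCGGCGTTCTCATACTGTCGGCTGGTCCGGAATAAAGAATTGCCCTTCACTGAAAAGCTGGGAGAGGTTGACCTTATGAACCAAACACTTGTGAAGAATAGCCTTTACTGTGCAGT",
    "ITS": "TAGCCTGTGGGAACGGAGAATGGCCTTCGAGTGGGTCGTGAATGCAGCTAGCGGCCGCGGCTAAGACTAGAAGGCAGACATTTGACCCACGCATTCATGACCCGGTGTCATGTTGACAGTTCGGGGGGTTTTTAAGTGTCCTATGCCTGGAAGTAGGCTCACGCAGCCCGGAAGGTACTACCTCGCGCACCTGCCGCAGCTCCTGTGAGATTCATCGTGTTGGTTCATACCGCTCCTATGATTGCGGTATCGCCATGCCCGGCGTTATCTCTGCGTGCGCAGACTGTCAGCCGTACCATTAGCAACTCATTAGGCATATCGCGACCGATGACACTTTACCGAGGATGAAGGGACGGACTTGTAAACTTGTGGGCGCTCTGCGCTCCAGCCTGAGTGGACGACTGCATGGTTGATGCTCTAGGGCAGGAGGGCCTTGTGTTATGCCCAGCATTGTCATATGTCCTGACAATTGAGCGGTCGTCATCCCGGCAATCTCCCAGAGAGCAGGCGCGAGGAAGTTGCAAAGTTGATTGGACGATCGCCGCGTCTTCTGTTCCCACAATTTAATGAGGCCAGACATTGCGAAACAGCTCGAGCGAT"
  },
  "regions": {
    "rbcLa": [1, 500],
    "rbcLb": [501, 900]
  },
  "consensus": "Type 2",
  "positions": [
    {
      "locus": "rbcL",
      "position": 172
    },
    {
      "locus": "rbcL",
      "position": 216
    },
    {
      "locus": "rbcL",
      "position": 392
    },
    {
      "locus": "rbcL",
      "position": 431
    },
    {
      "locus": "rbcL",
      "position": 512
    },
    {
      "locus": "rbcL",
      "position": 538
    },
    {
      "locus": "rbcL",
      "position": 566
    },
    {
      "locus": "rbcL",
      "position": 601
    },
    {
      "locus": "rbcL",
      "position": 640
    },
    {
      "locus": "rbcL",
      "position": 673
    },
    {
      "locus": "rbcL",
      "position": 702
    },
    {
      "locus": "rbcL",
      "position": 731
    },
    {
      "locus": "rbcL",
      "position": 760
    },
    {
      "locus": "rbcL",
      "position": 802
    },
    {
      "locus": "rbcL",
      "position": 845
    }
  ],
  "haplotypes": [
    {
      "name": "Type 1",
      "taxa": [
        "Ophiopogon japonicus (I)"
      ],
      "bases": {
        "172": "C",
        "216": "T",
        "392": "G",
        "431": "G",
        "512": "G",
        "538": "A",
        "566": "C",
        "601": "T",
        "640": "A",
        "673": "C",
        "702": "G",
        "731": "A",
        "760": "C",
        "802": "T",
        "845": "G"
      }
    },
    {
      "name": "Type 2",
      "taxa": [
        "Ophiopogon japonicus (II)",
        "Ophiopogon bodinieri"
      ],
      "bases": {
        "172": "A",
        "216": "C",
        "392": "G",
        "431": "G",
        "512": "A",
        "538": "G",
        "566": "C",
        "601": "T",
        "640": "A",
        "673": "C",
        "702": "G",
        "731": "A",
        "760": "C",
        "802": "T",
        "845": "G"
      }
    },
    {
      "name": "Type 3",
      "taxa": [
        "Ophiopogon planiscapus",
        "Ophiopogon chingii"
      ],
      "bases": {
        "172": "A",
        "216": "C",
        "392": "A",
        "431": "G",
        "512": "A",
        "538": "G",
        "566": "T",
        "601": "T",
        "640": "A",
        "673": "C",
        "702": "G",
        "731": "A",
        "760": "C",
        "802": "T",
        "845": "G"
      }
    },
    {
      "name": "Type 4",
      "taxa": [
        "Ophiopogon longifolius"
      ],
      "low_confidence": true,
      "bases": {
        "172": "A",
        "216": "C",
        "392": "G",
        "431": "G",
        "512": "A",
        "538": "G",
        "566": "C",
        "601": "T",
        "640": "A",
        "673": "C",
        "702": "T",
        "731": "C",
        "760": "C",
        "802": "T",
        "845": "G"
      }
    },
    {
      "name": "Type 5",
      "taxa": [
        "Ophiopogon jaburan"
      ],
      "bases": {
        "172": "A",
        "216": "C",
        "392": "G",
        "431": "G",
        "512": "A",
        "538": "G",
        "566": "C",
        "601": "T",
        "640": "A",
        "673": "C",
        "702": "G",
        "731": "A",
        "760": "A",
        "802": "G",
        "845": "C"
      }
    },
    {
      "name": "Type 6",
      "taxa": [
        "Liriope muscari",
        "Liriope spicata"
      ],
      "bases": {
        "172": "T",
        "216": "C",
        "392": "A",
        "431": "A",
        "512": "G",
        "538": "G",
        "566": "C",
        "601": "C",
        "640": "G",
        "673": "T",
        "702": "G",
        "731": "A",
        "760": "C",
        "802": "T",
        "845": "G"
      }
    }
  ],
  "genus_position": {
    "locus": "rbcL",
    "position": 431,
    "alleles": {
      "Ophiopogon": "G",
      "Liriope": "A"
    }
  },
  "its_triplet": {
    "positions": [46, 231, 545],
    "patterns": {
      "Ophiopogon planiscapus": ["A", "C", "C"],
      "Ophiopogon bodinieri": ["G", "T", "T"]
    },
    "orientation": "synthetic"
  }
}
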