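{
  "comment": "Executable evolutionary scenario for the vertebrate TRPV family. Branches are identified by the child-node label of the packaged species tree; events on one branch apply in listed order. The two basal vertebrate WGD rounds sit on the vertebrate stem (root branch), the teleost round on the teleost stem, the salmonid round on the Atlantic salmon terminal branch.",
  "wgd_tags": {
    "1R": "Vertebrata",
    "2R": "Vertebrata",
    "3R": "Teleostei",
    "4R": "atlantic_salmon"
  },
  "root_repertoire": [
    {"name": "TRPVC", "subtype": "TRPVC", "status": "coding"},
    {"name": "TRPVD", "subtype": "TRPVD", "status": "coding"}
  ],
  "events": [
    {"branch": "Vertebrata", "kind": "wgd", "tag": "1R", "name_rule": "explicit",
     "names": {"TRPVC": ["TRPVC1", "TRPVC2"], "TRPVD": ["TRPVD1", "TRPVD2"]}},
    {"branch": "Vertebrata", "kind": "wgd", "tag": "2R", "name_rule": "explicit",
     "names": {"TRPVC1": ["TRPV1", "TRPVCx1"], "TRPVC2": ["TRPV4", "TRPVCx2"],
               "TRPVD1": ["TRPV5", "TRPVDx1"], "TRPVD2": ["TRPV7", "TRPVDx2"]},
     "subtypes": {"TRPV1": "TRPV1", "TRPV4": "TRPV4", "TRPV5": "TRPV5", "TRPV7": "TRPV7"}},
    {"branch": "Vertebrata", "kind": "loss", "target": "TRPVCx1"},
    {"branch": "Vertebrata", "kind": "loss", "target": "TRPVCx2"},
    {"branch": "Vertebrata", "kind": "loss", "target": "TRPVDx1"},
    {"branch": "Vertebrata", "kind": "loss", "target": "TRPVDx2"},
    {"branch": "Vertebrata", "kind": "local_duplication", "target": "TRPV7",
     "copies": 1, "name_rule": "explicit", "names": ["TRPV8"], "subtypes": ["TRPV8"]},

    {"branch": "sea_lamprey", "kind": "loss", "target": "TRPV1"},
    {"branch": "sea_lamprey", "kind": "local_duplication", "target": "TRPV5",
     "copies": 1, "name_rule": "serial", "prefix": "cy"},

    {"branch": "Gnathostomata", "kind": "local_duplication", "target": "TRPV1",
     "copies": 1, "name_rule": "explicit", "names": ["TRPV3"], "subtypes": ["TRPV3"]},
    {"branch": "Gnathostomata", "kind": "local_duplication", "target": "TRPV3",
     "copies": 1, "name_rule": "explicit", "names": ["TRPV9"], "subtypes": ["TRPV9"]},

    {"branch": "Chondrichthyes", "kind": "local_duplication", "target": "TRPV5",
     "copies": 2, "name_rule": "serial", "prefix": "ch"},
    {"branch": "elephant_shark", "kind": "loss", "target": "TRPV9"},
    {"branch": "elephant_shark", "kind": "loss", "target": "chTRPV5-1"},
    {"branch": "Elasmobranchii", "kind": "local_duplication", "target": "TRPV8",
     "copies": 1, "name_rule": "serial", "prefix": ""},
    {"branch": "whale_shark", "kind": "loss", "target": "chTRPV5-1"},

    {"branch": "Osteichthyes", "kind": "loss", "target": "TRPV9"},

    {"branch": "Actinopterygii", "kind": "loss", "target": "TRPV3"},
    {"branch": "Polypteridae", "kind": "local_duplication", "target": "TRPV5",
     "copies": 4, "name_rule": "serial", "prefix": "po"},
    {"branch": "Neopterygii", "kind": "loss", "target": "TRPV7"},
    {"branch": "Neopterygii", "kind": "loss", "target": "TRPV8"},

    {"branch": "Teleostei", "kind": "wgd", "tag": "3R", "name_rule": "suffix_ab"},
    {"branch": "Teleostei", "kind": "loss", "target": "TRPV4b"},
    {"branch": "Teleostei", "kind": "loss", "target": "TRPV5b"},

    {"branch": "european_eel", "kind": "loss", "target": "TRPV1b"},
    {"branch": "asian_bonytongue", "kind": "loss", "target": "TRPV1b"},
    {"branch": "zebrafish", "kind": "loss", "target": "TRPV1b"},
    {"branch": "atlantic_cod", "kind": "local_duplication", "target": "TRPV1a",
     "copies": 2, "name_rule": "serial", "prefix": ""},
    {"branch": "atlantic_cod", "kind": "local_duplication", "target": "TRPV1b",
     "copies": 2, "name_rule": "serial", "prefix": ""},
    {"branch": "Protacanthopterygii", "kind": "loss", "target": "TRPV1b"},
    {"branch": "northern_pike", "kind": "local_duplication", "target": "TRPV5a",
     "copies": 1, "name_rule": "serial", "prefix": ""},
    {"branch": "atlantic_salmon", "kind": "wgd", "tag": "4R",
     "name_rule": "suffix_alphabeta"},

    {"branch": "coelacanth", "kind": "local_duplication", "target": "TRPV3",
     "copies": 2, "name_rule": "serial", "prefix": ""},

    {"branch": "Tetrapoda", "kind": "local_duplication", "target": "TRPV1",
     "copies": 1, "name_rule": "explicit", "names": ["TRPV2"], "subtypes": ["TRPV2"]},

    {"branch": "Amphibia", "kind": "local_duplication", "target": "TRPV5",
     "copies": 3, "name_rule": "serial", "prefix": "am"},
    {"branch": "xenopus_tropicalis", "kind": "local_duplication", "target": "TRPV4",
     "copies": 5, "name_rule": "serial", "prefix": ""},
    {"branch": "xenopus_laevis", "kind": "local_duplication", "target": "TRPV4",
     "copies": 2, "name_rule": "serial", "prefix": ""},

    {"branch": "Sauropsida", "kind": "local_duplication", "target": "TRPV5",
     "copies": 1, "name_rule": "serial", "prefix": "sau"},
    {"branch": "Sauropsida", "kind": "loss", "target": "TRPV7"},
    {"branch": "Sauropsida", "kind": "loss", "target": "TRPV8"},
    {"branch": "Aves", "kind": "pseudogenization", "target": "sauTRPV5-2"},

    {"branch": "Mammalia", "kind": "local_duplication", "target": "TRPV5",
     "copies": 1, "name_rule": "serial", "prefix": "m"},
    {"branch": "platypus", "kind": "loss", "target": "mTRPV5-1"},
    {"branch": "Theria", "kind": "loss", "target": "TRPV7"},
    {"branch": "opossum", "kind": "pseudogenization", "target": "TRPV8"},
    {"branch": "human", "kind": "loss", "target": "TRPV8"}
  ]
}
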