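[
  {
    "list_id": "synthetic-A",
    "targets": ["boot", "lamp", "fish", "chair", "bread", "cloud", "horse",
                "knife", "stone", "glove", "train", "mouse", "shell",
                "grape", "wheel"],
    "foils": ["desk", "rope", "plum", "fox", "brick", "snow", "barn",
              "spoon", "tent", "crow", "flute", "pond", "nail", "wolf",
              "cake"]
  },
  {
    "list_id": "synthetic-B",
    "targets": ["door", "sock", "bird", "plate", "milk", "storm", "sheep",
                "fork", "rock", "scarf", "ship", "rat", "crab", "pear",
                "tire"],
    "foils": ["bench", "twine", "peach", "deer", "slate", "rain", "shed",
              "cup", "hut", "hawk", "harp", "lake", "pin", "bear", "pie"]
  },
  {
    "list_id": "synthetic-C",
    "targets": ["gate", "shoe", "duck", "stool", "cheese", "wind", "goat",
                "blade", "sand", "belt", "boat", "moth", "worm", "fig",
                "drum"],
    "foils": ["fence", "thread", "lime", "elk", "tile", "mist", "shack",
              "bowl", "cave", "owl", "horn", "sea", "nut", "ox", "tart"]
  }
]
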