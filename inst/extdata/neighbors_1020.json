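{
  "source": "schematic-10-20-distance",
  "max_dist": 0.45,
  "positions": [
    {
      "label": "FP1",
      "x": -0.27,
      "y": 0.9
    },
    {
      "label": "FP2",
      "x": 0.27,
      "y": 0.9
    },
    {
      "label": "F7",
      "x": -0.72,
      "y": 0.55
    },
    {
      "label": "F3",
      "x": -0.39,
      "y": 0.55
    },
    {
      "label": "Fz",
      "x": 0,
      "y": 0.55
    },
    {
      "label": "F4",
      "x": 0.39,
      "y": 0.55
    },
    {
      "label": "F8",
      "x": 0.72,
      "y": 0.55
    },
    {
      "label": "FC5",
      "x": -0.59,
      "y": 0.3
    },
    {
      "label": "FC1",
      "x": -0.2,
      "y": 0.3
    },
    {
      "label": "FC2",
      "x": 0.2,
      "y": 0.3
    },
    {
      "label": "FC6",
      "x": 0.59,
      "y": 0.3
    },
    {
      "label": "T7",
      "x": -0.9,
      "y": 0
    },
    {
      "label": "C3",
      "x": -0.45,
      "y": 0
    },
    {
      "label": "Cz",
      "x": 0,
      "y": 0
    },
    {
      "label": "C4",
      "x": 0.45,
      "y": 0
    },
    {
      "label": "T8",
      "x": 0.9,
      "y": 0
    },
    {
      "label": "CP5",
      "x": -0.59,
      "y": -0.3
    },
    {
      "label": "CP1",
      "x": -0.2,
      "y": -0.3
    },
    {
      "label": "CP2",
      "x": 0.2,
      "y": -0.3
    },
    {
      "label": "CP6",
      "x": 0.59,
      "y": -0.3
    },
    {
      "label": "P7",
      "x": -0.72,
      "y": -0.55
    },
    {
      "label": "P3",
      "x": -0.39,
      "y": -0.55
    },
    {
      "label": "Pz",
      "x": 0,
      "y": -0.55
    },
    {
      "label": "P4",
      "x": 0.39,
      "y": -0.55
    },
    {
      "label": "P8",
      "x": 0.72,
      "y": -0.55
    },
    {
      "label": "O1",
      "x": -0.27,
      "y": -0.9
    },
    {
      "label": "Oz",
      "x": 0,
      "y": -0.9
    },
    {
      "label": "O2",
      "x": 0.27,
      "y": -0.9
    }
  ],
  "neighbors": {
    "FP1": ["Fz", "F3"],
    "FP2": ["Fz", "F4"],
    "F7": ["F3", "FC5"],
    "F3": ["FP1", "Fz", "F7", "FC1", "FC5"],
    "Fz": ["FP1", "FP2", "F3", "F4", "FC1", "FC2"],
    "F4": ["FP2", "Fz", "F8", "FC2", "FC6"],
    "F8": ["F4", "FC6"],
    "FC5": ["F3", "F7", "FC1", "C3", "T7"],
    "FC1": ["Fz", "F3", "FC2", "FC5", "Cz", "C3"],
    "FC2": ["Fz", "F4", "FC1", "FC6", "Cz", "C4"],
    "FC6": ["F4", "F8", "FC2", "C4", "T8"],
    "T7": ["FC5", "CP5"],
    "C3": ["FC1", "FC5", "CP1", "CP5"],
    "Cz": ["FC1", "FC2", "CP1", "CP2"],
    "C4": ["FC2", "FC6", "CP2", "CP6"],
    "T8": ["FC6", "CP6"],
    "CP5": ["C3", "T7", "CP1", "P3", "P7"],
    "CP1": ["Cz", "C3", "CP2", "CP5", "Pz", "P3"],
    "CP2": ["Cz", "C4", "CP1", "CP6", "Pz", "P4"],
    "CP6": ["C4", "T8", "CP2", "P4", "P8"],
    "P7": ["CP5", "P3"],
    "P3": ["CP1", "CP5", "Pz", "P7", "O1"],
    "Pz": ["CP1", "CP2", "P3", "P4", "Oz", "O1", "O2"],
    "P4": ["CP2", "CP6", "Pz", "P8", "O2"],
    "P8": ["CP6", "P4"],
    "O1": ["Pz", "P3", "Oz"],
    "Oz": ["Pz", "O1", "O2"],
    "O2": ["Pz", "P4", "Oz"]
  }
}
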