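{
  "format": "erpperm-pooling-map",
  "version": 1,
  "description": "19 pooled electrodes of the 10-20 system, each the unweighted mean of three adjacent recording electrodes.",
  "pools": {
    "Fpz": ["Fp1", "Fpz", "Fp2"],
    "AFz": ["AF3", "AFz", "AF4"],
    "F5":  ["F3", "F5", "F7"],
    "Fz":  ["F1", "Fz", "F2"],
    "F6":  ["F4", "F6", "F8"],
    "FC5": ["FC3", "FC5", "FT7"],
    "FCz": ["FC1", "FCz", "FC2"],
    "FC6": ["FC4", "FC6", "FT8"],
    "C5":  ["C3", "C5", "T7"],
    "Cz":  ["C1", "Cz", "C2"],
    "C6":  ["C4", "C6", "T8"],
    "CP5": ["CP3", "CP5", "TP7"],
    "CPz": ["CP1", "CPz", "CP2"],
    "CP6": ["CP4", "CP6", "TP8"],
    "P5":  ["P3", "P5", "P7"],
    "Pz":  ["P1", "Pz", "P2"],
    "P6":  ["P4", "P6", "P8"],
    "POz": ["PO3", "POz", "PO4"],
    "Oz":  ["O1", "Oz", "O2"]
  }
}
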