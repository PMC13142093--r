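{
  "title": "chromocycle trajectory frame sidecar",
  "type": "object",
  "required": ["t", "shape", "fork", "smc_pairs", "seed"],
  "properties": {
    "t": {"type": "number"},
    "shape": {
      "type": "object",
      "required": ["R", "d", "axis", "center"],
      "properties": {
        "mode": {"type": "string"},
        "R": {"type": "number"},
        "d": {"type": "number"},
        "axis": {"type": "array"},
        "center": {"type": "array"}
      }
    },
    "fork": {
      "type": "object",
      "required": ["left_fork_beads", "right_fork_beads", "complete", "n_dna_beads"],
      "properties": {
        "left_fork_beads": {"type": "integer"},
        "right_fork_beads": {"type": "integer"},
        "complete": {"type": "boolean"},
        "n_dna_beads": {"type": "integer"}
      }
    },
    "smc_pairs": {"type": "array"},
    "seed": {"type": "integer"},
    "n_dna_beads": {"type": "integer"},
    "n_ribosomes": {"type": "integer"}
  }
}
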