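{
  "name": "DPP4",
  "ser": {"resseq": 630, "resname": "SER"},
  "his": {"resseq": 740, "resname": "HIS"},
  "asp": {"resseq": 708, "resname": "ASP"},
  "oxyanion_donors": [
    {"resseq": 547, "resname": "TYR", "atom": "OH"},
    {"resseq": 631, "resname": "TYR", "atom": "N"}
  ],
  "distal_donor_index": 1,
  "his_loop": {"start": 738, "end": 742},
  "core": [
    {"start": 600, "end": 606},
    {"start": 624, "end": 629},
    {"start": 631, "end": 641},
    {"start": 662, "end": 668},
    {"start": 700, "end": 706},
    {"start": 729, "end": 735}
  ],
  "provenance": "Human dipeptidyl peptidase 4 (DPP-IV), author numbering. Special case of the oxyanion hole: the canonical alpha/beta-hydrolase oxyanion loop is shifted and the oxyanion is coordinated by the hydroxyl of Tyr547, so the donor heteroatom of the d2/d3 triangle sides is the Tyr547 sidechain oxygen. That atom is written 'TyrOG1' in some sources; standard Tyr nomenclature has no OG1, and this config deliberately uses the hydroxyl oxygen atom name 'OH'. Core segment ranges are CURATED ESTIMATES pending validation against a deposition."
}
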