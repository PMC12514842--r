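{
  "name": "AChE",
  "ser": {"resseq": 203, "resname": "SER"},
  "his": {"resseq": 447, "resname": "HIS"},
  "asp": {"resseq": 334, "resname": "GLU"},
  "oxyanion_donors": [
    {"resseq": 121, "resname": "GLY", "atom": "N"},
    {"resseq": 122, "resname": "GLY", "atom": "N"},
    {"resseq": 204, "resname": "ALA", "atom": "N"}
  ],
  "distal_donor_index": 1,
  "oxyanion_loop": {"start": 118, "end": 124},
  "his_loop": {"start": 445, "end": 449},
  "core": [
    {"start": 96, "end": 102},
    {"start": 140, "end": 146},
    {"start": 197, "end": 202},
    {"start": 204, "end": 214},
    {"start": 324, "end": 330},
    {"start": 397, "end": 403},
    {"start": 435, "end": 441},
    {"start": 516, "end": 522}
  ],
  "provenance": "Acetylcholinesterase (mouse numbering as in entry 1j06 and the organophosphate complexes 2y2v/2jgm/2jgk). The catalytic acid is a glutamate (Glu334), carried in the 'asp' slot of the triad. Oxyanion-hole donors: backbone amides of Gly121, Gly122 and Ala204; Gly121 configured as the distal donor. Loop and core segment ranges are CURATED ESTIMATES pending validation against the deposition's secondary structure."
}
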