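{
  "name": "pAPEH",
  "ser": {"resseq": 587, "resname": "SER"},
  "his": {"resseq": 707, "resname": "HIS"},
  "asp": {"resseq": 675, "resname": "ASP"},
  "oxyanion_donors": [
    {"resseq": 509, "resname": "GLY", "atom": "N"},
    {"resseq": 588, "resname": "HIS", "atom": "N"}
  ],
  "distal_donor_index": 1,
  "oxyanion_loop": {"start": 508, "end": 511},
  "his_loop": {"start": 705, "end": 709},
  "core": [
    {"start": 524, "end": 530},
    {"start": 549, "end": 555},
    {"start": 576, "end": 582},
    {"start": 588, "end": 598},
    {"start": 612, "end": 618},
    {"start": 648, "end": 654},
    {"start": 668, "end": 674},
    {"start": 694, "end": 700},
    {"start": 716, "end": 722}
  ],
  "provenance": "Porcine acylpeptide hydrolase, author numbering of the ligand-free deposition 7PX8 and the covalent-complex depositions 9GNE/9GOU/9HXQ. Catalytic triad Ser587/His707/Asp675; oxyanion-hole donors are the backbone amides of Gly509 (distal, inside the 508-511 oxyanion loop) and His588. The His-loop range (705-709) and the core segment ranges (eight central beta-strands of the hydrolase domain plus the helix following the catalytic Ser, residues 588-598) are CURATED ESTIMATES: the strand boundaries are not printed in the literature and could not be re-derived offline from the deposition's secondary-structure records. Validate against DSSP/author annotations of 7PX8 before quantitative use, and override per run if they differ."
}
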