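[
  {"label": "3.29", "mode": "R10", "key_residue": "S", "criticality": "supporting", "rules": []},
  {"label": "3.32", "mode": "R10", "key_residue": "W", "criticality": "supporting", "rules": []},
  {"label": "3.33", "mode": "R10", "key_residue": "V", "criticality": "supporting", "rules": []},
  {"label": "3.36", "mode": "R10", "key_residue": "N", "criticality": "supporting", "rules": []},
  {"label": "3.37", "mode": "R10", "key_residue": "Q", "criticality": "critical",
   "rules": [{"residues": "A", "effect": "abolished", "source": "Born2013:Q93A complete loss of responsiveness"}]},
  {"label": "5.39", "mode": "R10", "key_residue": "K", "criticality": "supporting", "rules": []},
  {"label": "5.40", "mode": "R10", "key_residue": "Q", "criticality": "critical", "rules": []},
  {"label": "5.42", "mode": "R10", "key_residue": "L", "criticality": "supporting", "rules": []},
  {"label": "5.43", "mode": "R10", "key_residue": "L", "criticality": "critical", "rules": []},
  {"label": "6.51", "mode": "R10", "key_residue": "Y", "criticality": "supporting", "rules": []},
  {"label": "7.39", "mode": "R10", "key_residue": "M", "criticality": "critical",
   "rules": [{"residues": "AE", "effect": "abolished", "source": "Born2013:M263A/E complete loss of responsiveness"}]},
  {"label": "7.42", "mode": "R10", "key_residue": "T", "criticality": "critical", "rules": []},

  {"label": "2.61", "mode": "R46", "key_residue": "W", "criticality": "supporting", "rules": []},
  {"label": "2.65", "mode": "R46", "key_residue": "E", "criticality": "supporting",
   "rules": [{"residues": "V", "effect": "tolerated", "source": "Brockhoff2010:E70V largely unaltered activation"}]},
  {"label": "2.66", "mode": "R46", "key_residue": "L", "criticality": "supporting", "rules": []},
  {"label": "3.25", "mode": "R46", "key_residue": "I", "criticality": "supporting",
   "rules": [{"residues": "T", "effect": "reduced", "source": "Brockhoff2010:I82T decreased response"}]},
  {"label": "3.32", "mode": "R46", "key_residue": "W", "criticality": "supporting", "rules": []},
  {"label": "3.36", "mode": "R46", "key_residue": "N", "criticality": "supporting",
   "rules": [{"residues": "GS", "effect": "reduced", "source": "Brockhoff2010:N92G decreased response; gorilla N92S"}]},
  {"label": "4.65", "mode": "R46", "key_residue": "N", "criticality": "supporting", "rules": []},
  {"label": "ECL2", "mode": "R46", "key_residue": "N", "criticality": "supporting", "rules": []},
  {"label": "5.39", "mode": "R46", "key_residue": "N", "criticality": "supporting",
   "rules": [{"residues": "D", "effect": "reduced", "source": "Brockhoff2010:N176D decreased response"}]},
  {"label": "5.42", "mode": "R46", "key_residue": "V", "criticality": "supporting", "rules": []},
  {"label": "6.51", "mode": "R46", "key_residue": "Y", "criticality": "supporting",
   "rules": [{"residues": "F", "effect": "reduced", "source": "Brockhoff2010:Y241F reduced maximum activation"},
             {"residues": "S", "effect": "tolerated", "source": "Sandal2015:Y241S higher activation level"}]},
  {"label": "6.63", "mode": "R46", "key_residue": "E", "criticality": "supporting",
   "rules": [{"residues": "GK", "effect": "reduced", "source": "Brockhoff2010:E253G decreased response; bonobo E253K"}]},
  {"label": "7.39", "mode": "R46", "key_residue": "E", "criticality": "critical",
   "rules": [{"residues": "D", "effect": "reduced", "source": "Brockhoff2010:E265D modest sensitivity decrease"},
             {"residues": "Q", "effect": "reduced", "source": "Brockhoff2010:E265Q ~100-fold sensitivity reduction, receptor still active"},
             {"residues": "K", "effect": "abolished", "source": "Brockhoff2010:E265K nearly abolished activation"}]},
  {"label": "7.42", "mode": "R46", "key_residue": "A", "criticality": "critical",
   "rules": [{"residues": "G", "effect": "reduced", "source": "Brockhoff2010:A268G slight sensitivity decrease"},
             {"residues": "TIR", "effect": "reduced", "source": "steric hindrance at 7.42 reduces sensitivity in ancestral backgrounds"}]},
  {"label": "7.43", "mode": "R46", "key_residue": "F", "criticality": "critical",
   "rules": [{"residues": "N", "effect": "abolished", "source": "Brockhoff2010:F269N near-complete loss"},
             {"property": "hydrophobic", "effect": "reduced", "source": "hydrophobicity at 7.43 fundamental for binding"}]}
]
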