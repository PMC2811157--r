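# Kinase consensus and docking motif library.
# Offsets are relative to the central phospho-acceptor (negative = N-terminal).
# ATM/ATR and Plk1 follow the published consensus strings; the CDK, PBD and
# Chk1/2 entries are minimal Scansite-style consensuses and can be edited here.
ATM/ATR:
  central: [S, T]
  slots:
    "+1": [Q]
CDK:
  central: [S, T]
  slots:
    "+1": [P]
CDK-strict:
  central: [S, T]
  kinase: CDK
  slots:
    "+1": [P]
    "+3": [K, R]
Plk1:
  central: [S, T]
  slots:
    "-2": [D, E]
PBD-docking:
  central: [S, T]
  kinase: PBD
  slots:
    "-1": [S]
    "+1": [P]
Chk1/2:
  central: [S, T]
  slots:
    "-3": [R]
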