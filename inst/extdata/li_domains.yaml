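# LI integrase C-terminal domain annotation scheme (deposit numbering).
# Same content as li_domain_scheme(); shipped so alternative schemes can be
# derived by editing a copy.
alphaE:
  range: [133, 140]
RD:
  range: [141, 256]
RD_ZD_linker:
  range: [257, 264]
ZD:
  range: [265, 452]
  carve_out: CC
  metadata:
    zinc_cysteines: [274, 277, 302, 314]
CC:
  range: [342, 416]
ZD_anchor:
  range: [338, 338]
  metadata:
    residue: ALA
    atom: CA
CC_tip:
  range: [374, 374]
  metadata:
    residue: TYR
    atom: CA
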