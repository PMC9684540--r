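foldsmith: 1
name: bbab
segments:
  - {name: E1, kind: strand, length: [4, 6]}
  - {name: L1, kind: loop, length: [2, 3]}
  - {name: E2, kind: strand, length: [4, 6]}
  - {name: L2, kind: loop, length: [2, 4]}
  - {name: H1, kind: helix, length: [10, 14]}
  - {name: L3, kind: loop, length: [2, 4]}
  - {name: E3, kind: strand, length: [4, 6]}
sheets:
  - {strands: [E1, E2, E3]}
pairings:
  - {type: strand, first: E1, second: E2, orientation: antiparallel}
  - {type: strand, first: E2, second: E3, orientation: antiparallel}
  - {type: helix_sheet, helix: H1, strands: [E1, E3]}
constraints:
  - {a: [H1, midpoint], b: [E2, midpoint]}
  - {a: [H1, C-end], b: [E2, C-end], target: 9, sd: 2}
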