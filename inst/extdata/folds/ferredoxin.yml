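foldsmith: 1
name: ferredoxin
segments:
  - {name: E1, kind: strand, length: [4, 6]}
  - {name: L1, kind: loop, length: [2, 4]}
  - {name: H1, kind: helix, length: [10, 16]}
  - {name: L2, kind: loop, length: [2, 4]}
  - {name: E2, kind: strand, length: [4, 6]}
  - {name: L3, kind: loop, length: [2, 4]}
  - {name: E3, kind: strand, length: [4, 6]}
  - {name: L4, kind: loop, length: [2, 4]}
  - {name: H2, kind: helix, length: [10, 16]}
  - {name: L5, kind: loop, length: [2, 4]}
  - {name: E4, kind: strand, length: [4, 6]}
sheets:
  - {strands: [E4, E1, E3, E2]}
pairings:
  - {type: strand, first: E3, second: E2, orientation: antiparallel}
  - {type: strand, first: E1, second: E3, orientation: antiparallel}
  - {type: strand, first: E4, second: E1, orientation: antiparallel}
  - {type: helix_sheet, helix: H1, strands: [E2, E3]}
  - {type: helix_sheet, helix: H2, strands: [E1]}
  - {type: helix, first: H1, second: H2, orientation: antiparallel}
constraints:
  - {a: [H1, midpoint], b: [E2, midpoint]}
  - {a: [H2, midpoint], b: [E1, midpoint]}
  - {a: [H1, N-end], b: [E3, N-end], target: 10, sd: 3}
  - {a: [H2, C-end], b: [E1, C-end], target: 10, sd: 3}
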