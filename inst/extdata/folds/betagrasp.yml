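foldsmith: 1
name: betagrasp
segments:
  - {name: E1, kind: strand, length: [4, 6]}
  - {name: L1, kind: loop, length: [2, 3]}
  - {name: E2, kind: strand, length: [4, 6]}
  - {name: L2, kind: loop, length: [2, 4]}
  - {name: H1, kind: helix, length: [10, 14]}
  - {name: L3, kind: loop, length: [2, 4]}
  - {name: E3, kind: strand, length: [4, 6]}
  - {name: L4, kind: loop, length: [2, 3]}
  - {name: E4, kind: strand, length: [4, 6]}
sheets:
  - {strands: [E2, E1, E4, E3]}
pairings:
  - {type: strand, first: E2, second: E1, orientation: antiparallel}
  - {type: strand, first: E1, second: E4, orientation: antiparallel}
  - {type: strand, first: E4, second: E3, orientation: antiparallel}
  - {type: helix_sheet, helix: H1, strands: [E1, E2]}
constraints:
  - {a: [H1, midpoint], b: [E1, midpoint]}
  - {a: [H1, C-end], b: [E3, N-end], target: 9}
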