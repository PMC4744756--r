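# Example Markov spec over the six prevalent H-bond patterns of the serine
# hairpin. Rows are transition percentages as published for that peptide;
# they are renormalised to probabilities on read (printed rows do not sum
# exactly to 100).
states: [oooo, oooc, cooc, cocc, ccoc, cccc]
transition_matrix:
  - [94, 4, 0, 0, 0, 0]
  - [9, 49, 23, 8, 3, 1]
  - [0, 3, 72, 14, 7, 2]
  - [0, 1, 6, 79, 1, 8]
  - [0, 2, 39, 8, 37, 9]
  - [0, 0, 6, 39, 3, 46]
n_runs: 11
n_frames_per_run: 5000
seed: 1
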