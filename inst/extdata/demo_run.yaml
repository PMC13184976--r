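# Synthetic end-to-end demo: no file inputs, so the pipeline simulates a
# pool and observables from the generator block before fitting.
seed: 7
generator:
  n_folded: 6
  n_unfolded: 6
  donor_element: Br
  acceptor_element: O
energetics:
  reference_folded_fraction: 0.22
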