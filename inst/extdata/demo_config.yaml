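# Demo run: small synthetic colony field, annotation, responder summary.
seed: 7
generate:
  n_colonies: 3
  colony_cells_min: 15
  colony_cells_max: 30
  n_singles: 15
  field_width_um: 1200
  field_height_um: 1200
annotate:
  eps: 22.5
respond:
  group_by: edge_degree
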