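states:
- label: W
  role: transdurable
- label: S
  role: transdurable
- label: U
  role: transdurable
- label: D
  role: absorbing
- label: E
  role: absorbing
transitions:
- W->S
- W->U
- S->W
- S->U
- U->W
- U->S
- W+S+U->D
- W+S+U->E
wle_states:
- W
- S
- U
pension_age: 65.0
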