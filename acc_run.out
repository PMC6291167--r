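✔ | F W  S  OK | Context

⠏ |          0 | acceptance                                                     
⠋ |          1 | acceptance                                                     
⠙ |         12 | acceptance                                                     
⠧ |         48 | acceptance                                                     
⠸ |         94 | acceptance                                                     
⠧ |        118 | acceptance                                                     
⠸ |        124 | acceptance                                                     
⠴ |        126 | acceptance                                                     
⠙ |        132 | acceptance                                                     
⠹ | 1      132 | acceptance                                                     
⠸ | 1      133 | acceptance                                                     
✖ | 1      135 | acceptance [93.7s]
────────────────────────────────────────────────────────────────────────────────
Failure ('test-acceptance.R:149:3'): acceptance 9: cluster permutation familywise error is calibrated
abs(fwe/n_sim - 0.05) is not strictly less than 0.02. Difference: 0.024
────────────────────────────────────────────────────────────────────────────────

══ Results ═════════════════════════════════════════════════════════════════════
Duration: 93.8 s

── Failed tests ────────────────────────────────────────────────────────────────
Failure ('test-acceptance.R:149:3'): acceptance 9: cluster permutation familywise error is calibrated
abs(fwe/n_sim - 0.05) is not strictly less than 0.02. Difference: 0.024

[ FAIL 1 | WARN 0 | SKIP 0 | PASS 135 ]
Error: Test failures
Execution halted
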