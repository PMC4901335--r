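# Universal register machine M_u: 8 registers (0-7), 23 instructions.
# g(x) enters register 1, y enters register 2; result in register 0 at halt.
l0:  SUB 1 l1  l2
l1:  ADD 7 l0
l2:  ADD 6 l3
l3:  SUB 5 l2  l4
l4:  SUB 6 l5  l3
l5:  ADD 5 l6
l6:  SUB 7 l7  l8
l7:  ADD 1 l4
l8:  SUB 6 l9  l0
l9:  ADD 6 l10
l10: SUB 4 l0  l11
l11: SUB 5 l12 l13
l12: SUB 5 l14 l15
l13: SUB 2 l18 l19
l14: SUB 5 l16 l17
l15: SUB 3 l18 l20
l16: ADD 4 l11
l17: ADD 2 l21
l18: SUB 4 l0  lh
l19: SUB 0 l0  l18
l20: ADD 0 l0
l21: ADD 3 l18
lh:  HALT
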