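>r01
ADEG-
>r02
ADEG-
>r03
A-EG-
>r04
A-EG-
>r05
A-EG-
>r06
A-EG-
>r07
A-EG-
>r08
A-EG-
>r09
A-EG-
>r10
A-EGH
>r11
A-EG-
>r12
A-EG-
>r13
A-EG-
>r14
A-EG-
>r15
A-EG-
>r16
A--G-
>r17
A--G-
>r18
A--G-
>r19
A--G-
>r20
A--GH
>r21
A--G-
>r22
A--G-
>r23
A--G-
>r24
A--G-
>r25
A--G-
>r26
A--G-
>r27
A--G-
>r28
A--G-
>r29
A--G-
>r30
A--G-
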