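group,validated,not_validated
Lenke type 1,4,4
Lenke type 2,2,0
Lenke type 3,29,4
Lenke type 4,2,0
Lenke type 5,9,0
Lenke type 6,13,2
Normal,9,16
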