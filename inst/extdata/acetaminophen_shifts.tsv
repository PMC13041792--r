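# ramanprep bundled acetaminophen Raman shift library, version 1.0
# columns: shift_cm1 <TAB> analyte
213.3	acetaminophen
329.2	acetaminophen
390.9	acetaminophen
465.1	acetaminophen
504.0	acetaminophen
651.6	acetaminophen
710.8	acetaminophen
797.2	acetaminophen
834.5	acetaminophen
857.9	acetaminophen
968.7	acetaminophen
1105.5	acetaminophen
1168.5	acetaminophen
1236.8	acetaminophen
1278.5	acetaminophen
1323.9	acetaminophen
1371.5	acetaminophen
1515.1	acetaminophen
1561.6	acetaminophen
1648.4	acetaminophen
2931.1	acetaminophen
3326.6	acetaminophen
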