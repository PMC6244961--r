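hla_class,unique_to,bead
I,LC,A*02:02
I,LC,A*02:05
I,LC,B*07:03
I,LC,B*15:18
I,LC,B*27:03
I,LC,B*35:08
I,LC,B*82:01
I,LC,Cw*04:03
I,LC,Cw*07:01
I,LC,Cw*08:02
I,LC,Cw*12:02
I,LC,Cw*18:01
I,LS,A*02:06
I,LS,A*30:02
I,LS,A*34:01
I,LS,B*13:01
I,LS,B*15:10
I,LS,B*40:06
I,LS,B*51:02
I,LS,B*57:03
I,LS,B*82:02
I,LS,Cw*03:02
I,LS,Cw*12:03
I,LS,Cw*18:02
II,LC,DRB1*03:03
II,LC,DRB1*08:02
II,LC,DRB1*11:03
II,LC,DRB1*13:05
II,LC,DRB1*14:03
II,LC,DRB1*14:04
II,LC,DQB1*02:02\DQA1*03:02
II,LC,DQB1*02:02\DQA1*05:01
II,LC,DQB1*03:01\DQA1*03:02
II,LC,DQB1*03:01\DQA1*05:01
II,LC,DQB1*03:03\DQA1*04:01
II,LC,DQB1*03:03\DQA1*06:01
II,LC,DQB1*04:01\DQA1*04:01
II,LC,DQB1*04:01\DQA1*05:01
II,LC,DQB1*04:02\DQA1*03:01
II,LC,DQB1*04:02\DQA1*06:01
II,LC,DQB1*05:01\DQA1*01:02
II,LC,DQB1*05:03\DQA1*01:04
II,LC,DQB1*06:01\DQA1*01:04
II,LC,DQB1*06:01\DQA1*02:01
II,LC,DPB1*01:01\DPA1*02:02
II,LC,DPB1*01:01\DPA1*03:01
II,LC,DPB1*04:01\DPA1*01:03
II,LC,DPB1*04:01\DPA1*02:01
II,LC,DPB1*04:01\DPA1*02:02
II,LC,DPB1*04:01\DPA1*03:01
II,LC,DPB1*04:01\DPA1*04:01
II,LC,DPB1*04:02\DPA1*03:01
II,LC,DPB1*05:01\DPA1*03:01
II,LC,DPB1*11:01\DPA1*02:01
II,LC,DPB1*13:01\DPA1*04:01
II,LC,DPB1*18:01\DPA1*01:03
II,LC,DPB1*19:01\DPA1*02:01
II,LC,DPB1*28:01\DPA1*02:02
II,LS,DRB1*09:02
II,LS,DRB1*14:02
II,LS,DRB1*14:54
II,LS,DRB4*01:03
II,LS,DQB1*02:01\DQA1*03:01
II,LS,DQB1*02:01\DQA1*04:01
II,LS,DQB1*03:01\DQA1*02:01
II,LS,DQB1*03:03\DQA1*03:01
II,LS,DQB1*03:01\DQA1*05:03
II,LS,DQB1*03:01\DQA1*05:05
II,LS,DQB1*03:03\DQA1*02:01
II,LS,DQB1*04:01\DQA1*03:03
II,LS,DQB1*04:02\DQA1*02:01
II,LS,DQB1*06:02\DQA1*01:01
II,LS,DQB1*06:09\DQA1*01:02
II,LS,DPB1*03:01\DPA1*01:05
II,LS,DPB1*03:01\DPA1*02:01
II,LS,DPB1*04:01\DPA1*01:03
II,LS,DPB1*06:01\DPA1*02:01
II,LS,DPB1*10:01\DPA1*02:02
II,LS,DPB1*11:01\DPA1*01:03
II,LS,DPB1*11:01\DPA1*02:02
II,LS,DPB1*13:01\DPA1*02:02
II,LS,DPB1*13:01\DPA1*03:01
II,LS,DPB1*18:01\DPA1*01:04
II,LS,DPB1*18:01\DPA1*01:05
II,LS,DPB1*18:01\DPA1*02:01
II,LS,DPB1*19:01\DPA1*01:03
II,LS,DPB1*09:01\DPA1*02:01
II,LS,DPB1*20:01\DPA1*03:01
II,LS,DPB1*23:01\DPA1*02:01
II,LS,DPB1*28:01\DPA1*01:03
II,LS,DPB1*28:01\DPA1*01:05
II,LS,DPB1*28:01\DPA1*04:01
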