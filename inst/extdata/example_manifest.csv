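IlmnID,Name,Chr,MapInfo,Infinium_Design_Type,SNP,RefStrand,AddressA_ID,AddressB_ID,MappingComment
exm-rs1000001,rs1000001,1,1234567,II,[A/G],+,10001,,
exm-rs1000002,rs1000002,2,2345678,II,[C/T],-,10002,,
exm-rs1000003,rs1000003,3,3456789,I,[C/G],+,10003,20003,
exm-rs1000004,rs1000004,4,4567890,II,[T/C],+,10004,,
exm-rs1000005,rs1000005,5,5678901,I,[A/T],-,10005,20005,
exm-rs1000006,rs1000006,0,0,II,[A/G],+,10006,,
exm-rs1000007,rs1000007,X,6789012,II,[A/C],+,10007,,
exm-rs1000008,rs1000008,Y,789012,II,[G/T],-,10008,,
exm-rs1000009,rs1000009,MT,8901,II,[A/G],+,10009,,
exm-rs1000010,rs1000010,6,6543210,II,[A/G],+,10010,,duplicated region
exm-rs1000011,rs1000011,7,7654321,II,[I/D],+,10011,,
exm-rs1000012,rs1000012,8,8765432,II,[A/C],+,10012,,
exm-rs1000012b,rs1000012,8,8765432,I,[A/C],+,10013,20013,
exm-rs1000014,rs1000014,9,9876543,I,[G/C],-,10014,20014,
exm-rs1000015,rs1000015,10,1098765,II,[T/G],+,10015,,
exm-rs28362918,rs28362918,11,1111111,II,[A/G],+,10016,,
exm-rs1000017,rs1000017,12,1212121,II,[C/T],+,10017,,
exm-rs1000018,rs1000018,13,1313131,I,[G/C],+,10018,20018,
exm-rs1000019,rs1000019,14,1414141,II,[A/G],-,10019,,
exm-rs1000020,rs1000020,15,1515151,I,[T/A],+,10020,20020,
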