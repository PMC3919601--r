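base_id,subunit,position,ecoli_equiv,region,ref_nonrotated,ref_rotated,is_control
A2207,25S,2207,A1847,B7a,2,4,FALSE
G913,18S,913,A702,B7a,1,4,FALSE
U2258,25S,2258,NA,B2a,2,4,FALSE
A2262,25S,2262,NA,B2a,0,2,FALSE
C1644,18S,1644,NA,B2a,1,2,FALSE
G1645,18S,1645,NA,B2a,0,1,FALSE
U2301,25S,2301,NA,B3,0,1,TRUE
G2302,25S,2302,NA,B3,0,0,TRUE
A1655,18S,1655,NA,B3,1,2,TRUE
U1656,18S,1656,NA,B3,2,2,TRUE
U2860,25S,2860,U2491,AC,1,0,FALSE
U2924,25S,2924,U2555,AC,4,1,FALSE
A2926,25S,2926,NA,AC,4,1,FALSE
U3023,25S,3023,NA,SRL,1,0,FALSE
A3027,25S,3027,NA,SRL,2,0,FALSE
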