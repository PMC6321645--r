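sample	snps_total	snps_anchored
noncarrier-SP1	277605	275799
noncarrier-SP2	276564	274772
carrier-SP1	318046	315859
carrier-SP2	298496	296419
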