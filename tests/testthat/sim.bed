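chr1	36	46
chr1	113	123
chr1	294	304
chr1	356	366
chr1	529	539
chr1	635	645
chr1	778	788
chr1	791	801
chr1	846	856
chr1	921	931
chr1	963	973
chr1	976	986
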