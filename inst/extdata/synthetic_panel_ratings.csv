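subject,rater,category
s1,E1,non-obstructed
s1,E2,non-obstructed
s1,E3,non-obstructed
s1,CAD,non-obstructed
s2,E1,non-obstructed
s2,E2,non-obstructed
s2,E3,non-obstructed
s2,CAD,non-obstructed
s3,E1,non-obstructed
s3,E2,non-obstructed
s3,E3,non-obstructed
s3,CAD,non-obstructed
s4,E1,non-obstructed
s4,E2,non-obstructed
s4,E3,non-obstructed
s4,CAD,non-obstructed
s5,E1,non-obstructed
s5,E2,non-obstructed
s5,E3,non-obstructed
s5,CAD,non-obstructed
s6,E1,non-obstructed
s6,E2,non-obstructed
s6,E3,non-obstructed
s6,CAD,non-obstructed
s7,E1,non-obstructed
s7,E2,non-obstructed
s7,E3,non-obstructed
s7,CAD,non-obstructed
s8,E1,non-obstructed
s8,E2,non-obstructed
s8,E3,non-obstructed
s8,CAD,non-obstructed
s9,E1,non-obstructed
s9,E2,non-obstructed
s9,E3,non-obstructed
s9,CAD,non-obstructed
s10,E1,non-obstructed
s10,E2,non-obstructed
s10,E3,non-obstructed
s10,CAD,non-obstructed
s11,E1,non-obstructed
s11,E2,non-obstructed
s11,E3,non-obstructed
s11,CAD,non-obstructed
s12,E1,non-obstructed
s12,E2,non-obstructed
s12,E3,non-obstructed
s12,CAD,non-obstructed
s13,E1,non-obstructed
s13,E2,non-obstructed
s13,E3,non-obstructed
s13,CAD,non-obstructed
s14,E1,non-obstructed
s14,E2,non-obstructed
s14,E3,non-obstructed
s14,CAD,non-obstructed
s15,E1,non-obstructed
s15,E2,non-obstructed
s15,E3,non-obstructed
s15,CAD,non-obstructed
s16,E1,non-obstructed
s16,E2,non-obstructed
s16,E3,non-obstructed
s16,CAD,non-obstructed
s17,E1,non-obstructed
s17,E2,non-obstructed
s17,E3,non-obstructed
s17,CAD,non-obstructed
s18,E1,non-obstructed
s18,E2,non-obstructed
s18,E3,non-obstructed
s18,CAD,non-obstructed
s19,E1,non-obstructed
s19,E2,non-obstructed
s19,E3,non-obstructed
s19,CAD,obstructed
s20,E1,non-obstructed
s20,E2,non-obstructed
s20,E3,non-obstructed
s20,CAD,obstructed
s21,E1,non-obstructed
s21,E2,non-obstructed
s21,E3,equivocal
s21,CAD,obstructed
s22,E1,non-obstructed
s22,E2,non-obstructed
s22,E3,equivocal
s22,CAD,obstructed
s23,E1,non-obstructed
s23,E2,non-obstructed
s23,E3,obstructed
s23,CAD,obstructed
s24,E1,non-obstructed
s24,E2,non-obstructed
s24,E3,obstructed
s24,CAD,obstructed
s25,E1,non-obstructed
s25,E2,equivocal
s25,E3,equivocal
s25,CAD,non-obstructed
s26,E1,non-obstructed
s26,E2,equivocal
s26,E3,equivocal
s26,CAD,equivocal
s27,E1,non-obstructed
s27,E2,obstructed
s27,E3,obstructed
s27,CAD,obstructed
s28,E1,equivocal
s28,E2,non-obstructed
s28,E3,equivocal
s28,CAD,non-obstructed
s29,E1,equivocal
s29,E2,non-obstructed
s29,E3,equivocal
s29,CAD,non-obstructed
s30,E1,equivocal
s30,E2,non-obstructed
s30,E3,equivocal
s30,CAD,equivocal
s31,E1,equivocal
s31,E2,non-obstructed
s31,E3,obstructed
s31,CAD,equivocal
s32,E1,equivocal
s32,E2,obstructed
s32,E3,non-obstructed
s32,CAD,non-obstructed
s33,E1,equivocal
s33,E2,obstructed
s33,E3,equivocal
s33,CAD,equivocal
s34,E1,equivocal
s34,E2,obstructed
s34,E3,equivocal
s34,CAD,equivocal
s35,E1,equivocal
s35,E2,obstructed
s35,E3,equivocal
s35,CAD,obstructed
s36,E1,equivocal
s36,E2,obstructed
s36,E3,obstructed
s36,CAD,non-obstructed
s37,E1,equivocal
s37,E2,obstructed
s37,E3,obstructed
s37,CAD,obstructed
s38,E1,equivocal
s38,E2,obstructed
s38,E3,obstructed
s38,CAD,obstructed
s39,E1,obstructed
s39,E2,non-obstructed
s39,E3,non-obstructed
s39,CAD,non-obstructed
s40,E1,obstructed
s40,E2,non-obstructed
s40,E3,non-obstructed
s40,CAD,non-obstructed
s41,E1,obstructed
s41,E2,non-obstructed
s41,E3,equivocal
s41,CAD,non-obstructed
s42,E1,obstructed
s42,E2,non-obstructed
s42,E3,equivocal
s42,CAD,non-obstructed
s43,E1,obstructed
s43,E2,equivocal
s43,E3,non-obstructed
s43,CAD,non-obstructed
s44,E1,obstructed
s44,E2,obstructed
s44,E3,non-obstructed
s44,CAD,non-obstructed
s45,E1,obstructed
s45,E2,obstructed
s45,E3,non-obstructed
s45,CAD,obstructed
s46,E1,obstructed
s46,E2,obstructed
s46,E3,non-obstructed
s46,CAD,obstructed
s47,E1,obstructed
s47,E2,obstructed
s47,E3,non-obstructed
s47,CAD,obstructed
s48,E1,obstructed
s48,E2,obstructed
s48,E3,non-obstructed
s48,CAD,obstructed
s49,E1,obstructed
s49,E2,obstructed
s49,E3,equivocal
s49,CAD,obstructed
s50,E1,obstructed
s50,E2,obstructed
s50,E3,obstructed
s50,CAD,non-obstructed
s51,E1,obstructed
s51,E2,obstructed
s51,E3,obstructed
s51,CAD,equivocal
s52,E1,obstructed
s52,E2,obstructed
s52,E3,obstructed
s52,CAD,obstructed
s53,E1,obstructed
s53,E2,obstructed
s53,E3,obstructed
s53,CAD,obstructed
s54,E1,obstructed
s54,E2,obstructed
s54,E3,obstructed
s54,CAD,obstructed
s55,E1,obstructed
s55,E2,obstructed
s55,E3,obstructed
s55,CAD,obstructed
s56,E1,obstructed
s56,E2,obstructed
s56,E3,obstructed
s56,CAD,obstructed
s57,E1,obstructed
s57,E2,obstructed
s57,E3,obstructed
s57,CAD,obstructed
s58,E1,obstructed
s58,E2,obstructed
s58,E3,obstructed
s58,CAD,obstructed
s59,E1,obstructed
s59,E2,obstructed
s59,E3,obstructed
s59,CAD,obstructed
s60,E1,obstructed
s60,E2,obstructed
s60,E3,obstructed
s60,CAD,obstructed
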