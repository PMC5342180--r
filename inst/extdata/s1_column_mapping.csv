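from,to
Footprint ID,footprint_id
Trail ID,trail_id
Animal ID,animal_id
Sex,sex
Age,age_years
Side,side
Var 1,V1
Var 2,V2
Var 3,V3
Var 4,V4
Var 5,V5
Var 6,V6
Var 7,V7
Var 8,V8
Var 9,V9
Var 10,V10
Var 11,V11
Var 12,V12
Var 13,V13
Var 14,V14
Var 15,V15
Var 16,V16
Var 17,V17
Var 18,V18
Var 19,V19
Var 20,V20
Var 21,V21
Var 22,V22
Var 23,V23
Var 24,V24
Var 25,V25
Var 26,V26
Var 27,V27
Var 28,V28
Var 29,V29
Var 30,V30
Var 31,V31
Var 32,V32
Var 33,V33
Var 34,V34
Var 35,V35
Var 36,V36
Var 37,V37
Var 38,V38
Var 39,V39
Var 40,V40
Var 41,V41
Var 42,V42
Var 43,V43
Var 44,V44
Var 45,V45
Var 46,V46
Var 47,V47
Var 48,V48
Var 49,V49
Var 50,V50
Var 51,V51
Var 52,V52
Var 53,V53
Var 54,V54
Var 55,V55
Var 56,V56
Var 57,V57
Var 58,V58
Var 59,V59
Var 60,V60
Var 61,V61
Var 62,V62
Var 63,V63
Var 64,V64
Var 65,V65
Var 66,V66
Var 67,V67
Var 68,V68
Var 69,V69
Var 70,V70
Var 71,V71
Var 72,V72
Var 73,V73
Var 74,V74
Var 75,V75
Var 76,V76
Var 77,V77
Var 78,V78
Var 79,V79
Var 80,V80
Var 81,V81
Var 82,V82
Var 83,V83
Var 84,V84
Var 85,V85
Var 86,V86
Var 87,V87
Var 88,V88
Var 89,V89
Var 90,V90
Var 91,V91
Var 92,V92
Var 93,V93
Var 94,V94
Var 95,V95
Var 96,V96
Var 97,V97
Var 98,V98
Var 99,V99
Var 100,V100
Var 101,V101
Var 102,V102
Var 103,V103
Var 104,V104
Var 105,V105
Var 106,V106
Var 107,V107
Var 108,V108
Var 109,V109
Var 110,V110
Var 111,V111
Var 112,V112
Var 113,V113
Var 114,V114
Var 115,V115
Var 116,V116
Var 117,V117
Var 118,V118
Var 119,V119
Var 120,V120
Var 121,V121
Var 122,V122
Var 123,V123
Var 124,V124
Var 125,V125
Var 126,V126
Var 127,V127
Var 128,V128
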