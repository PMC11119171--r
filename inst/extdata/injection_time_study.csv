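exam,experienced,punctures_with,time_with,punctures_without,time_without
1,no,1,03:08,2,09:13
2,no,1,00:09,1,00:17
3,no,2,00:42,4,01:27
4,yes,1,00:17,3,01:08
5,yes,1,00:14,4,01:37
6,yes,1,00:07,1,00:13
7,yes,1,00:40,2,01:21
8,yes,3,02:31,3,02:14
9,no,1,00:06,2,00:23
10,yes,2,00:57,3,01:42
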