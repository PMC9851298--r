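gene	cell1	cell2	cell3	cell4
GENE001	72.77	15.61	72.35	7.35
GENE002	2.23	6.57	10.22	19.85
GENE003	3.69	8.61	49.21	17.11
GENE004	4.89	66.02	11.8	14.96
GENE005	2.8	10.56	3.02	27.27
GENE006	2.87	111.8	5.43	1.84
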