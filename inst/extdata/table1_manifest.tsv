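disease	dataset_id	n_cases	n_controls
PAH	GSE254617	96	52
PAH	GSE168905	12	9
HAPC	GSE29977	5	5
HAPC	GSE145802	70	32
IS	GSE162955	6	6
IS	GSE16561	39	24
IS	GSE202709	12	4
PE	GSE30186	6	6
PE	GSE10588	17	26
PE	GSE24129	8	8
PE	GSE25906	23	37
PE	GSE43942	5	7
PE	GSE4707	10	4
PE	GSE44711	8	8
PE	GSE75010	80	77
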