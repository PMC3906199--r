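stress	n_up	n_down	n_total	n_unique
cold	447	40	487	161
heat	458	1621	2079	930
salt	1565	1137	2702	507
drought	2290	5790	8080	NA
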