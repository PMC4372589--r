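library	raw_total	distinct_raw	clean_total	distinct_clean
CON	11803601	452202	11566379	215671
CS	12265029	475010	12010122	220622
FS	12113951	466406	11908614	261717
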