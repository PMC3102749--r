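name	length	cen_start	cen_end
ChrIII	316620	114385	114501
ChrV	576874	151987	152104
ChrX	745751	436307	436425
ChrXII	1078177	150828	150947
ChrXIII	924431	268031	268149
ChrXVI	948066	555957	556073
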