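((((((buff_rumped_thornbill,yellow_rumped_thornbill),yellow_thornbill),weebill),white_throated_gerygone),spotted_pardalote),((((((yellow_tinted_honeyeater,white_plumed_honeyeater),singing_honeyeater),(yellow_tufted_honeyeater,yellow_throated_miner)),lewins_honeyeater),((white_naped_honeyeater,white_eared_honeyeater),new_holland_honeyeater))));
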