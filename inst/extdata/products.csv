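product_id,name,abv_percent,container_volume_ml
beer_can_full,Full-strength beer can,4.8,375
beer_can_mid,Mid-strength beer can,3.5,375
wine_bottle,Bottled wine,13,750
cask_wine,Cask wine (poured share),10,2000
spirits_bottle,Bottled spirits,37,700
softdrink_bottle_mix,Pre-mixed in soft-drink bottle,6,1250
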