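# fibroquant 0.1.0 config=534d4954e5071a68341c678a93feb3b6
layer,connective_pct,myocyte_pct,adipose_pct,analyzed_area_px,denominator_mode,provenance,excluded_from_analysis,section_id,midline_feasible
trabecular,51.329442,48.670558,0.000000,3084,tissue,measured,FALSE,S1,TRUE
inner_compact,47.228178,50.045942,2.725881,3265,tissue,measured,FALSE,S1,TRUE
outer_compact,35.183651,59.403480,5.412869,3621,tissue,measured,FALSE,S1,TRUE
epicardium,32.422216,63.681303,3.896482,3439,tissue,measured,TRUE,S1,TRUE
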