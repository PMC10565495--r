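quantity,condition,value,units,source_note,authoritative
IDP_L45,upright standing,0.50,MPa,"in vivo intradiscal pressure, classic transducer study; approximate figure-derived value",no
IDP_L45,30 deg flexion,1.10,MPa,"in vivo, approximate figure-derived value",no
IDP_L45,upright 20 kg held close,1.10,MPa,"in vivo lifting study, approximate",no
IAP,upright standing,4.0,mmHg,"range 1.5-7.5 mmHg across in vivo studies",no
IAP,flexed lifting,16.0,mmHg,"approximate upper range during lifting",no
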