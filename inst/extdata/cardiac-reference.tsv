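http://example.org/human#Heart	http://example.org/mouse#Heart	1
http://example.org/human#Myocardium	http://example.org/mouse#CardiacMuscleTissue	1
http://example.org/human#MitralValve	http://example.org/mouse#MitralValve	1
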