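category,cropped,downsample,cleaned
DO,17697,1000,871
E,756,0,264
ES,4342,1000,799
G,1365,0,882
R,528,0,263
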