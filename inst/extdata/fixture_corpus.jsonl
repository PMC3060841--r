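{"id":"fix-001","chemical":"Styrene","text":"Styrene is widely used in industry. The aim was to assess styrene genotoxicity. Mice were exposed to styrene for two weeks. Adduct levels increased significantly. We conclude that styrene is genotoxic.","sentences":[{"start":0,"end":35,"labels":{"S1":"OBJ","S2":"BKG","S3":"BKG"}},{"start":36,"end":79,"labels":{"S1":"OBJ","S2":"OBJ","S3":"GOAL"}},{"start":80,"end":123,"labels":{"S1":"METH","S2":"METH","S3":"EXP"}},{"start":124,"end":162,"labels":{"S1":"RES","S2":"RES","S3":"RES"}},{"start":163,"end":201,"labels":{"S1":"CON","S2":"CON","S3":"CON"}}]}
{"id":"fix-002","chemical":"Chloroform","text":"Chloroform induces liver tumors in rodents. Dna adducts were measured by mass spectrometry. No increase was observed. These findings suggest a nongenotoxic mechanism.","sentences":[{"start":0,"end":43,"labels":{"S1":"OBJ","S2":"BKG","S3":"BKG"}},{"start":44,"end":91,"labels":{"S1":"METH","S2":"METH","S3":"METH"}},{"start":92,"end":117,"labels":{"S1":"RES","S2":"RES","S3":"OBS"}},{"start":118,"end":166,"labels":{"S1":"CON","S2":"CON"}}]}
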