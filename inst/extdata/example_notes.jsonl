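{"doc_id":"ex1","text":"He likes burning things"}
{"doc_id":"ex2","text":"She painted a picture of the situation"}
{"doc_id":"ex3","text":"She is in constant pain"}
{"doc_id":"ex4","text":"He suffers from severe headaches"}
{"doc_id":"ex5","text":"He is not on painkillers"}
{"doc_id":"ex6","text":"Afraid I will be in pain if surgery is unsuccessful"}
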