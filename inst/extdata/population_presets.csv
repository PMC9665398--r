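preset,country,hped,hocc,htau,ht,ht2,n_participants
uk-paper,UK,-10.7,-3.17,0.291,0.1,100,186
jp-paper,JP,4.18,-6.47,0.388,0.1,100,346
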