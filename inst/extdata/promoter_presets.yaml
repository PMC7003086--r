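nos:
  maternal:
    c_emb_w: 0.0
    c_germ_w: 0.96
    h: 0.833333333333
    r1_w: 0.3
    c_y: 0.0
    r1_y: 0.1
    c_emb_y: 0.0
    p_som_white: 1.0
    p_som_yellow: 1.0
  zygotic:
    c_emb_w: 0.0
    c_germ_w: 0.96
    h: 0.833333333333
    r1_w: 0.3
    c_y: 0.0
    r1_y: 0.1
    c_emb_y: 0.0
    p_som_white: 1.0
    p_som_yellow: 1.0
  rnp:
    c_emb_w: 0.85875
    c_emb_y: 0.0
vas:
  maternal:
    c_emb_w: 0.0
    c_germ_w: 0.96
    h: 0.835416666667
    r1_w: 0.164556962025
    c_y: 0.0
    r1_y: 0.1
    c_emb_y: 0.0
    p_som_white: 1.0
    p_som_yellow: 1.0
  zygotic:
    c_emb_w: 0.0
    c_germ_w: 0.96
    h: 0.835416666667
    r1_w: 0.164556962025
    c_y: 0.0
    r1_y: 0.1
    c_emb_y: 0.0
    p_som_white: 1.0
    p_som_yellow: 1.0
  rnp:
    c_emb_w: 0.865336658354
    c_emb_y: 0.0
BicC:
  maternal:
    c_emb_w: 0.0
    c_germ_w: 0.98
    h: 0.605102040816
    r1_w: 0.0
    c_y: 0.993333333333
    r1_y: 0.1
    c_emb_y: 0.0
    p_som_white: 1.0
    p_som_yellow: 1.0
  zygotic:
    c_emb_w: 0.0
    c_germ_w: 0.98
    h: 0.605102040816
    r1_w: 0.0
    c_y: 0.0
    r1_y: 0.1
    c_emb_y: 0.0
    p_som_white: 0.643
    p_som_yellow: 0.0
  rnp:
    c_emb_w: 0.871838111298
    c_emb_y: 0.993333333333
Ubi:
  maternal:
    c_emb_w: 0.0
    c_germ_w: 0.977
    h: 0.685772773797
    r1_w: 0.110749185668
    c_y: 0.288888888889
    r1_y: 0.1
    c_emb_y: 0.0
    p_som_white: 1.0
    p_som_yellow: 1.0
  zygotic:
    c_emb_w: 0.0
    c_germ_w: 0.979
    h: 0.898876404494
    r1_w: 0.0
    c_y: 0.288888888889
    r1_y: 0.1
    c_emb_y: 0.0
    p_som_white: 1.0
    p_som_yellow: 0.913
  rnp:
    c_emb_w: 0.889552238806
    c_emb_y: 0.288888888889
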