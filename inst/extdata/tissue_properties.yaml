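# Default tissue properties (1.5 T regime). PD relative (0-1), T1/T2 ms.
# Override any entry and pass the edited table to assignProperties().
source: literature-regime defaults
classes:
  background: {class: 0, PD: 0.02, T1: 100,  T2: 10}
  body:       {class: 1, PD: 0.75, T1: 900,  T2: 50}
  lungL:      {class: 2, PD: 0.20, T1: 800,  T2: 40}
  lungR:      {class: 3, PD: 0.20, T1: 800,  T2: 40}
  lvMyo:      {class: 4, PD: 0.80, T1: 870,  T2: 50}
  lvBlood:    {class: 5, PD: 0.95, T1: 1200, T2: 250}
  rvMyo:      {class: 6, PD: 0.80, T1: 870,  T2: 50}
  rvBlood:    {class: 7, PD: 0.95, T1: 1200, T2: 250}
  la:         {class: 8, PD: 0.95, T1: 1200, T2: 250}
  ra:         {class: 9, PD: 0.95, T1: 1200, T2: 250}
  aorta:      {class: 10, PD: 0.95, T1: 1200, T2: 250}
  liverFat:   {class: 11, PD: 0.85, T1: 380,  T2: 55}
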