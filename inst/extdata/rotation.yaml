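# Default cyclic rotation track: each crop passes through phenological
# stage 1 then stage 2 (3 months each) before the next crop in a fixed
# order. Bare-soil fields are not listed and therefore persist.
track:
  - {crop: alfalfa, stage: "1", duration: 3}
  - {crop: alfalfa, stage: "2", duration: 3}
  - {crop: bean, stage: "1", duration: 3}
  - {crop: bean, stage: "2", duration: 3}
  - {crop: corn, stage: "1", duration: 3}
  - {crop: corn, stage: "2", duration: 3}
  - {crop: pasture, stage: "1", duration: 3}
  - {crop: pasture, stage: "2", duration: 3}
  - {crop: potato, stage: "1", duration: 3}
  - {crop: potato, stage: "2", duration: 3}
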