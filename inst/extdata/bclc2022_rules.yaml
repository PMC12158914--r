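# BCLC 2022 management flowchart as an ordered first-match rule table.
# Three-level routing: performance status, then stage, then tumour size.
# Leaf labels mirror the flowchart decision points.
rules:
  - ps: ["3", "4"]
    leaf: "BCLC=D→supportive care"
    recommend: ["supportive care"]
  - stage: ["D"]
    leaf: "BCLC=D→supportive care"
    recommend: ["supportive care"]
  - stage: ["C"]
    leaf: "BCLC=C→medical therapy"
    recommend: ["medical therapy"]
  - ps: ["1", "2"]
    leaf: "BCLC=C→medical therapy"
    recommend: ["medical therapy"]
  - stage: ["0"]
    size_max: 20
    leaf: "PS=0→BCLC=0"
    recommend: ["ablation", "resection"]
  - stage: ["0"]
    size_min: 20
    leaf: "PS=0→BCLC=A"
    recommend: ["resection", "transplant", "ablation"]
  - stage: ["A"]
    leaf: "PS=0→BCLC=A"
    recommend: ["resection", "transplant", "ablation"]
  - stage: ["B"]
    leaf: "PS=0→BCLC=B"
    recommend: ["TACE", "transplant"]
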