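{
  "NodesExamined": ["(?:a total of )?(<num>)\\s+(?:regional\\s+)?lymph nodes?\\s+(?:were\\s+|was\\s+)?(?:examined|dissected|sampled)", "of\\s+(<num>)\\s+lymph nodes?"],
  "NodesPositive": ["(<num>)\\s+of\\s+(?:<num>)\\s+lymph nodes?\\s+(?:are\\s+|were\\s+)?(?:positive|involved)", "(<num>)\\s+positive\\s+(?:regional\\s+)?lymph nodes?"],
  "TumorSize": ["tumou?r\\s+(?:size\\s+|measuring\\s+|measures\\s+)?(<num>)\\s*cm", "(<num>)\\s*cm\\s+(?:in\\s+)?(?:greatest\\s+)?(?:dimension|diameter)"],
  "SurgicalMarginsDistance": ["margin(?:s)?\\s+distance\\s+(<num>)\\s*cm", "(<num>)\\s*cm\\s+(?:from|to)\\s+the\\s+(?:closest\\s+)?(?:surgical\\s+)?margin"]
}
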