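[{"rule_id":"primary-site-diagnosis-cooccur","coding_item":"Primary Site","antecedents":[{"attribute":"section","op":"eq","value":"Diagnosis"},{"attribute":"cooccurHistology","op":"eq","value":"TRUE"}],"consequent":[{"type":"PRIMARY_SITE_CODING","value":"C341"},{"type":"LATERALITY_CODING","value":"2"}],"weight":1}]
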