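format-version: 1.2
ontology: mi (synthetic subset)

[Term]
id: MI:0001
name: interaction detection method

[Term]
id: MI:0045
name: experimental interaction detection
is_a: MI:0001 ! parent

[Term]
id: MI:0063
name: interaction prediction
is_a: MI:0001 ! parent

[Term]
id: MI:0401
name: biochemical
is_a: MI:0045 ! parent

[Term]
id: MI:0090
name: protein complementation assay
is_a: MI:0045 ! parent

[Term]
id: MI:0013
name: biophysical
is_a: MI:0045 ! parent

[Term]
id: MI:0004
name: affinity chromatography technology
is_a: MI:0401 ! parent

[Term]
id: MI:0096
name: pull down
is_a: MI:0004 ! parent

[Term]
id: MI:0019
name: coimmunoprecipitation
is_a: MI:0004 ! parent

[Term]
id: MI:0006
name: anti bait coimmunoprecipitation
is_a: MI:0019 ! parent

[Term]
id: MI:0007
name: anti tag coimmunoprecipitation
is_a: MI:0019 ! parent

[Term]
id: MI:0018
name: two hybrid
is_a: MI:0090 ! parent

[Term]
id: MI:0397
name: two hybrid array
is_a: MI:0018 ! parent

[Term]
id: MI:0071
name: molecular sieving
is_a: MI:0013 ! parent

[Term]
id: MI:0038
name: dynamic light scattering
is_a: MI:0013 ! parent

[Term]
id: MI:0190
name: interaction type

[Term]
id: MI:0914
name: association
is_a: MI:0190 ! parent

[Term]
id: MI:0915
name: physical association
is_a: MI:0914 ! parent

[Term]
id: MI:0407
name: direct interaction
is_a: MI:0915 ! parent

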