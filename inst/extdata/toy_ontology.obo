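format-version: 1.2
ontology: toy

[Term]
id: R:BP
name: biological process root
namespace: biological_process

[Term]
id: a
name: process a
namespace: biological_process
is_a: R:BP ! biological process root

[Term]
id: b
name: process b
namespace: biological_process
is_a: R:BP ! biological process root

[Term]
id: c
name: process c
namespace: biological_process
is_a: a ! process a
is_a: b ! process b

[Term]
id: d
name: process d
namespace: biological_process
is_a: c ! process c

[Term]
id: e
name: process e
namespace: biological_process
is_a: d ! process d

[Term]
id: f
name: process f
namespace: biological_process
is_a: a ! process a
is_a: e ! process e

[Term]
id: g
name: process g
namespace: biological_process
is_a: f ! process f

[Term]
id: obs1
name: withdrawn process
namespace: biological_process
is_obsolete: true
is_a: a ! process a

[Term]
id: R:MF
name: molecular function root
namespace: molecular_function

[Term]
id: m1
name: function m1
namespace: molecular_function
is_a: R:MF ! molecular function root

[Term]
id: R:CC
name: cellular component root
namespace: cellular_component

[Term]
id: c1
name: component c1
namespace: cellular_component
is_a: R:CC ! cellular component root
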