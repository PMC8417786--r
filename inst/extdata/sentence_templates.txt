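# Relation sentence templates for the synthetic corpus generator.
# Placeholders: {concept} = disease-related concept, {cytokine} = cytokine.
# The trigger verb lies strictly between the two entities so the templates
# are parseable by the adjacency heuristic; harder templates can be added
# here to probe its limits.
{concept} induces {cytokine} secretion in macrophages.
{cytokine} is elevated in {concept} patients.
{concept} increased {cytokine} levels in plasma.
{cytokine} was reduced in {concept} models after treatment.
{concept} stimulates {cytokine} release from cultured cells.
{cytokine} is associated with {concept} severity.
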