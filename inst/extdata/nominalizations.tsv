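# verb lemma <TAB> nominal surface
induce	induction
treat	treatment
diagnose	diagnosis
inhibit	inhibition
activate	activation
regulate	regulation
express	expression
associate	association
relate	relation
cause	causation
mutate	mutation
develop	development
prevent	prevention
stimulate	stimulation
suppress	suppression
mediate	mediation
produce	production
bind	binding
interact	interaction
recommend	recommendation
characterize	characterization
reduce	reduction
increase	increase
transcribe	transcription
translate	translation
replicate	replication
infect	infection
mutagenize	mutagenesis
proliferate	proliferation
differentiate	differentiation
migrate	migration
secrete	secretion
degrade	degradation
phosphorylate	phosphorylation
methylate	methylation
encode	encoding
use	use
involve	involvement
require	requirement
affect	effect
target	targeting
block	blockade
trigger	triggering
occur	occurrence
define	definition
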