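# Behaviour code -> category mapping for captive crow groups.
peck:
  category: agonistic
  description: pecks the recipient
jab:
  category: agonistic
  description: jabs with the bill
feather_pull:
  category: agonistic
  description: pulls the recipient's feathers
chase:
  category: agonistic
  description: chases the recipient
displace:
  category: agonistic
  description: approach causing the recipient to retreat
allopreen:
  category: affiliative
  description: preens the recipient
co_forage:
  category: affiliative
  description: forages jointly with the recipient
co_explore:
  category: affiliative
  description: explores an object jointly
sit_close:
  category: affiliative
  description: sits in close proximity
approach:
  category: ambiguous
  description: approach without clear intention
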