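# Reactive end-group template pairs for the AB-type split search.
# Entries are tried in order; the first match wins. Each side anchors both
# fragment ends: the fragment must begin with `head` and end with `tail`
# (without the anchors overlapping); `exact: true` means the fragment must
# equal `head` outright. Fragments are matched against rotations of the
# asterisk-stripped repeat-unit core.
- name: polyester          # diol + diacid-derived fragment
  first:  {head: "O", tail: "O"}
  second: {head: "C(=O)", tail: "C(=O)"}
- name: polyamide          # diamine + diacid-derived fragment
  first:  {head: "N", tail: "N"}
  second: {head: "C(=O)", tail: "C(=O)"}
- name: polyurethane       # diol + diisocyanate-derived fragment
  first:  {head: "O", tail: "O"}
  second: {head: "C(=O)N", tail: "NC(=O)"}
- name: polycarbonate      # diol + lone carbonate carbonyl
  first:  {head: "O", tail: "O"}
  second: {head: "C(=O)", tail: "C(=O)", exact: true}
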