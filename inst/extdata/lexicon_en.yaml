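# Default English mining lexicon.
# The three ESC-anchored worded descriptions map to 50 / 45 / 39 percent;
# "severely reduced" and "normal" are artifact-defined extras and may be
# removed. Swap this file out to mine notes in another language.
locale: en
triggers:
  - EF
  - ejection fraction
percent_words:
  - percent
worded_map:
  preserved: 50
  mildly reduced: 45
  reduced: 39
  severely reduced: 25
  normal: 60
past_qualifiers:
  - a year ago
  - years ago
  - previously
past_patterns:
  - '\bin (19|20)[0-9]{2}\b'
numeric_left_context: true
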