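# Published state tables for the two bundled panels: the high-function
# label of every state, in index order (undetermined CF marked "CF*", the
# bottom state empty). Used to pin the model's structure and numbering.

adni2_state_labels <- c(
  "ATT EM1 EM2 EM3 VF CF PS",
  "ATT EM1 EM2 EM3 VF CF",
  "ATT EM1 EM2 EM3 VF PS",
  "ATT EM1 EM2 EM3 VF",
  "ATT EM1 EM2 EM3 CF PS",
  "ATT EM1 EM2 EM3 PS",
  "ATT EM1 EM2 EM3 CF*",
  "ATT EM1 EM2 VF CF PS",
  "ATT EM1 EM2 VF CF",
  "ATT EM1 EM2 VF PS",
  "ATT EM1 EM2 VF",
  "ATT EM1 EM2 CF PS",
  "ATT EM1 EM2 PS",
  "ATT EM1 EM2 CF*",
  "ATT EM1 VF CF PS",
  "ATT EM1 VF CF",
  "ATT EM1 VF PS",
  "ATT EM1 VF",
  "ATT EM1 CF PS",
  "ATT EM1 PS",
  "ATT EM1 CF*",
  "ATT VF CF PS",
  "ATT VF CF",
  "ATT VF PS",
  "ATT VF",
  "ATT CF PS",
  "ATT PS",
  "ATT CF*",
  "")

aibl_state_labels <- {
  blocks <- c("ATT EM1 EM2 EM3", "ATT EM1 EM2", "ATT EM1", "ATT")
  suffixes <- c(" VF CF PS", " VF CF", " VF PS", " VF",
                " CF PS", " CF", " PS", "")
  c(as.vector(t(outer(blocks, suffixes, paste0))), "")
}
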