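# Synthetic stand-in for a proteinase-core model (residues 186..698, 513
# residues) with planted catalytic-triad geometry and a planted loop-end
# pair. The deposited PrtP models are external downloads; these stand-ins
# exist so the geometry queries can be exercised against known truth.
make_standin_core_model <- function(h_s, model_id, d_s = 7, pair_422_574 = 10) {
  base <- make_helix_rod(513, start_index = 186L, model_id = model_id)
  ca <- base$ca
  idx <- base$seq_index
  phi <- 120 * pi / 180
  ca[match(215L, idx), ] <- c(0, 0, 0)
  ca[match(618L, idx), ] <- c(d_s, 0, 0)
  ca[match(279L, idx), ] <- c(d_s, 0, 0) + h_s * c(cos(phi), sin(phi), 0)
  ca[match(422L, idx), ] <- c(40, 40, 0)
  ca[match(574L, idx), ] <- c(40 + pair_422_574, 40, 0)
  aa <- base$aa
  aa[match(c(215L, 279L, 618L), idx)] <- c("D", "H", "S")
  chain_model(model_id, "MS22337_orf", idx, aa, ca)
}
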