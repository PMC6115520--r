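# shared fixtures built in code

toy_cache <- new.env(parent = emptyenv())

toys <- function() {
  if (is.null(toy_cache$nets)) toy_cache$nets <- toy_networks()
  toy_cache$nets
}

tracer_u20 <- function() ct_tracer("glc_u13c_20")
tracer_1c <- function() ct_tracer("glc_1_13c")

# 50/50 labeled/unlabeled tracer for every source of a toy network
toy_tracer <- function(net, frac = 0.3) {
  srcs <- net$metabolites$id[net$metabolites$role == "source"]
  nc <- stats::setNames(net$metabolites$n_carbons, net$metabolites$id)
  make_tracer(stats::setNames(lapply(srcs, function(s) {
    data.frame(pattern = c(strrep("1", nc[s]), strrep("0", nc[s])),
               fraction = c(frac, 1 - frac))
  }), srcs))
}

# MDV of every balanced metabolite by both simulators; returns max deviation
max_emu_vs_brute_dev <- function(net, v, tracer) {
  nc <- stats::setNames(net$metabolites$n_carbons, net$metabolites$id)
  bal <- net$metabolites$id[net$metabolites$role == "balanced" &
                              net$metabolites$n_carbons > 0]
  bf <- brute_force_simulate(net, v, tracer)
  max(vapply(bal, function(m) {
    max(abs(emu_mdv(net, v, tracer, m) -
              mdv_from_isotopomers(bf[[m]], seq_len(nc[m]))))
  }, 0))
}

diamond_fragments <- function() {
  data.frame(fragment = c("D_full", "D_c1"), amino_acid = "D",
             carbon_set = c("1-2", "1"), formula = "")
}

diamond_tracer <- function() {
  make_tracer(list(AX = data.frame(pattern = c("10", "00"),
                                   fraction = c(0.5, 0.5))))
}
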