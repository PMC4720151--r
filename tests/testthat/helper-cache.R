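# lazily computed objects shared across test files (one R session per run)
.cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (is.null(.cache[[key]])) .cache[[key]] <- force(expr)
  .cache[[key]]
}

bcell_net <- function() cached("net", load_bcell_network())
bcell_params <- function() cached("params", squad_params(bcell_net()))

# exhaustive wild-type enumeration over all 2^22 states (a few seconds;
# reused by several files)
wt_attractors <- function()
  cached("wt", label_attractors(enumerate_attractors(bcell_net())))
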