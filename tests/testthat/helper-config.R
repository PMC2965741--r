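# Coarse meshes keep unit-test runs fast; physics tests that need accuracy
# state their own mesh.
coarse_config <- function(..., n_r = 16, n_z = 80, total_time = 120) {
  args <- list(...)
  nm <- c(list(n_r = n_r, n_z = n_z, total_time = total_time),
          args$numerics %||% list())
  args$numerics <- nm[!duplicated(names(nm), fromLast = TRUE)]
  do.call(fiber_config, args)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# cache heavyweight simulations shared between tests within a file
run_cached <- local({
  cache <- new.env(parent = emptyenv())
  function(key, expr) {
    if (!exists(key, cache)) assign(key, force(expr), cache)
    get(key, cache)
  }
})
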