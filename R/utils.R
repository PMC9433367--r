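# Classed errors so callers (and the command-line driver) can map
# failure modes to distinct exit categories.
dosem_error <- function(category, message, call = sys.call(-1)) {
  stop(structure(
    class = c(paste0("dosem_", category), "dosem_error", "error", "condition"),
    list(message = message, call = call, category = category)
  ))
}

# Run an expression under a fixed seed without disturbing the caller's
# RNG stream.
with_preserved_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  old <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

is_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
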