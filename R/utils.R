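# Internal helpers: subsystem RNG streams and small numeric utilities.

# Independent RNG streams derived from one master seed, so that toggling one
# stochastic subsystem (loop extrusion, BD noise, particle placement) does not
# perturb the draws of the others. Each stream stores a .Random.seed snapshot.
make_rng_streams <- function(master_seed, names = c("smc", "bd", "placement")) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  streams <- new.env(parent = emptyenv())
  for (k in seq_along(names)) {
    # keep derived seeds inside 32-bit integer range
    set.seed((master_seed + 7919L * k) %% .Machine$integer.max)
    assign(names[k], get(".Random.seed", envir = globalenv()), envir = streams)
  }
  if (!is.null(old)) {
    assign(".Random.seed", old, envir = globalenv())
  }
  streams
}

# Evaluate expr with the given stream's RNG state active; update the stream.
with_stream <- function(streams, name, expr) {
  had <- exists(".Random.seed", envir = globalenv())
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  assign(".Random.seed", get(name, envir = streams), envir = globalenv())
  on.exit({
    assign(name, get(".Random.seed", envir = globalenv()), envir = streams)
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else {
      rm(".Random.seed", envir = globalenv())
    }
  })
  expr
}

random_unit_vector <- function() {
  repeat {
    v <- stats::rnorm(3)
    n <- sqrt(sum(v^2))
    if (n > 1e-12) return(v / n)
  }
}

`%||%` <- function(a, b) if (is.null(a)) b else a
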