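# Named RNG substreams derived from one master seed.
#
# Uses L'Ecuyer-CMRG streams (parallel::nextRNGStream) so that each
# (stage, sample, replicate) draws from its own stream: adding replicates or
# stages never perturbs draws made by earlier ones.

# Build an environment of independent stream states for the given names.
rng_streams <- function(seed, names) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed, kind = "L'Ecuyer-CMRG")
  s <- get(".Random.seed", envir = globalenv())
  streams <- new.env(parent = emptyenv())
  for (nm in names) {
    assign(nm, s, envir = streams)
    s <- parallel::nextRNGStream(s)
  }
  streams
}

# Evaluate `expr` with the RNG positioned at stream `name`. The stream state
# advances and is saved back, so successive draws from one stream never
# repeat; the caller's RNG state is restored afterwards.
with_stream <- function(streams, name, expr) {
  if (!exists(name, envir = streams)) stop("unknown RNG stream: ", name)
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  assign(".Random.seed", get(name, envir = streams), envir = globalenv())
  result <- expr
  assign(name, get(".Random.seed", envir = globalenv()), envir = streams)
  result
}
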