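# Internal helpers shared across modules.

# Clip probabilities away from 0/1 so log-likelihoods stay finite even for
# lapse = 0 fits.
clip_prob <- function(p, eps = 1e-9) {
  pmin(pmax(p, eps), 1 - eps)
}

# Derive `n` independent sub-seeds from one master seed without disturbing
# the caller's RNG stream. Used to give every observer/procedure its own
# reproducible stream.
derive_seeds <- function(seed, n) {
  stopifnot(length(seed) == 1L, is.finite(seed))
  old <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  sample.int(2147483646L, n)
}

# Stable hash of an R object via its canonical JSON form; ties reports to
# the exact configuration that produced them.
config_hash <- function(x) {
  json <- jsonlite::toJSON(x, auto_unbox = TRUE, digits = 15, null = "null",
                           force = TRUE)
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  writeLines(as.character(json), tmp)
  unname(tools::md5sum(tmp))
}

`%||%` <- function(x, y) if (is.null(x)) y else x
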