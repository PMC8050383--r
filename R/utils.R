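# internal helpers

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

is_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

# evaluate expr with a temporarily seeded RNG, restoring the caller's state
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

# short stable hash of an R object (provenance stamps)
config_hash <- function(x) {
  json <- jsonlite::serializeJSON(x, digits = 10)
  tf <- tempfile()
  on.exit(unlink(tf))
  writeChar(as.character(json), tf, eos = NULL)
  unname(tools::md5sum(tf))
}

vnorm <- function(v) sqrt(sum(v^2))

# 3x3 rotation about a unit axis by angle (radians), Rodrigues form
rotation_about_axis <- function(axis, angle) {
  u <- axis / vnorm(axis)
  K <- matrix(c(0, u[3], -u[2], -u[3], 0, u[1], u[2], -u[1], 0), 3, 3)
  diag(3) + sin(angle) * K + (1 - cos(angle)) * (K %*% K)
}
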