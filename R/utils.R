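# Internal helpers: classed error conditions, reproducible RNG scoping,
# object fingerprints.

abort <- function(subclass, message, ..., call = sys.call(-1)) {
  cond <- structure(
    class = c(paste0("atroscore_", subclass), "atroscore_error",
              "error", "condition"),
    list(message = message, call = call, ...)
  )
  stop(cond)
}

#' Evaluate an expression with a temporary RNG seed
#'
#' Runs `expr` with the global RNG seeded to `seed` and restores the caller's
#' RNG state afterwards, so library code never perturbs a user's random
#' stream.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @export
with_seed <- function(seed, expr) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    set.seed(NULL)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed)
  expr
}

# md5 of a canonical (version-pinned) serialization; used to fingerprint
# meshes, models and configs so cross-stage provenance can be checked.
object_fingerprint <- function(object) {
  tmp <- tempfile()
  on.exit(unlink(tmp), add = TRUE)
  con <- file(tmp, "wb")
  serialize(object, con, version = 2, xdr = TRUE)
  close(con)
  unname(tools::md5sum(tmp))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
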