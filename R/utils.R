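`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate code under a temporary RNG seed
#'
#' Runs `code` with the global RNG seeded at `seed`, then restores the
#' caller's RNG state, so simulation helpers are reproducible without
#' clobbering the session stream.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @keywords internal
local_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

unit_vector <- function(v) {
  nv <- sqrt(sum(v^2))
  if (nv == 0) stop("zero-length vector has no direction")
  v / nv
}

stopifnot_scalar_positive <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0)
    stop(sprintf("`%s` must be a single positive finite number", name), call. = FALSE)
  invisible(x)
}

#' Stable hash of a configuration list
#'
#' Serializes the (name-sorted) list to canonical JSON and returns its MD5,
#' so every output artifact can embed the resolved configuration it was
#' produced under.
#'
#' @param config a list of configuration values.
#' @return a length-1 character MD5 string.
#' @export
config_hash <- function(config) {
  ord <- function(x) {
    if (is.list(x) && !is.null(names(x))) {
      x <- x[order(names(x))]
      lapply(x, ord)
    } else x
  }
  txt <- jsonlite::toJSON(ord(config), auto_unbox = TRUE, digits = NA, null = "null")
  f <- tempfile(fileext = ".json")
  on.exit(unlink(f))
  writeLines(as.character(txt), f)
  unname(tools::md5sum(f))
}
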