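# Internal helpers.

#' Derive a 31-bit sub-seed from a base seed and a stage label
#'
#' Keeps the generator stages (network, population, stations, ...)
#' independently reproducible from one scenario seed.
#' @keywords internal
derive_seed <- function(seed, label) {
  h <- sum(utf8ToInt(label) * seq_along(utf8ToInt(label)) * 131)
  as.integer((as.numeric(seed) * 7919 + h) %% 2147483647)
}

#' Set a derived seed, returning a function that restores the RNG state
#' @keywords internal
local_seed <- function(seed, label) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  set.seed(derive_seed(seed, label))
  function() {
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
    invisible(NULL)
  }
}

#' Stop unless a scalar condition holds
#' @keywords internal
abort_if <- function(cond, msg) {
  if (isTRUE(cond)) stop(msg, call. = FALSE)
  invisible(NULL)
}
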