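#' Evaluate an expression under a temporary RNG seed
#'
#' Sets the random seed, runs \code{expr}, and restores the caller's RNG
#' state afterwards, so seeded internals never disturb the user's stream.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return the value of \code{expr}.
#' @keywords internal
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
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
  expr
}

# Deterministic integer sub-seed derived from a base seed and stream ids;
# kept strictly below 2^31 so it is always a valid R integer.
derive_seed <- function(seed, ...) {
  ids <- c(seed, ...)
  h <- 0
  for (x in ids) h <- (h * 69069 + as.numeric(x) + 1) %% 2147483647
  as.integer(h)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_lrsc <- function(fmt, ...) {
  stop(sprintf(fmt, ...), call. = FALSE)
}

# canonical class labels used throughout
LRSC_CLASSES <- c("benign", "malignant")

normalize_label <- function(label, where = "label") {
  if (is.null(label)) return(NA_character_)
  if (length(label) == 0) return(character(0))
  out <- tolower(trimws(as.character(label)))
  out[out %in% c("", "na")] <- NA_character_
  bad <- !(out %in% LRSC_CLASSES) & !is.na(out)
  if (any(bad)) {
    stop_lrsc("unknown %s '%s' (expected one of: %s)", where,
              out[bad][1], paste(LRSC_CLASSES, collapse = ", "))
  }
  out
}
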