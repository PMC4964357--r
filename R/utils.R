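#' @keywords internal
"_PACKAGE"

# Deterministic child seed from a master seed and a string tag.
# Kept below 2^31 so it is always a valid R integer seed.
derive_seed <- function(master, tag) {
  stopifnot(is.numeric(master), length(master) == 1L)
  h <- sum(utf8ToInt(paste0(tag, ":")) * seq_along(utf8ToInt(paste0(tag, ":"))))
  as.integer((as.numeric(master) * 48271 + h * 16807) %% 2147483587)
}

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

stop_cfg <- function(...) stop(sprintf(...), call. = FALSE)

check_proportion <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1)
    stop_cfg("configuration error: %s must be a proportion in [0, 1], got %s",
             name, format(x))
  invisible(x)
}

is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && !is.na(x) && x >= 1 && x == round(x)
}
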