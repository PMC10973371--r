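#' @keywords internal
"_PACKAGE"

# Internal plumbing: argument checks and stderr logging shared by all stages.

sf_log <- function(stage, ..., verbose = getOption("sigforge.verbose", FALSE)) {
  if (isTRUE(verbose)) {
    message(sprintf("[sigforge:%s] %s", stage, paste0(...)))
  }
  invisible(NULL)
}

stop_sf <- function(...) stop(sprintf(...), call. = FALSE)

check_flag01 <- function(x, what) {
  if (!all(x %in% c(0L, 1L))) {
    stop_sf("%s must be coded 0/1; found: %s", what,
            paste(utils::head(setdiff(unique(x), c(0, 1)), 3), collapse = ", "))
  }
  as.integer(x)
}

# seeded sub-stream: derive a reproducible child seed (< 2^31) from a parent
# seed and a stream label, so expression / survival / graph draws are
# independently reproducible.
child_seed <- function(seed, stream) {
  h <- sum(utf8ToInt(stream) * seq_along(utf8ToInt(stream)))
  (as.numeric(seed) * 48271 + h) %% 2147483587 + 1
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
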