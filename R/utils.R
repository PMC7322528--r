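# internal helpers shared across modules

#' Evaluate code with a temporary RNG seed
#'
#' Saves and restores the global RNG state so that seeded package
#' functions do not perturb the caller's random stream.
#' @noRd
withSeed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    stop("'seed' must be a single non-missing number")
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) {
    old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv()),
      add = TRUE
    )
  }
  set.seed(as.integer(seed))
  force(code)
}

#' Counts-per-million normalization
#'
#' Columns are scaled to a common library size of 1e6. Zero library
#' sizes are an error: a sample without any counts carries no signal.
#' @noRd
cpmNormalize <- function(mat) {
  libs <- colSums(mat)
  if (any(libs <= 0))
    stop("zero library size in sample(s): ",
         paste(colnames(mat)[libs <= 0], collapse = ", "))
  sweep(mat, 2L, libs, "/") * 1e6
}

#' @noRd
checkProb <- function(p, what = "p") {
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1))
    stop("'", what, "' values must lie in [0, 1]")
  invisible(p)
}
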