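#' @importFrom stats plogis pbinom quantile rnorm rlnorm rpois runif sd var
#'   cor.test binom.test friedman.test wilcox.test ks.test approx aggregate
#' @importFrom utils read.csv write.csv
#' @import data.table
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate code under a temporary RNG seed
#'
#' Saves and restores `.Random.seed` so seeded helpers do not perturb the
#' caller's random stream.
#'
#' @param seed integer seed, or NULL to leave the stream untouched.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  if (is.null(seed)) return(code)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  code
}

# Derive an independent sub-seed (< 2^31) from a master seed and stream index.
substream_seed <- function(seed, i) {
  as.integer((as.numeric(seed) %% 99991L) * 20011 + 7919 * (i %% 10007L)) %% 2147483587L + 1L
}

stop_missing_cols <- function(df, cols, what) {
  miss <- setdiff(cols, names(df))
  if (length(miss))
    stop(sprintf("%s is missing required column(s): %s", what,
                 paste(miss, collapse = ", ")), call. = FALSE)
  invisible(TRUE)
}

# Linear-interpolation upsampling of y over x onto a regular fine grid.
upsample_linear <- function(x, y, step = 0.1) {
  if (length(x) < 2L) return(list(x = x, y = y))
  grid <- seq(min(x), max(x), by = step)
  list(x = grid, y = stats::approx(x, y, xout = grid)$y)
}

# First grid point at/above criterion; NA if never reached.
first_crossing <- function(x, y, criterion) {
  hit <- which(y >= criterion)
  if (!length(hit)) NA_real_ else x[hit[1L]]
}
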