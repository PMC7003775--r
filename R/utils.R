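#' @useDynLib mpmriseg, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats quantile rnorm runif sd optim cor
#' @importFrom utils write.csv read.csv
NULL

# Run an expression with a private RNG stream so package functions are
# deterministic given `seed` and never disturb the caller's RNG state.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(as.integer(seed))
  expr
}

# Deterministic child seeds (kept below 2^31) derived from a parent seed.
derive_seeds <- function(seed, n) {
  with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}

stopf <- function(...) stop(sprintf(...), call. = FALSE)

warnf <- function(...) warning(sprintf(...), call. = FALSE)

`%||%` <- function(a, b) if (is.null(a)) b else a

check_same_dim <- function(a, b, what = "volumes") {
  if (!identical(dim(a), dim(b)))
    stopf("%s have mismatched grid shapes: (%s) vs (%s)", what,
          paste(dim(a), collapse = "x"), paste(dim(b), collapse = "x"))
  invisible(TRUE)
}

# Random halves stratified by a grouping factor (e.g. lesion phenotype), so
# both halves see every phenotype — at clinical cohort sizes random halves
# have this property automatically; stratifying preserves it at desk scale.
stratified_halves <- function(groups, seed) {
  idx_by <- split(seq_along(groups), groups)
  f1 <- integer(0)
  extra_to_first <- TRUE
  with_seed(seed, {
    for (g in idx_by) {
      p <- if (length(g) > 1) sample(g) else g
      k <- floor(length(p) / 2)
      if (length(p) %% 2 == 1) { # alternate odd remainders between halves
        if (extra_to_first) k <- k + 1
        extra_to_first <- !extra_to_first
      }
      f1 <- c(f1, p[seq_len(k)])
    }
  })
  list(sort(f1), sort(setdiff(seq_along(groups), f1)))
}

# sample() without the scalar-x surprise
resample <- function(x, k = length(x)) x[sample.int(length(x), k)]

as_mask <- function(x) {
  m <- array(as.logical(x), dim = dim(x))
  m[is.na(m)] <- FALSE
  m
}
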