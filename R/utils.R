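# Internal helpers shared across modules.

# Exponentials in the Arrhenius and logistic terms can overflow IEEE doubles
# for extreme (but representable) temperatures; cap the argument first.
.EXP_CAP <- 700

.exp_clamped <- function(x) exp(pmin(pmax(x, -.EXP_CAP), .EXP_CAP))

.check <- function(cond, ...) {
  if (!isTRUE(cond)) stop(..., call. = FALSE)
  invisible(TRUE)
}

.is_num1 <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state so
# that seeded operations do not perturb the global random stream.
.with_seed <- function(seed, code) {
  .check(.is_num1(seed), "seed must be a single finite number")
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = genv)
    else if (exists(".Random.seed", envir = genv, inherits = FALSE)) {
      rm(".Random.seed", envir = genv)
    }
  })
  set.seed(as.integer(seed) %% .Machine$integer.max)
  force(code)
}

# Latin-hypercube style stratified sample of n points in [0,1]^d: one point
# per stratum along every dimension, strata paired by random permutation.
.lhs_unit <- function(n, d) {
  m <- matrix(0, n, d)
  for (j in seq_len(d)) m[, j] <- (sample.int(n) - runif(n)) / n
  m
}

# Write a data frame as CSV with 17 significant digits so numeric round trips
# through text are lossless.
.write_csv17 <- function(df, path) {
  out <- df
  for (j in seq_along(out)) {
    if (is.numeric(out[[j]])) out[[j]] <- sprintf("%.17g", out[[j]])
  }
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
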