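# small shared internals

# evaluate expr under a local RNG state; the caller's stream is untouched
.with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Latin-hypercube starts scaled into [lower, upper]; rows are start vectors
.lhs_starts <- function(n, lower, upper, seed) {
  d <- length(lower)
  if (n < 1) return(matrix(numeric(0), nrow = 0, ncol = d))
  u <- .with_seed(seed, lhs::randomLHS(n, d))
  sweep(sweep(u, 2, upper - lower, `*`), 2, lower, `+`)
}

# run bounded Levenberg-Marquardt from several starts, return the best.
# Ties closer than 1e-12 go to the smaller parameter norm.
.multistart_lm <- function(resid_fn, starts, lower, upper,
                           control = minpack.lm::nls.lm.control(
                             maxiter = 1000, ftol = 1e-12, ptol = 1e-12)) {
  best <- NULL
  n_ok <- 0L
  for (i in seq_len(nrow(starts))) {
    fit <- tryCatch(
      minpack.lm::nls.lm(par = starts[i, ], lower = lower, upper = upper,
                         fn = resid_fn, control = control),
      error = function(e) NULL)
    if (is.null(fit)) next
    ok <- fit$info %in% 1:4
    if (ok) n_ok <- n_ok + 1L
    obj <- sum(fit$fvec^2)
    if (is.null(best) || obj < best$obj - 1e-12 ||
        (abs(obj - best$obj) <= 1e-12 &&
         sum(fit$par^2) < sum(best$fit$par^2))) {
      best <- list(fit = fit, obj = obj, ok = ok)
    }
  }
  if (is.null(best))
    stop("optimization failed from every start", call. = FALSE)
  best$n_ok <- n_ok
  best
}

# FNV-1a-style 29-bit hash of a string, for lightweight artifact provenance
# (29 bits keeps the multiply exact in double precision)
.fnv1a <- function(s) {
  bytes <- utf8ToInt(s)
  h <- 2166136261 %% 536870912
  for (b in bytes) {
    h <- bitwXor(h, b)
    h <- (h * 16777619) %% 536870912
  }
  sprintf("%08x", h)
}
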