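# Internal helpers shared across modules.

stopf <- function(...) stop(sprintf(...), call. = FALSE)
warnf <- function(...) warning(sprintf(...), call. = FALSE)

is_scalar_num <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

#' Evaluate code under a temporary RNG seed
#'
#' Runs `code` after `set.seed(seed)` and restores the caller's RNG stream
#' afterwards, so library functions never perturb user-level randomness.
#'
#' @param seed Integer seed.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  genv <- globalenv()
  old <- if (exists(".Random.seed", envir = genv, inherits = FALSE))
    get(".Random.seed", envir = genv)
  else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = genv, inherits = FALSE))
        rm(".Random.seed", envir = genv)
    } else {
      assign(".Random.seed", old, envir = genv)
    }
  })
  set.seed(seed)
  force(code)
}

# sign-preserving power: keeps odd symmetry for negative bases so that
# scores raised to non-integer exponents stay real
signed_pow <- function(x, p) sign(x) * abs(x)^p

# out[i, j] = m[i + dr, j + dc]; `fill` where the source index leaves the matrix
shift_matrix <- function(m, dr, dc, fill = FALSE) {
  M <- nrow(m)
  N <- ncol(m)
  out <- matrix(fill, M, N)
  rs <- seq_len(M) + dr
  cs <- seq_len(N) + dc
  rok <- rs >= 1L & rs <= M
  cok <- cs >= 1L & cs <= N
  if (any(rok) && any(cok))
    out[seq_len(M)[rok], seq_len(N)[cok]] <- m[rs[rok], cs[cok]]
  out
}
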