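#' Split-chain potential scale reduction factor (Rhat)
#'
#' Each chain is split in half and the standard potential scale reduction
#' factor is computed over the resulting half-chains:
#' `Rhat = sqrt(((L - 1) / L * W + B / L) / W)` with `B` the between- and
#' `W` the within-half-chain variance. Values below 1.1 are the
#' conventional convergence criterion. A parameter with (numerically) zero
#' within-chain variance is non-computable and reported as `NA` — a
#' degenerate chain stuck at a constant is "converged-degenerate", not
#' evidence of mixing.
#'
#' @param x a `dhglm_fit`, or a draws matrix (rows = draws).
#' @param chain chain index per row (required for a matrix).
#' @param parameter optional parameter name(s) to return.
#' @return Named numeric vector of Rhat values.
#' @export
rhat <- function(x, parameter = NULL, chain = NULL) {
  if (inherits(x, "dhglm_fit")) {
    out <- x$rhat
  } else {
    x <- as.matrix(x)
    if (is.null(chain)) stop("supply the chain index for a draws matrix")
    out <- split_rhat(x, chain)
  }
  if (!is.null(parameter)) {
    if (!all(parameter %in% names(out)))
      stop("unknown parameter: ",
           paste(setdiff(parameter, names(out)), collapse = ", "))
    out <- out[parameter]
  }
  out
}

split_rhat <- function(draws, chain) {
  draws <- as.matrix(draws)
  stopifnot(nrow(draws) == length(chain))
  halves <- lapply(split(seq_len(nrow(draws)), chain), function(ix) {
    h <- length(ix) %/% 2
    list(ix[seq_len(h)], ix[h + seq_len(h)])
  })
  parts <- unlist(halves, recursive = FALSE)
  L <- min(lengths(parts))
  parts <- lapply(parts, function(ix) ix[seq_len(L)])
  apply(draws, 2, function(v) {
    means <- vapply(parts, function(ix) mean(v[ix]), 0)
    vars <- vapply(parts, function(ix) var(v[ix]), 0)
    W <- mean(vars)
    B <- L * var(means)
    if (!is.finite(W) || W < 1e-300 ||
        W < 1e-12 * max(abs(means))^2 + 1e-300)
      return(NA_real_)
    sqrt(((L - 1) / L * W + B / L) / W)
  })
}
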