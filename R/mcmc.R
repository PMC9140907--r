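# Affine-invariant ensemble ("stretch move") MCMC sampler used for credible
# intervals. Minimal implementation of the Goodman & Weare move with the
# two-half update scheme; adequate for the low-dimensional, bounded
# posteriors arising here.

# log_post: function(par) -> log posterior (-Inf outside support)
# init: n_walkers x d matrix of starting positions (all finite log_post)
# Returns list(samples = (n_walkers*n_keep) x d, acceptance = fraction)
stretch_sampler <- function(log_post, init, n_steps, burn = floor(n_steps / 2),
                            a = 2) {
  x <- init
  nw <- nrow(x); d <- ncol(x)
  if (nw < 2 * d + 2) stop("need at least 2d + 2 walkers", call. = FALSE)
  lp <- apply(x, 1, log_post)
  if (any(!is.finite(lp)))
    stop("all walkers must start at finite posterior density", call. = FALSE)
  half <- nw %/% 2
  idx1 <- seq_len(half); idx2 <- (half + 1):nw
  keep <- vector("list", n_steps - burn)
  n_acc <- 0; n_prop <- 0
  for (step in seq_len(n_steps)) {
    for (side in 1:2) {
      act <- if (side == 1) idx1 else idx2
      oth <- if (side == 1) idx2 else idx1
      z <- ((a - 1) * runif(length(act)) + 1)^2 / a
      j <- sample(oth, length(act), replace = TRUE)
      prop <- x[j, , drop = FALSE] +
        z * (x[act, , drop = FALSE] - x[j, , drop = FALSE])
      lp_prop <- apply(prop, 1, log_post)
      log_r <- (d - 1) * log(z) + lp_prop - lp[act]
      acc <- log(runif(length(act))) < log_r
      acc[!is.finite(lp_prop)] <- FALSE
      x[act[acc], ] <- prop[acc, , drop = FALSE]
      lp[act[acc]] <- lp_prop[acc]
      n_acc <- n_acc + sum(acc); n_prop <- n_prop + length(acc)
    }
    if (step > burn) keep[[step - burn]] <- x
  }
  list(samples = do.call(rbind, keep), acceptance = n_acc / n_prop)
}
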