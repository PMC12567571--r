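# First-order Sobol global sensitivity indices of the integrated stage
# models, estimated with a Saltelli-type sampling plan.

#' First-order Sobol sensitivity indices
#'
#' Estimates the first-order index S_i = V_i / V for each input of a model
#' over an independent uniform box, using a Saltelli plan with two base
#' matrices A and B of size N and the estimator
#' S_i = mean(f(B) (f(A_B^i) - f(A))) / Var(f), where A_B^i is A with its
#' i-th column taken from B. An input the model does not depend on yields an
#' index of exactly 0 under this estimator; for purely additive models the
#' indices sum to 1 within Monte-Carlo error.
#'
#' @param model Function taking a data frame with one column per input
#'   (named as in `bounds`) and returning a numeric vector.
#' @param bounds Data frame with columns `input`, `lower`, `upper`
#'   (finite, `upper > lower`).
#' @param N Base sample size (default 2^14; must be >= 64).
#' @param seed Integer seed for the sampling plan.
#' @return Named numeric vector of first-order indices, with attributes
#'   `N`, `seed` and `variance`.
#' @examples
#' # additive model f = X + 2Y on U(0,1)^2: indices 1/5 and 4/5
#' b <- data.frame(input = c("x", "y"), lower = 0, upper = 1)
#' sobol_first_order(function(d) d$x + 2 * d$y, b, N = 4096, seed = 1)
#' @export
sobol_first_order <- function(model, bounds, N = 2^14, seed = 1L) {
  stopifnot(is.function(model), is.data.frame(bounds),
            all(c("input", "lower", "upper") %in% names(bounds)))
  if (any(!is.finite(bounds$lower)) || any(!is.finite(bounds$upper))) {
    stop("bounds must be finite")
  }
  if (any(bounds$upper <= bounds$lower)) stop("degenerate input box")
  if (N < 64) stop("N must be >= 64")
  k <- nrow(bounds)
  set.seed(seed)
  scale_cols <- function(u) {
    d <- as.data.frame(sweep(sweep(u, 2, bounds$upper - bounds$lower, "*"),
                             2, bounds$lower, "+"))
    names(d) <- bounds$input
    d
  }
  # Latin-hypercube base matrices: same estimator, substantially smaller
  # Monte-Carlo error for models dominated by few inputs
  A <- scale_cols(lhs::randomLHS(N, k))
  B <- scale_cols(lhs::randomLHS(N, k))
  fA <- model(A); fB <- model(B)
  if (length(fA) != N || any(!is.finite(fA)) || any(!is.finite(fB))) {
    stop("model must return a finite vector of length nrow(input)")
  }
  V <- stats::var(c(fA, fB))
  S <- vapply(seq_len(k), function(i) {
    ABi <- A; ABi[[i]] <- B[[i]]
    mean(fB * (model(ABi) - fA)) / V
  }, numeric(1))
  names(S) <- bounds$input
  attr(S, "N") <- N
  attr(S, "seed") <- seed
  attr(S, "variance") <- V
  S
}

#' Sobol indices of a fitted stage model
#'
#' Wraps [sobol_first_order()] around [stage_predict()]: the sampled inputs
#' are stage-predictor columns (e.g. `conc`, `tmix`, `rho_in_die`), any
#' remaining predictor is held at a fixed value.
#'
#' @param stage_model List with `combination` and `theta` (a `rom_fit` or a
#'   [ground_truth()] element).
#' @param bounds Data frame (`input`, `lower`, `upper`) over the sampled
#'   predictors.
#' @param norm A [norm_spec()].
#' @param fixed Named list of predictor columns held constant.
#' @param geom A [tablet_geometry()].
#' @inheritParams sobol_first_order
#' @return As [sobol_first_order()].
#' @export
sobol_stage <- function(stage_model, bounds, norm, fixed = list(),
                        geom = tablet_geometry(), N = 2^14, seed = 1L) {
  comb <- stage_model$combination
  theta <- stage_model$theta
  model <- function(d) {
    for (nm in names(fixed)) d[[nm]] <- fixed[[nm]]
    stage_predict(comb, theta, d, norm, geom)
  }
  sobol_first_order(model, bounds, N = N, seed = seed)
}
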