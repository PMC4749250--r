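#' Deterministic allele-frequency trajectory under selection
#'
#' Iterates the per-generation recursion of the chosen model, assuming a
#' constant, effectively infinite population.  Models (s >= 0 favours the
#' allele): `"simple"` unnormalized geometric growth `f' = f (1+s)` (an
#' upper bound on the normalized models, hence a lower bound on s when
#' inverted); `"dominance"` heterozygote and favoured homozygote both have
#' fitness 1+s, `f' = f (1+s) / (1 + (2-f) f s)`; `"additive"` heterozygote
#' 1+s, favoured homozygote 1+2s, `f' = f (1+s+fs) / (1 + 2fs)`.
#'
#' @param f0 starting allele frequency in \[0, 1\].
#' @param s selection coefficient per generation (>= 0).
#' @param n number of generations (>= 0).
#' @param model `"simple"`, `"dominance"` or `"additive"`.
#' @return Frequency after `n` generations (the simple model may exceed 1;
#'   it is an unnormalized bound).
#' @export
forward_freq <- function(f0, s, n,
                         model = c("simple", "dominance", "additive")) {
  model <- match.arg(model)
  if (any(f0 < 0 | f0 > 1)) stop("f0 must lie in [0, 1]")
  if (s < 0) stop("s must be >= 0")
  if (n < 0) stop("n must be >= 0")
  f <- f0
  for (i in seq_len(n)) {
    f <- switch(model,
                simple = f * (1 + s),
                dominance = f * (1 + s) / (1 + (2 - f) * f * s),
                additive = f * (1 + s + f * s) / (1 + 2 * f * s))
  }
  f
}

#' Closed-form simple-model selection coefficient
#'
#' Inverts `p1 = p0 (1+s)^n`: `s = exp(log(p1/p0)/n) - 1`.  Scale-invariant,
#' so dosages and frequencies give the same answer; a lower bound for the
#' dominance and additive estimates.
#'
#' @param p0 pre-selection level (genome-wide mean average dosage, or a
#'   frequency).
#' @param p1 post-selection level at the selected locus (> p0).
#' @param n generations.
#' @return The selection coefficient.
#' @export
s_simple <- function(p0, p1, n = 20) {
  if (p0 <= 0) stop("p0 must be > 0")
  if (p1 <= p0) stop("p1 must exceed p0: no positive-selection solution")
  exp(log(p1 / p0) / n) - 1
}

#' Estimate the selection coefficient from pre/post-selection dosages
#'
#' For the dominance and additive models, converts dosages to allele
#' frequencies by halving, then solves `forward_freq(p0/2, s, n) = p1/2`
#' for s by interval bisection, exploiting the monotonicity of the
#' trajectory in s.  The initial bracket \[0, 1\] is doubled upward until
#' it straddles the target.  The simple model dispatches to the
#' closed form [s_simple()].
#'
#' @param p0 genome-wide mean average dosage (proxy for the pre-selection
#'   level), in (0, 2).
#' @param p1 peak average dosage at the selected locus, in (p0, 2\].
#' @param n generations (default 20).
#' @param model `"simple"`, `"dominance"` or `"additive"`.
#' @param epsilon convergence tolerance on the frequency scale.
#' @param max_iter bisection iteration cap.
#' @return An object of class `selection_fit`: `s_hat`, `p0`, `p1`,
#'   `generations`, `model`, `epsilon`, `bracket`, `iterations`,
#'   `residual`.
#' @examples
#' solve_s(0.128, 0.365, model = "dominance")
#' @export
solve_s <- function(p0, p1, n = 20,
                    model = c("simple", "dominance", "additive"),
                    epsilon = 1e-8, max_iter = 200) {
  model <- match.arg(model)
  if (!(p0 > 0 && p1 > p0 && p1 <= 2))
    stop("need 0 < p0 < p1 <= 2 on the dosage scale")
  if (model == "simple") {
    s <- s_simple(p0, p1, n)
    fit <- list(s_hat = s, p0 = p0, p1 = p1, generations = n,
                model = model, epsilon = epsilon, bracket = NULL,
                iterations = 0L, residual = 0)
    class(fit) <- "selection_fit"
    return(fit)
  }
  f0 <- p0 / 2
  target <- p1 / 2
  if (target >= 1)
    stop("p1/2 must be < 1 for the dominance/additive recursions")
  a <- 0; b <- 1
  while (forward_freq(f0, b, n, model) < target) {
    a <- b; b <- 2 * b
    if (b > 2^20) stop("bracket expansion failed")
  }
  it <- 0L
  repeat {
    s <- (a + b) / 2
    y <- forward_freq(f0, s, n, model)
    it <- it + 1L
    if (abs(y - target) < epsilon || it >= max_iter) break
    if (y > target) b <- s else a <- s
  }
  if (abs(y - target) >= epsilon)
    stop("bisection did not converge within max_iter")
  structure(list(s_hat = s, p0 = p0, p1 = p1, generations = n,
                 model = model, epsilon = epsilon, bracket = c(a, b),
                 iterations = it, residual = y - target),
            class = "selection_fit")
}

#' @export
print.selection_fit <- function(x, ...) {
  cat(sprintf(
    "selection_fit (%s model): s = %.3f  [p0 = %.3f, p1 = %.3f, %d generations]\n",
    x$model, x$s_hat, x$p0, x$p1, x$generations))
  if (!is.null(x$bracket))
    cat(sprintf("  bisection: %d iterations, residual %.2e (epsilon %.0e)\n",
                x$iterations, x$residual, x$epsilon))
  invisible(x)
}

#' @export
coef.selection_fit <- function(object, ...) c(s = object$s_hat)
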