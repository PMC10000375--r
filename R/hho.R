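#' @include AllGenerics.R
NULL

#' Create a Harris hawks optimization configuration
#'
#' @param PS population size (>= 2).
#' @param Tm maximum iterations (>= 1).
#' @param lb,ub numeric vectors of per-dimension bounds, `lb < ub`.
#' @param seed integer seed for the run.
#' @return a validated [HHOConfig-class].
#' @examples
#' hhoConfig(PS = 20, Tm = 100, lb = c(0, 0), ub = c(5, 5), seed = 0)
#' @export
hhoConfig <- function(PS, Tm, lb, ub, seed = 1L) {
  obj <- new("HHOConfig", PS = as.integer(PS), Tm = as.integer(Tm),
             lb = as.numeric(lb), ub = as.numeric(ub), seed = as.integer(seed))
  validObject(obj)
  obj
}

#' Escaping energy of the prey
#'
#' The prey's energy decays linearly with iteration:
#' \eqn{E_p = 2 E_0 (1 - iter/T_m)}.  `|Ep| >= 1` selects exploration,
#' `|Ep| < 1` exploitation.
#'
#' @param E0 initial energy in [-1, 1].
#' @param iter current iteration (0 <= iter <= Tm).
#' @param Tm maximum iterations.
#' @return the energy `Ep`.
#' @examples
#' preyEnergy(0.8, 0, 100)   # 1.6
#' preyEnergy(0.8, 100, 100) # 0
#' @export
preyEnergy <- function(E0, iter, Tm) {
  if (iter < 0 || iter > Tm) stop("'iter' must satisfy 0 <= iter <= Tm")
  2 * E0 * (1 - iter / Tm)
}

#' Jump strength of the evading prey
#'
#' \eqn{F = 2 (1 - r_5)} with \eqn{r_5 \sim U(0,1)}, so `F` lies in [0, 2].
#' @param r5 uniform draw in [0, 1].
#' @return the jump strength.
#' @export
jumpStrength <- function(r5) {
  if (any(r5 < 0 | r5 > 1)) stop("'r5' must be in [0, 1]")
  2 * (1 - r5)
}

#' Heavy-tailed Levy flight step (Mantegna construction, beta = 1.5)
#'
#' @param d dimension (>= 1).
#' @param beta stability index of the Levy distribution.
#' @param seed optional seed; when given, draws are made under it and the
#'   global RNG stream is untouched.
#' @return a d-dimensional step vector.
#' @export
levyStep <- function(d, beta = 1.5, seed = NULL) {
  if (d < 1) stop("'d' must be >= 1")
  draw <- function() {
    sigma <- (gamma(1 + beta) * sin(pi * beta / 2) /
              (gamma((1 + beta) / 2) * beta * 2^((beta - 1) / 2)))^(1 / beta)
    u <- rnorm(d, sd = sigma)
    v <- rnorm(d)
    0.01 * u / abs(v)^(1 / beta)
  }
  if (is.null(seed)) draw() else withSeed(seed, draw())
}

# Uniform draw helper that honours injected values for testability.
.draw <- function(draws, name, n = 1L) {
  if (!is.null(draws[[name]])) draws[[name]] else runif(n)
}

#' One Harris hawk position update
#'
#' Applies the branch structure of the hunt: exploration when `|Ep| >= 1`
#' (random-hawk or mean-position move), otherwise one of the four besieges
#' chosen by the escape draw `r` and `|Ep|`: soft besiege, hard besiege, and
#' the two progressive-rapid-dive variants, whose candidate positions `Y`
#' (and Levy-perturbed `Z`) are accepted only when fitter than the current
#' hawk.  The result is clipped to the box.
#'
#' @param X current hawk position.
#' @param fX its fitness (minimization).
#' @param Xp prey (best-so-far) position and `fp` unused fitness bookkeeping.
#' @param Xrand position of a randomly chosen hawk (exploration branch).
#' @param Xa mean hawk position.
#' @param Ep escaping energy for this hawk at this iteration.
#' @param lb,ub box bounds.
#' @param objective objective function, required for the rapid-dive branches.
#' @param draws optional named list overriding the internal uniform draws
#'   (`q`, `r`, `r1`-`r5`, `B`, `levy`) for deterministic testing.
#' @return the new (clipped) position.
#' @export
hawkUpdate <- function(X, fX, Xp, Xrand, Xa, Ep, lb, ub,
                       objective = NULL, draws = list()) {
  d <- length(X)
  clipBox <- function(v) pmin(pmax(v, lb), ub)
  if (abs(Ep) >= 1) {                      # exploration
    q <- .draw(draws, "q")
    if (q >= 0.5) {
      r1 <- .draw(draws, "r1"); r2 <- .draw(draws, "r2")
      Xn <- Xrand - r1 * abs(Xrand - 2 * r2 * X)
    } else {
      r3 <- .draw(draws, "r3"); r4 <- .draw(draws, "r4")
      Xn <- (Xp - Xa) - r3 * (lb + r4 * (ub - lb))
    }
    return(clipBox(Xn))
  }
  r <- .draw(draws, "r")
  Fj <- jumpStrength(.draw(draws, "r5"))
  dX <- Xp - X
  if (r >= 0.5 && abs(Ep) >= 0.5) {        # soft besiege
    Xn <- dX - Ep * abs(Fj * Xp - X)
  } else if (r >= 0.5) {                   # hard besiege
    Xn <- Xp - Ep * abs(dX)
  } else {                                 # progressive rapid dives
    if (is.null(objective)) stop("rapid-dive branches need an 'objective'")
    base <- if (abs(Ep) >= 0.5) X else Xa  # hard dives dive at the mean
    Y <- clipBox(Xp - Ep * abs(Fj * Xp - base))
    B <- .draw(draws, "B", d)
    lf <- if (!is.null(draws$levy)) draws$levy else levyStep(d)
    Z <- clipBox(Y + B * lf)
    fY <- objective(Y); fZ <- objective(Z)
    Xn <- if (fY < fX) Y else if (fZ < fX) Z else X
  }
  clipBox(Xn)
}

#' Run Harris hawks optimization
#'
#' Population metaheuristic with a linearly decaying prey energy: hawks
#' explore while `|Ep| >= 1` and switch to soft/hard besieges (with or
#' without Levy-flight rapid dives) as the energy dissipates.  The prey is
#' the best-so-far hawk; minimization convention.
#'
#' @param objective function mapping a d-vector to a finite scalar.
#' @param config an [HHOConfig-class].
#' @return an [HHOResult-class] with non-increasing `fitnessHistory`.
#' @examples
#' sphere <- function(x) sum((x - 3)^2)
#' res <- hhoOptimize(sphere, hhoConfig(20, 50, c(0, 0), c(5, 5), seed = 0))
#' bestFitness(res)
#' @export
hhoOptimize <- function(objective, config) {
  stopifnot(is(config, "HHOConfig"))
  lb <- config@lb; ub <- config@ub
  d <- length(lb); PS <- config@PS; Tm <- config@Tm
  evalObj <- function(x) {
    v <- objective(x)
    if (!is.finite(v)) {
      stop("objective returned a non-finite value at position (",
           paste(signif(x, 6), collapse = ", "), ")")
    }
    v
  }
  withSeed(config@seed, {
    X <- matrix(runif(PS * d, rep(lb, each = PS), rep(ub, each = PS)), PS, d)
    fit <- apply(X, 1, evalObj)
    bi <- which.min(fit)
    Xp <- X[bi, ]; fp <- fit[bi]
    history <- numeric(Tm)
    for (iter in seq_len(Tm)) {
      Xa <- colMeans(X)
      for (i in seq_len(PS)) {
        E0 <- runif(1, -1, 1)
        Ep <- preyEnergy(E0, iter, Tm)
        Xrand <- X[sample.int(PS, 1L), ]
        X[i, ] <- hawkUpdate(X[i, ], fit[i], Xp, Xrand, Xa, Ep, lb, ub,
                             objective = evalObj)
        fit[i] <- evalObj(X[i, ])
        if (fit[i] < fp) { fp <- fit[i]; Xp <- X[i, ] }
      }
      history[iter] <- fp
    }
    new("HHOResult", bestPosition = Xp, bestFitness = fp, history = history)
  })
}

#' @rdname HHOResult-class
#' @aliases bestPosition,HHOResult-method
setMethod("bestPosition", "HHOResult", function(object) object@bestPosition)
#' @rdname HHOResult-class
setMethod("bestFitness", "HHOResult", function(object) object@bestFitness)
#' @rdname HHOResult-class
setMethod("fitnessHistory", "HHOResult", function(object) object@history)

setMethod("show", "HHOResult", function(object) {
  cat(sprintf("HHOResult: best fitness %.6g after %d iterations\n",
              object@bestFitness, length(object@history)))
})
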