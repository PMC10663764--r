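# Extensible registry of sampling distributions for the synthetic
# block-matrix generator. Each family registers a sampler(n, par) and a
# parameter validator. Beyond the common families, the registry includes the
# rarer ones relevant for stress-testing a nonmetric dissimilarity space:
# von Mises (circular), Zipf (power-law ranks), Borel (branching-process
# totals) and the leading Poisson-Dirichlet weight.

.dist_registry <- new.env(parent = emptyenv())

#' Register a sampling distribution family
#'
#' @param family family name (string).
#' @param sampler `function(n, par)` returning `n` draws; `par` is the numeric
#'   parameter vector of a [dist_spec()].
#' @param validator optional `function(par)` that stops on invalid parameters.
#' @param npar expected parameter count (checked at spec construction).
#' @export
register_distribution <- function(family, sampler, validator = NULL, npar = NULL) {
  stopifnot(is.character(family), length(family) == 1L, is.function(sampler))
  assign(family, list(sampler = sampler, validator = validator, npar = npar),
         envir = .dist_registry)
  invisible(family)
}

#' Names of all registered distribution families
#' @export
registered_distributions <- function() sort(ls(.dist_registry))

#' Names of the builtin distribution families
#' @export
builtin_families <- function() {
  c("normal", "uniform", "cauchy", "binomial", "poisson", "exponential",
    "gamma", "beta", "vonmises", "zipf", "borel", "poisson-dirichlet")
}

#' Distribution specification
#'
#' @param family a registered family name; see [registered_distributions()].
#' @param ... numeric parameters, in the family's canonical order.
#' @return object of class `nma_dist`: list with `family` and `par`.
#' @examples
#' dist_spec("uniform", 0, 1)
#' dist_spec("normal", mean = 5, sd = 1)
#' @export
dist_spec <- function(family, ...) {
  if (!exists(family, envir = .dist_registry, inherits = FALSE)) {
    stop2("unknown distribution family: ", family,
          " (registered: ", paste(registered_distributions(), collapse = ", "), ")")
  }
  entry <- get(family, envir = .dist_registry, inherits = FALSE)
  par <- c(...)
  if (length(par) && !is.numeric(par)) stop2("distribution parameters must be numeric")
  if (!is.null(entry$npar) && length(par) != entry$npar) {
    stop2(family, " expects ", entry$npar, " parameter(s), got ", length(par))
  }
  if (!is.null(entry$validator)) entry$validator(par)
  structure(list(family = family, par = par), class = "nma_dist")
}

#' @export
print.nma_dist <- function(x, ...) {
  cat(sprintf("%s(%s)\n", x$family, paste(format(x$par), collapse = ", ")))
  invisible(x)
}

#' Draw from a registered distribution
#'
#' @param spec a [dist_spec()].
#' @param n number of draws.
#' @param seed RNG seed; `NULL` uses the current stream.
#' @return numeric vector of length `n`.
#' @export
sample_distribution <- function(spec, n, seed = NULL) {
  stopifnot(inherits(spec, "nma_dist"), n >= 0)
  entry <- get(spec$family, envir = .dist_registry, inherits = FALSE)
  if (!is.null(entry$validator)) entry$validator(spec$par)
  with_seed(seed, entry$sampler(as.integer(n), spec$par))
}

# von Mises sampler, Best & Fisher (1979) wrapped-Cauchy rejection,
# vectorized in batches. Returns angles in (-pi, pi] around mu.
rvonmises <- function(n, mu, kappa) {
  if (kappa < 1e-10) return(stats::runif(n, -pi, pi))
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(0)
  while (length(out) < n) {
    m <- max(16L, ceiling((n - length(out)) * 1.6))
    u1 <- stats::runif(m); u2 <- stats::runif(m); u3 <- stats::runif(m)
    z <- cos(pi * u1)
    f <- (1 + r * z) / (r + z)
    cc <- kappa * (r - f)
    keep <- (cc * (2 - cc) - u2 > 0) | (log(cc / u2) + 1 - cc >= 0)
    theta <- sign(u3 - 0.5)[keep] * acos(pmin(1, pmax(-1, f[keep])))
    out <- c(out, theta)
  }
  theta <- out[seq_len(n)] + mu
  ((theta + pi) %% (2 * pi)) - pi
}

# Borel-Tanner: total progeny of `ancestors` independent Galton-Watson
# branching processes with Poisson(mu) offspring, mu in (0, 1).
rborel <- function(n, ancestors, mu) {
  vapply(seq_len(n), function(i) {
    total <- 0
    current <- ancestors
    while (current > 0) {
      total <- total + current
      current <- stats::rpois(1, mu * current)
    }
    total
  }, numeric(1))
}

# Zipf on 1..nmax with exponent s: P(k) proportional to k^(-s).
rzipf <- function(n, nmax, s) {
  p <- seq_len(nmax)^(-s)
  sample.int(nmax, n, replace = TRUE, prob = p)
}

check_len <- function(par, k, family) {
  if (length(par) != k) stop2(family, " expects ", k, " parameter(s)")
}

register_builtin_distributions <- function() {
  register_distribution("normal",
    function(n, par) stats::rnorm(n, par[1], par[2]),
    function(par) { check_len(par, 2, "normal")
      if (par[2] <= 0) stop2("normal: sd must be > 0") }, npar = 2)
  register_distribution("uniform",
    function(n, par) stats::runif(n, par[1], par[2]),
    function(par) { check_len(par, 2, "uniform")
      if (par[1] >= par[2]) stop2("uniform: requires a < b") }, npar = 2)
  register_distribution("cauchy",
    function(n, par) stats::rcauchy(n, par[1], par[2]),
    function(par) { check_len(par, 2, "cauchy")
      if (par[2] <= 0) stop2("cauchy: scale must be > 0") }, npar = 2)
  register_distribution("binomial",
    function(n, par) stats::rbinom(n, par[1], par[2]),
    function(par) { check_len(par, 2, "binomial")
      if (par[1] < 1 || par[1] != round(par[1])) stop2("binomial: size must be a positive integer")
      if (par[2] <= 0 || par[2] >= 1) stop2("binomial: prob must be in (0, 1)") }, npar = 2)
  register_distribution("poisson",
    function(n, par) stats::rpois(n, par[1]),
    function(par) { check_len(par, 1, "poisson")
      if (par[1] <= 0) stop2("poisson: lambda must be > 0") }, npar = 1)
  register_distribution("exponential",
    function(n, par) stats::rexp(n, par[1]),
    function(par) { check_len(par, 1, "exponential")
      if (par[1] <= 0) stop2("exponential: rate must be > 0") }, npar = 1)
  register_distribution("gamma",
    function(n, par) stats::rgamma(n, shape = par[1], rate = par[2]),
    function(par) { check_len(par, 2, "gamma")
      if (any(par <= 0)) stop2("gamma: shape and rate must be > 0") }, npar = 2)
  register_distribution("beta",
    function(n, par) stats::rbeta(n, par[1], par[2]),
    function(par) { check_len(par, 2, "beta")
      if (any(par <= 0)) stop2("beta: both shape parameters must be > 0") }, npar = 2)
  register_distribution("vonmises",
    function(n, par) rvonmises(n, par[1], par[2]),
    function(par) { check_len(par, 2, "vonmises")
      if (par[2] < 0) stop2("vonmises: kappa must be >= 0") }, npar = 2)
  register_distribution("zipf",
    function(n, par) rzipf(n, par[1], par[2]),
    function(par) { check_len(par, 2, "zipf")
      if (par[1] < 1 || par[1] != round(par[1])) stop2("zipf: support size must be a positive integer")
      if (par[2] <= 0) stop2("zipf: exponent must be > 0") }, npar = 2)
  register_distribution("borel",
    function(n, par) rborel(n, par[1], par[2]),
    function(par) { check_len(par, 2, "borel")
      if (par[1] < 1 || par[1] != round(par[1])) stop2("borel: ancestor count must be a positive integer")
      if (par[2] <= 0 || par[2] >= 1) stop2("borel: offspring mean must be in (0, 1)") }, npar = 2)
  register_distribution("poisson-dirichlet",
    function(n, par) stats::rbeta(n, 1 - par[2], par[1] + par[2]),
    function(par) {
      if (length(par) == 1L) par <- c(par, 0)
      if (length(par) != 2L) stop2("poisson-dirichlet expects 1 or 2 parameter(s)")
      if (par[2] < 0 || par[2] >= 1) stop2("poisson-dirichlet: discount alpha must be in [0, 1)")
      if (par[1] <= -par[2]) stop2("poisson-dirichlet: concentration theta must exceed -alpha")
    }, npar = NULL)
}

# poisson-dirichlet sampler expects par of length 2; pad a 1-parameter spec
.pd_pad <- function(par) if (length(par) == 1L) c(par, 0) else par

register_builtin_distributions()

# fix up poisson-dirichlet to tolerate the 1-parameter form at sample time
local({
  entry <- get("poisson-dirichlet", envir = .dist_registry)
  entry$sampler <- function(n, par) {
    par <- .pd_pad(par)
    stats::rbeta(n, 1 - par[2], par[1] + par[2])
  }
  assign("poisson-dirichlet", entry, envir = .dist_registry)
})

#' Random distribution specification for the asymptotic survey
#'
#' Draws a family uniformly from `families` and integer parameters uniformly
#' from `range` (default 1..400), with the normalization exceptions needed for
#' validity: the binomial probability and the Borel offspring mean are divided
#' by `range[2]` to land in (0, 1), uniform endpoints are sorted (and nudged
#' when equal), the Poisson-Dirichlet discount is dropped to its 1-parameter
#' form, and the Zipf exponent is kept as drawn.
#'
#' @param families candidate family names; defaults to the builtin families
#'   (user-registered families need their own parameter randomization).
#' @param range integer parameter range.
#' @return a [dist_spec()].
#' @export
random_dist_spec <- function(families = builtin_families(),
                             range = c(1, 400)) {
  family <- sample(families, 1L)
  r <- function() sample(seq.int(range[1], range[2]), 1L)
  par <- switch(family,
    "normal" = c(r(), r()),
    "uniform" = {
      ab <- sort(c(r(), r()))
      if (ab[1] == ab[2]) ab[2] <- ab[2] + 1
      ab
    },
    "cauchy" = c(r(), r()),
    "binomial" = c(r(), r() / range[2]),
    "poisson" = r(),
    "exponential" = r(),
    "gamma" = c(r(), r()),
    "beta" = c(r(), r()),
    "vonmises" = c(r(), r()),
    "zipf" = c(r(), r()),
    "borel" = c(r(), r() / range[2]),
    "poisson-dirichlet" = r(),
    c(r(), r())
  )
  # normalized parameters can hit invalid boundary values; nudge inward
  if (family %in% c("binomial", "borel") && par[2] >= 1) par[2] <- 1 - 1e-6
  dist_spec(family, par)
}
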