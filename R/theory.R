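#' Diffusion fixation probability of a new semidominant mutation
#'
#' Kimura's diffusion approximation for the probability that a single new
#' copy of a mutation with heterozygous advantage `s_het` (so homozygous
#' advantage `2 * s_het` under semidominance) eventually fixes in a
#' panmictic Wright-Fisher population of `N` diploids:
#' \deqn{u = \frac{1 - e^{-2 s_{het}}}{1 - e^{-4 N s_{het}}}}
#' The neutral limit `s_het -> 0` is `1/(2N)`; for `4 N s_het >> 1` the
#' probability approaches `2 s_het` (Haldane's classic result).
#'
#' @param s_het Heterozygous selection coefficient per generation (may be a
#'   vector; 0 gives the neutral value exactly).
#' @param N Diploid population size (scalar, >= 1).
#' @return Numeric vector of fixation probabilities in (0, 1).
#' @examples
#' fixation_prob(0, 1000)       # 1/2000
#' fixation_prob(0.01, 1000)    # ~0.0198
#' @export
fixation_prob <- function(s_het, N) {
  stopifnot(is.numeric(s_het), length(N) == 1L, N >= 1)
  vapply(s_het, function(s) {
    if (abs(s) < 1e-12) return(1 / (2 * N))
    num <- -expm1(-2 * s)
    den <- -expm1(-4 * N * s)
    num / den
  }, numeric(1))
}

#' Sweep timescales for a beneficial semidominant allele
#'
#' Computes two classic timescales for an allele sweeping through a
#' panmictic population, both in generations:
#' \itemize{
#'   \item `t_intermediate`: the deterministic logistic transit time between
#'     frequencies `p_lo` and `p_hi`,
#'     \eqn{\ln[p_{hi}(1-p_{lo}) / (p_{lo}(1-p_{hi}))] / s};
#'   \item `t_fix`: the expected fixation time of a new mutation conditional
#'     on fixation. The default is the large-`2Ns` diffusion asymptotic
#'     \eqn{(2/s)(\ln(2Ns) + \gamma)} with \eqn{\gamma} the Euler-Mascheroni
#'     constant; `fixation_method = "quadrature"` instead integrates the
#'     conditional sojourn-time density of the diffusion numerically.
#' }
#' Here `s` is the logistic per-generation growth rate of the allele, i.e.
#' the heterozygous advantage of a semidominant allele whose scaled strength
#' is `2 N s`. For Drosophila-like parameters (`2Ns = 250`, `N = 1e6`, so
#' `s = 1.25e-4`) these give roughly 22,200 generations between frequencies
#' 0.2 and 0.8 and roughly 97,600 generations to fix.
#'
#' @param s Logistic growth rate of the sweeping allele (> 0), per generation.
#' @param N Diploid population size.
#' @param p_lo,p_hi Frequency bounds defining "intermediate" (default 0.2, 0.8).
#' @param fixation_method `"asymptotic"` (default) or `"quadrature"` for the
#'   full conditional sojourn-time integral.
#' @return A tibble with columns `s`, `N`, `p_lo`, `p_hi`, `t_intermediate`,
#'   `t_fix` (generations).
#' @examples
#' sweep_duration(1.25e-4, 1e6)
#' @export
sweep_duration <- function(s, N, p_lo = 0.2, p_hi = 0.8,
                           fixation_method = c("asymptotic", "quadrature")) {
  stopifnot(length(s) == 1L, is.numeric(s))
  if (s <= 0) stop("`s` must be > 0", call. = FALSE)
  stopifnot(p_lo > 0, p_hi < 1, p_lo < p_hi)
  fixation_method <- match.arg(fixation_method)
  t_int <- log((p_hi * (1 - p_lo)) / (p_lo * (1 - p_hi))) / s
  t_fix <- switch(fixation_method,
    asymptotic = (2 / s) * (log(2 * N * s) + -digamma(1)),
    quadrature = conditional_fixation_time_quadrature(s, N)
  )
  tibble::tibble(s = s, N = N, p_lo = p_lo, p_hi = p_hi,
                 t_intermediate = t_int, t_fix = t_fix)
}

# Mean fixation time of a new mutation conditional on fixation, by numerical
# integration of the diffusion sojourn-time density (Ewens' t*(x) for genic
# selection with logistic rate s, scaled strength S = 4 N s_het = 2 * 2Ns).
# Drift variance x(1-x)/(2N) per generation; u(x) = (1-e^{-Sx})/(1-e^{-S}).
conditional_fixation_time_quadrature <- function(s, N) {
  S <- 4 * N * s   # scaled strength of the diffusion; s is the logistic rate
  p0 <- 1 / (2 * N)
  # Green's-function sojourn density conditional on fixation, start p0:
  #   x > p0: t*(x) = 2 S_psi(1) u(x)(1-u(x)) / [V(x) psi(x)]
  # with psi(x) = e^{-Sx}, u(x) = (1-e^{-Sx})/(1-e^{-S}),
  # V(x) = x(1-x)/(2N), S_psi(1) = (1-e^{-S})/S. Algebraically:
  #   t*(x) = (4N/S) (1-e^{-Sx})(1-e^{-S(1-x)}) / [(1-e^{-S}) x(1-x)]
  # which is numerically stable for large S. For x < p0 multiply by
  # u(x)(1-u(p0)) / [u(p0)(1-u(x))] (negligible mass for p0 = 1/2N).
  u <- function(x) -expm1(-S * x) / -expm1(-S)
  t_upper <- function(x) {
    (4 * N / S) * expm1(-S * x) * expm1(-S * (1 - x)) /
      (-expm1(-S) * x * (1 - x))
  }
  t_lower <- function(x) {
    t_upper(x) * u(x) * (1 - u(p0)) / (u(p0) * (1 - u(x)))
  }
  i1 <- stats::integrate(t_upper, p0, 1, rel.tol = 1e-8,
                         subdivisions = 1000L, stop.on.error = FALSE)
  i2 <- stats::integrate(t_lower, 0, p0, rel.tol = 1e-8,
                         subdivisions = 1000L, stop.on.error = FALSE)
  if (!i1$message %in% c("OK", "the integral is probably divergent"))
    stop("sojourn-time quadrature failed: ", i1$message, call. = FALSE)
  i1$value + i2$value
}

#' Rate of adaptive substitutions and mean waiting time between them
#'
#' Given the adaptive proportion of substitutions `alpha`, the number of
#' functional sites `L`, the divergence per site `d`, and the divergence time
#' `T` in generations, the adaptive substitution rate is
#' \eqn{\alpha L d / T} substitutions per generation, and the mean waiting
#' time between adaptive substitutions is its reciprocal.
#'
#' @param alpha Proportion of substitutions driven by positive selection, in
#'   `[0, 1]`.
#' @param L Number of functional sites (bp).
#' @param d Substitutions per bp accumulated since divergence.
#' @param T_gen Generations since divergence (> 0).
#' @return A tibble with `rate` (substitutions/generation) and
#'   `waiting_time` (generations; `Inf` when `rate` is 0).
#' @examples
#' adaptive_substitution_rate(0.5, 15e6, 0.0067, 14e6)
#' @export
adaptive_substitution_rate <- function(alpha, L, d, T_gen) {
  stopifnot(alpha >= 0, alpha <= 1, L >= 0, d >= 0)
  if (T_gen <= 0) stop("`T_gen` must be > 0", call. = FALSE)
  rate <- alpha * L * d / T_gen
  tibble::tibble(alpha = alpha, L = L, d = d, T_gen = T_gen,
                 rate = rate, waiting_time = ifelse(rate > 0, 1 / rate, Inf))
}

#' Expected number of concurrently incomplete selective sweeps
#'
#' Under a steady stream of adaptive substitutions at `rate` per generation,
#' each spending `intermediate_duration` generations in the intermediate
#' frequency band, the expected number of sweeps simultaneously at
#' intermediate frequency is `rate * intermediate_duration` (Little's law).
#'
#' @param rate Adaptive substitutions per generation (>= 0).
#' @param intermediate_duration Generations a sweeping allele spends at
#'   intermediate frequencies.
#' @return Expected count (numeric scalar).
#' @examples
#' n_incomplete_sweeps(1 / 280, 22200)  # ~79
#' @export
n_incomplete_sweeps <- function(rate, intermediate_duration) {
  stopifnot(rate >= 0, intermediate_duration >= 0)
  rate * intermediate_duration
}

#' Predicted adaptive proportion of substitutions under an exponential DFE
#'
#' With a fraction `p_a` of new functional-site mutations beneficial, with
#' homozygous effects exponentially distributed with mean `mean_s`
#' (heterozygous effect `s/2`), and the remaining fraction neutral, the
#' long-run proportion of substitutions that are adaptive is
#' \deqn{\alpha = \frac{p_a E[u(s/2, N)]}{p_a E[u(s/2, N)] + (1 - p_a)/(2N)}}
#' where `u` is [fixation_prob()] and the expectation over the DFE is taken
#' by adaptive quadrature.
#'
#' @param dfe A [dfe_config()] object (fields `p_a`, `mean_s`).
#' @param N Diploid population size.
#' @return Predicted alpha in `[0, 1]`.
#' @examples
#' predict_alpha(dfe_config(p_a = 1e-4, mean_s = 0.02), N = 5000)
#' @export
predict_alpha <- function(dfe, N) {
  dfe <- as_dfe_config(dfe)
  stopifnot(N >= 1)
  if (dfe$p_a == 0) return(0)
  if (dfe$mean_s == 0) return(dfe$p_a)  # "beneficial" draws are neutral
  integrand <- function(s) {
    fixation_prob(s / 2, N) * stats::dexp(s, rate = 1 / dfe$mean_s)
  }
  eu <- stats::integrate(integrand, 0, Inf, rel.tol = 1e-10)
  if (eu$message != "OK")
    stop("DFE quadrature did not converge: ", eu$message, call. = FALSE)
  num <- dfe$p_a * eu$value
  num / (num + (1 - dfe$p_a) * (1 / (2 * N)))
}

#' Back-of-envelope sweep summary for a panmictic population
#'
#' Convenience wrapper chaining [adaptive_substitution_rate()],
#' [sweep_duration()] and [n_incomplete_sweeps()] for a single parameter set,
#' e.g. the Drosophila melanogaster calculation (`alpha = 0.5`, `L` = 15 Mbp
#' nonsynonymous sites, `d = 0.0067` subs/bp, `T_gen = 14e6`, `N = 1e6`,
#' `two_Ns = 250`).
#'
#' @param alpha,L,d,T_gen See [adaptive_substitution_rate()].
#' @param N Diploid effective population size.
#' @param two_Ns Scaled selection strength `2 N s` of sweeping alleles.
#' @param p_lo,p_hi Intermediate-frequency band (default 0.2-0.8).
#' @inheritParams sweep_duration
#' @return A one-row tibble: inputs plus `rate`, `waiting_time`,
#'   `t_intermediate`, `t_fix`, `n_incomplete_sweeps`. Class
#'   `"sweep_theory"` so [glance()] works on it.
#' @examples
#' sweep_theory_summary(0.5, 15e6, 0.0067, 14e6, N = 1e6, two_Ns = 250)
#' @export
sweep_theory_summary <- function(alpha, L, d, T_gen, N, two_Ns,
                                 p_lo = 0.2, p_hi = 0.8,
                                 fixation_method = "asymptotic") {
  s <- two_Ns / (2 * N)
  subs <- adaptive_substitution_rate(alpha, L, d, T_gen)
  dur <- sweep_duration(s, N, p_lo, p_hi, fixation_method = fixation_method)
  out <- tibble::tibble(
    alpha = alpha, L = L, d = d, T_gen = T_gen, N = N, two_Ns = two_Ns,
    s = s, p_lo = p_lo, p_hi = p_hi,
    rate = subs$rate,
    waiting_time = subs$waiting_time,
    t_intermediate = dur$t_intermediate,
    t_fix = dur$t_fix,
    n_incomplete_sweeps = n_incomplete_sweeps(subs$rate, dur$t_intermediate)
  )
  class(out) <- c("sweep_theory", class(out))
  out
}

#' @export
glance.sweep_theory <- function(x, ...) {
  tibble::as_tibble(x)[, c("rate", "waiting_time", "t_intermediate",
                           "t_fix", "n_incomplete_sweeps")]
}

#' @export
print.sweep_theory <- function(x, ...) {
  cat("Sweep theory summary (panmictic, semidominant)\n")
  cat(sprintf("  adaptive substitution rate : %.4g per generation\n", x$rate))
  cat(sprintf("  waiting time between subs  : %.4g generations\n",
              x$waiting_time))
  cat(sprintf("  sojourn at %.2g-%.2g freq    : %.4g generations\n",
              x$p_lo, x$p_hi, x$t_intermediate))
  cat(sprintf("  conditional fixation time  : %.4g generations\n", x$t_fix))
  cat(sprintf("  concurrent incomplete sweeps: %.4g\n", x$n_incomplete_sweeps))
  invisible(x)
}
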