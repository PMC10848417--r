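# Sequential mutation-acquisition likelihood framework: relative
# likelihoods that a series of k mutations (d of them drivers) was
# sequentially acquired within one clonal lineage, as a function of the
# per-division mutation rate mu, tumor size T and the clonal-expansion
# fraction c that follows each driver event.

#' Stable log(1 - exp(a)) for a <= 0
#' @noRd
log1mexp <- function(a) {
  stopifnot(all(a <= 0))
  out <- numeric(length(a))
  big <- a > -log(2)
  out[big] <- log(-expm1(a[big]))
  out[!big] <- log1p(-exp(a[!big]))
  out
}

#' log(1 - (1 - mu)^x), evaluated stably
#'
#' This is the log-probability that at least one of `x` cell divisions
#' (Poisson-like trials) acquires a mutation of per-division rate `mu`.
#' @noRd
log_p_at_least_one <- function(mu, x) {
  log1mexp(x * log1p(-mu))
}

check_evolution_params <- function(k, d, mu, T, c = 1) {
  if (any(k < 1)) stop("k must be >= 1", call. = FALSE)
  if (any(d < 0) || any(d > k - 1 + 1e-12))
    stop("d must satisfy 0 <= d <= k - 1", call. = FALSE)
  if (any(mu <= 0) || any(mu >= 1)) stop("mu must be in (0,1)", call. = FALSE)
  if (any(T < 1)) stop("T must be >= 1", call. = FALSE)
  if (any(c <= 0) || any(c > 1)) stop("c must be in (0,1]", call. = FALSE)
  invisible(TRUE)
}

#' Sequential-acquisition likelihood for a series of mutations
#'
#' Computes the unnormalized probability that a series of `k` mutations,
#' `d` of which are drivers (each followed by clonal expansion to a
#' fraction `c` of a tumor of `T` cells), was sequentially acquired within
#' the same clonal lineage:
#'
#' \deqn{P_{seq}(k,d) \propto (1-(1-\mu)^{Tc})^d \; \mu^{k-d-1} \;
#'   (1-(1-\mu)^T)}
#'
#' The first factor is the probability, per driver, that at least one cell
#' of the expanded clone (Tc cells) acquires the next mutation; passenger
#' mutations contribute a bare factor \eqn{\mu} each because random drift
#' provides no systematic expansion; the last factor is the probability
#' that the initial mutation arises at all. Evaluation is in log space
#' (`log1p`/`expm1`) so exponents as small as 1e-266 do not underflow.
#'
#' `k` and `d` may be fractional: the framework is applied to cohort
#' averages (e.g. a mean of 3.4 assayed mutations per patient).
#'
#' @param k number of sequentially acquired mutations (>= 1, real).
#' @param d number of driver mutations among the k - 1 subsequent
#'   mutations (0 <= d <= k - 1, real).
#' @param mu mutation probability per site (or per exome, for exome-wide
#'   series) per cell division, in (0,1).
#' @param T tumor size in cells.
#' @param c clonal-expansion fraction reached after each driver event,
#'   in (0,1].
#' @return list with `prob` (unnormalized probability; 0 if it underflows
#'   double range) and `log10` (its log10, always finite).
#' @examples
#' p_sequence(k = 3, d = 1, mu = 1e-4, T = 1e9)
#' @seealso [passenger_vs_driver_ratio()], [p_sequence_bounded()]
#' @export
p_sequence <- function(k, d, mu, T, c = 1) {
  check_evolution_params(k, d, mu, T, c)
  lp <- d * log_p_at_least_one(mu, T * c) +
    (k - d - 1) * log(mu) +
    log_p_at_least_one(mu, T)
  list(prob = exp(lp), log10 = lp / log(10))
}

#' Sequential-acquisition likelihood under a CCF expansion ceiling
#'
#' Variant of [p_sequence()] in which every clonal expansion is capped at
#' a fraction `f` of the tumor (e.g. f = 0.5: the lineage never exceeds
#' half the primary tumor's cells; f = 0.03: it stays beneath a 3%
#' detection floor). Implemented by evaluating the framework with c = f.
#'
#' @inheritParams p_sequence
#' @param f CCF ceiling in (0,1].
#' @return as [p_sequence()].
#' @export
p_sequence_bounded <- function(k, d, mu, T, f) {
  p_sequence(k, d, mu, T, c = f)
}

#' Closed-form upper bound on the all-passenger sequential probability
#'
#' With d = 0 the sequential-acquisition probability reduces to
#' \eqn{(1-(1-\mu)^T)\,\mu^{k-1} \le \mu^{k-1}}: the chance that one cell
#' acquires the remaining k - 1 passenger mutations with no clonal
#' expansion. At an exome-wide rate mu = 0.1 per division this bound is
#' 1e-3 for k = 4 and 1e-4 for k = 5.
#'
#' @param k number of sequential mutations (>= 1).
#' @param mu mutation rate per division in (0,1).
#' @return the bound mu^(k-1).
#' @export
passenger_upper_bound <- function(k, mu) {
  if (any(k < 1)) stop("k must be >= 1", call. = FALSE)
  if (any(mu <= 0) || any(mu >= 1)) stop("mu must be in (0,1)", call. = FALSE)
  exp((k - 1) * log(mu))
}

#' Relative likelihood of the all-passenger vs the driver model
#'
#' Ratio of the sequential-acquisition likelihood with no drivers to the
#' likelihood with `d_driver` drivers. The initial-mutation and shared
#' passenger factors cancel, leaving
#' \deqn{\left(\frac{\mu}{1-(1-\mu)^{Tc}}\right)^{d}}
#' which under saturated expansion (Tc\eqn{\mu \gg} 1, so every expanded
#' clone surely yields the next mutation) reduces to \eqn{\mu^{d}}.
#'
#' @param k series length (enters only through the requirement
#'   d_driver <= k - 1).
#' @param d_driver number of drivers in the driver model.
#' @param mu mutation rate per division.
#' @param T tumor size in cells; ignored when `saturated = TRUE`.
#' @param c expansion fraction per driver; ignored when `saturated = TRUE`.
#' @param saturated if TRUE assume Tc*mu >> 1 so the driver term is 1.
#' @return list with `ratio` (0 if underflowed) and `log10_ratio` (finite).
#' @examples
#' # at mu = 10^-4.5 and saturated expansion, 7 drivers cost 10^-31.5
#' passenger_vs_driver_ratio(k = 8, d_driver = 7, mu = 10^-4.5,
#'                           saturated = TRUE)
#' @export
passenger_vs_driver_ratio <- function(k, d_driver, mu, T = NULL, c = 1,
                                      saturated = is.null(T)) {
  if (any(d_driver < 0) || any(d_driver > k - 1 + 1e-12))
    stop("d_driver must satisfy 0 <= d_driver <= k - 1", call. = FALSE)
  if (any(mu <= 0) || any(mu >= 1)) stop("mu must be in (0,1)", call. = FALSE)
  if (saturated) {
    lr <- d_driver * log(mu)
  } else {
    check_evolution_params(k, d_driver, mu, T, c)
    lr <- d_driver * (log(mu) - log_p_at_least_one(mu, T * c))
  }
  list(ratio = exp(lr), log10_ratio = lr / log(10))
}

#' Combine per-patient sequential-acquisition probabilities
#'
#' Product across patients, accumulated in log space so that cohort-level
#' combined likelihoods far below double underflow remain representable.
#'
#' @param p numeric vector of per-patient probabilities (if
#'   `log10 = FALSE`) or their log10 values (if `log10 = TRUE`).
#' @param log10 whether `p` is already on the log10 scale.
#' @return list with `prob` (0 if underflowed) and `log10`.
#' @export
combine_patient_probabilities <- function(p, log10 = FALSE) {
  if (length(p) < 1) stop("need at least one probability", call. = FALSE)
  lp <- if (log10) p else base::log10(p)
  tot <- sum(lp)
  list(prob = 10^tot, log10 = tot)
}
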