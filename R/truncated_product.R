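#' Truncated-product combination of two p-values
#'
#' Combines an association p-value and a deregulation p-value by the
#' truncated product method: the statistic is the product of the p-values
#' that do not exceed the truncation threshold \code{tau} (1 if neither
#' does), and its null probability is evaluated analytically by conditioning
#' on how many of the two uniforms fall below \code{tau}. At \code{tau = 1}
#' the combined probability reduces to Fisher's two-test closed form
#' \code{w * (1 - log(w))}.
#'
#' Note that the combined p-value has an atom at 1 of mass
#' \code{(1 - tau)^2} under the null: it is exactly uniform only below
#' \code{1 - (1 - tau)^2} and conservative above, which is the intended
#' behavior of a truncation test.
#'
#' @param p_assoc,p_dereg p-values in (0, 1]; may be equal-length vectors.
#' @param tau Truncation threshold in (0, 1]. Default 0.01.
#' @return An object of class \code{combined_pvalue}: a data frame with
#'   columns \code{p_assoc}, \code{p_dereg}, \code{w} (the truncated
#'   product) and \code{p_combined} = Pr(W <= w).
#' @export
truncated_product <- function(p_assoc, p_dereg, tau = 0.01) {
  if (!(length(tau) == 1L && is.finite(tau) && tau > 0 && tau <= 1)) {
    stop("tau must be in (0, 1]")
  }
  p <- cbind(as.numeric(p_assoc), as.numeric(p_dereg))
  if (any(!is.finite(p)) || any(p <= 0) || any(p > 1)) {
    stop("p-values must lie in (0, 1]")
  }
  w <- ifelse(p[, 1L] <= tau, p[, 1L], 1) * ifelse(p[, 2L] <= tau, p[, 2L], 1)
  pr <- tp_tail_two(w, tau)
  out <- data.frame(p_assoc = p[, 1L], p_dereg = p[, 2L],
                    w = w, p_combined = pr)
  attr(out, "tau") <- tau
  class(out) <- c("combined_pvalue", "data.frame")
  out
}

# Pr(W <= w) for the two-test truncated product with threshold tau,
# conditioning on k = number of component p-values <= tau:
#   k = 1: 2 * tau * (1 - tau) * min(w, tau) / tau  -> 2 (1 - tau) min(w, tau)
#   k = 2: w * (1 + 2 log(tau) - log(w)) for w <= tau^2, else tau^2
# Pr(W <= 1) is 1 by definition (the whole probability space).
tp_tail_two <- function(w, tau) {
  k1 <- 2 * (1 - tau) * pmin(w, tau)
  k2 <- ifelse(w <= tau^2,
               w * (1 + 2 * log(tau) - log(w)),
               tau^2)
  pr <- k1 + k2
  pr[w >= 1] <- 1
  pmin(pr, 1)
}
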