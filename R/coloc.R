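# Bayesian colocalization of two association signals via per-variant
# Wakefield approximate Bayes factors and the five-hypothesis posterior.

#' Wakefield log approximate Bayes factor
#'
#' For an estimate `beta` with variance `V = se^2` and a normal prior with
#' variance `W = prior_sd^2` on the true effect, the log ABF against the
#' null is `0.5 * (log(1 - r) + z^2 * r)` with `r = W / (V + W)` and
#' `z = beta / se`.
#'
#' @param beta,se effect estimates and standard errors (vectorized).
#' @param prior_sd prior standard deviation of the true effect
#'   (conventionally 0.2 for a binary trait on the log-odds scale, 0.15 for
#'   a quantitative trait in SD units).
#' @return vector of log ABFs.
#' @export
wakefield_labf <- function(beta, se, prior_sd) {
  stop_if(any(se <= 0), "se must be > 0")
  stop_if(any(prior_sd <= 0), "prior_sd must be > 0")
  r <- prior_sd^2 / (se^2 + prior_sd^2)
  z <- beta / se
  0.5 * (log1p(-r) + z^2 * r)
}

#' Assemble an ABF track for colocalization
#'
#' @param variant_id variant identifiers.
#' @param beta,se summary statistics.
#' @param type "cc" (binary trait) or "quant"; selects the default prior sd
#'   (0.2 and 0.15 respectively).
#' @param prior_sd override for the prior standard deviation.
#' @return object of class `abf_track`.
#' @export
abf_track <- function(variant_id, beta, se, type = c("cc", "quant"),
                      prior_sd = NULL) {
  type <- match.arg(type)
  prior_sd <- prior_sd %||% if (type == "cc") 0.2 else 0.15
  labf <- wakefield_labf(beta, se, prior_sd)
  stop_if(any(!is.finite(labf)), "log ABFs must be finite")
  structure(list(variant_id = as.character(variant_id), labf = labf,
                 type = type, prior_sd = prior_sd),
            class = "abf_track")
}

#' Colocalization posterior from two ABF tracks
#'
#' Evaluates the five-hypothesis posterior (no association; trait 1 only;
#' trait 2 only; two distinct causal variants; one shared causal variant)
#' under the single-causal-variant assumption per trait, using log-sum-exp
#' throughout. The tracks are intersected on variant id; non-overlapping
#' variants are ignored with a message.
#'
#' @param track1,track2 [abf_track()] objects.
#' @param p1,p2 prior probabilities that a variant is causal for trait 1 /
#'   trait 2.
#' @param p12 prior probability that a variant is causal for both.
#' @return object of class `coloc_result`: `pp` (named PP0..PP4 summing to
#'   1), `n_variants`, priors, and `colocalized` (`PP4 > 0.75`).
#' @export
coloc_abf <- function(track1, track2, p1 = 1e-4, p2 = 1e-4, p12 = 1e-5) {
  stopifnot(inherits(track1, "abf_track"), inherits(track2, "abf_track"))
  common <- intersect(track1$variant_id, track2$variant_id)
  stop_if(length(common) == 0, "tracks share no variant")
  n_lost <- length(track1$variant_id) + length(track2$variant_id) -
    2 * length(common)
  if (n_lost > 0) message(n_lost, " non-overlapping variant record(s) ignored")
  l1 <- track1$labf[match(common, track1$variant_id)]
  l2 <- track2$labf[match(common, track2$variant_id)]
  s1 <- logsumexp(l1); s2 <- logsumexp(l2); s12 <- logsumexp(l1 + l2)
  lh <- c(PP0 = 0,
          PP1 = log(p1) + s1,
          PP2 = log(p2) + s2,
          PP3 = log(p1) + log(p2) + logdiffexp(s1 + s2, s12),
          PP4 = log(p12) + s12)
  pp <- exp(lh - logsumexp(lh))
  structure(list(pp = pp, n_variants = length(common),
                 priors = c(p1 = p1, p2 = p2, p12 = p12),
                 colocalized = colocalization_call(pp["PP4"])),
            class = "coloc_result")
}

#' Colocalization decision rule
#'
#' @param pp4 posterior probability of a shared causal variant, or a
#'   `coloc_result`.
#' @param threshold decision threshold (strictly above).
#' @return logical.
#' @export
colocalization_call <- function(pp4, threshold = 0.75) {
  if (inherits(pp4, "coloc_result")) pp4 <- pp4$pp["PP4"]
  unname(pp4 > threshold)
}

#' @export
print.coloc_result <- function(x, ...) {
  cat("colocalization posterior over", x$n_variants, "shared variants:\n")
  print(round(x$pp, 4))
  cat(if (x$colocalized) "PP4 > 0.75: colocalized\n" else "not colocalized\n")
  invisible(x)
}
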