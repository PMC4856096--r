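# Analytic genotype-frequency expectations under male transmission parameter
# k, MLE of k from progeny counts, and segregation goodness-of-fit tests.

#' Progeny genotype frequencies
#'
#' @param p_II,p_H,p_JJ Class probabilities; non-negative, summing to 1
#'   within 1e-12.
#' @return Named numeric vector of class `progeny_freq`.
#' @export
progeny_freq <- function(p_II, p_H, p_JJ) {
  p <- c(II = p_II, H = p_H, JJ = p_JJ)
  if (any(p < -1e-15) || abs(sum(p) - 1) > 1e-12)
    stop("progeny frequencies must be non-negative and sum to 1")
  structure(pmax(p, 0), class = "progeny_freq")
}

#' @export
print.progeny_freq <- function(x, ...) {
  cat(sprintf("<progeny freq> II=%.4g  H=%.4g  JJ=%.4g\n", x[["II"]], x[["H"]], x[["JJ"]]))
  invisible(x)
}

#' Progeny genotype counts
#'
#' Observed counts of the three genotype classes in a progeny population.
#' Testcross data use only the `H` and `JJ` classes (leave `n_II = 0`).
#'
#' @param n_II,n_H,n_JJ Non-negative integer counts; total must be positive.
#' @return An object of class `count_data`.
#' @examples
#' count_data(n_H = 134, n_JJ = 17)
#' @export
count_data <- function(n_II = 0, n_H = 0, n_JJ = 0) {
  n <- c(II = n_II, H = n_H, JJ = n_JJ)
  if (any(n < 0) || any(abs(n - round(n)) > 1e-8))
    stop("counts must be non-negative integers")
  if (sum(n) <= 0) stop("total count must be positive")
  structure(as.integer(round(n)), names = names(n), class = "count_data")
}

#' Observed genotype-class frequencies from counts
#'
#' @param counts A [count_data()] object.
#' @return Named numeric vector of class proportions (sums to 1).
#' @export
genotype_frequencies <- function(counts) {
  stopifnot(inherits(counts, "count_data"))
  unclass(counts) / sum(counts)
}

#' Percentage of a genotype class among progeny
#'
#' Convenience wrapper for frequencies quoted as "n_class / n_total"
#' (e.g. the recovered J-homozygote fractions 27/225 = 12.0% and
#' 31/161 = 19.3% in selfed progeny).
#'
#' @param n_class Count in the class of interest.
#' @param n_total Total progeny count (> 0).
#' @return Percentage, `100 * n_class / n_total`.
#' @examples
#' genotype_class_percent(27, 225) # 12
#' @export
genotype_class_percent <- function(n_class, n_total) {
  stopifnot(n_total > 0, n_class >= 0, n_class <= n_total)
  100 * n_class / n_total
}

.check_k <- function(k) {
  if (!is.numeric(k) || length(k) != 1L || is.na(k) || k < 0 || k > 1)
    stop("k must be a single number in [0, 1]")
  invisible(k)
}

#' Expected testcross class frequencies
#'
#' A heterozygous male parent crossed onto a JJ female: progeny are `H` with
#' probability `k` (the male gamete carried the favoured I allele) and `JJ`
#' with probability `1 - k`.
#'
#' @param k Male transmission parameter of the favoured allele; `k = 0.5` is
#'   Mendelian, `k = 1` complete killing.
#' @return Named numeric vector `c(H = k, JJ = 1 - k)`.
#' @examples
#' testcross_freq(0.89)
#' @export
testcross_freq <- function(k) {
  .check_k(k)
  c(H = k, JJ = 1 - k)
}

#' Expected selfed-progeny genotype frequencies
#'
#' Selfing a heterozygote with distorted male gametes `(k, 1-k)` and
#' Mendelian female gametes `(0.5, 0.5)` gives
#' `p_II = k/2`, `p_H = 1/2`, `p_JJ = (1-k)/2`. The heterozygote class is
#' always 1/2, whatever k: only the female side contributes variation there.
#'
#' @inheritParams testcross_freq
#' @return A [progeny_freq()].
#' @examples
#' selfing_freq(0.89) # (0.445, 0.5, 0.055)
#' @export
selfing_freq <- function(k) {
  .check_k(k)
  progeny_freq(k / 2, 0.5, (1 - k) / 2)
}

#' Genotype frequencies after g generations of single-seed descent
#'
#' Starting from an F1 heterozygote, each generation replaces a line by one
#' selfed offspring. Heterozygosity halves every generation
#' (`p_H(g) = 2^-g`), and fixation accrues in ratio `k : 1-k`:
#' `p_II(g) = k (1 - 2^-g)`, `p_JJ(g) = (1-k)(1 - 2^-g)`. The recursion is
#' iterated generation-wise; `generations = Inf` returns the fixation limit
#' `(k, 0, 1-k)` of a recombinant-inbred population.
#'
#' @inheritParams testcross_freq
#' @param generations Number of selfing generations, a non-negative integer
#'   or `Inf`.
#' @return A [progeny_freq()].
#' @examples
#' ssd_freq(0.89, 1)   # equals selfing_freq(0.89)
#' ssd_freq(0.89, Inf) # (0.89, 0, 0.11)
#' @export
ssd_freq <- function(k, generations) {
  .check_k(k)
  if (!is.numeric(generations) || length(generations) != 1L ||
      is.na(generations) || generations < 0)
    stop("generations must be a non-negative integer (or Inf)")
  if (is.infinite(generations)) return(progeny_freq(k, 0, 1 - k))
  generations <- as.integer(generations)
  p <- c(II = 0, H = 1, JJ = 0)
  for (g in seq_len(generations)) {
    # a het line fixes II w.p. k/2, JJ w.p. (1-k)/2, stays het w.p. 1/2
    p <- c(
      II = p[["II"]] + p[["H"]] * k / 2,
      H  = p[["H"]] / 2,
      JJ = p[["JJ"]] + p[["H"]] * (1 - k) / 2
    )
  }
  progeny_freq(p[["II"]], p[["H"]], p[["JJ"]])
}

#' Expected fixed-line counts in a recombinant-inbred population
#'
#' At the single-seed-descent fixation limit, lines are homozygous II or JJ
#' in ratio `k : 1-k`. Expected integer counts use round-half-away-from-zero
#' on `n * k`.
#'
#' @inheritParams testcross_freq
#' @param n_lines Number of RI lines (> 0).
#' @return Integer vector `c(II = ..., JJ = ...)` summing to `n_lines`.
#' @examples
#' ri_fixation(0.89, 148) # c(II = 132, JJ = 16)
#' @export
ri_fixation <- function(k, n_lines) {
  .check_k(k)
  stopifnot(is.numeric(n_lines), length(n_lines) == 1L, n_lines > 0,
            n_lines == round(n_lines))
  n_II <- as.integer(floor(n_lines * k + 0.5)) # half away from zero (k >= 0)
  c(II = n_II, JJ = as.integer(n_lines) - n_II)
}

#' Estimate the transmission parameter k from progeny counts
#'
#' Testcross design: `k_hat = n_H / (n_H + n_JJ)` (each H progeny received
#' the favoured I allele through the male gamete). Selfing design:
#' `k_hat = n_II / (n_II + n_JJ)` — heterozygote counts are uninformative
#' because `p_H = 1/2` regardless of k, so they are ignored. An exact
#' Clopper-Pearson binomial confidence interval is attached.
#'
#' @param counts A [count_data()] object.
#' @param design `"testcross"` or `"selfing"`.
#' @param conf_level Confidence level, default 0.95.
#' @return An object of class `k_estimate` with elements `k_hat`, `ci_low`,
#'   `ci_high`, `n` (informative total), `method`, `design`, `conf_level`.
#' @examples
#' estimate_k(count_data(n_H = 134, n_JJ = 17), "testcross")
#' @export
estimate_k <- function(counts, design = c("testcross", "selfing"),
                       conf_level = 0.95) {
  stopifnot(inherits(counts, "count_data"))
  design <- match.arg(design)
  stopifnot(conf_level > 0, conf_level < 1)
  x <- if (design == "testcross") counts[["H"]] else counts[["II"]]
  n <- x + counts[["JJ"]]
  if (n <= 0)
    stop("no informative counts for design '", design, "'")
  alpha <- 1 - conf_level
  ci_low  <- if (x == 0) 0 else stats::qbeta(alpha / 2, x, n - x + 1)
  ci_high <- if (x == n) 1 else stats::qbeta(1 - alpha / 2, x + 1, n - x)
  structure(
    list(k_hat = x / n, ci_low = ci_low, ci_high = ci_high, n = as.integer(n),
         method = "clopper-pearson", design = design, conf_level = conf_level),
    class = "k_estimate"
  )
}

#' @export
print.k_estimate <- function(x, ...) {
  cat(sprintf("<k estimate> k_hat = %.4f  %g%% CI [%.4f, %.4f]  (n = %d informative, %s design, %s)\n",
              x$k_hat, 100 * x$conf_level, x$ci_low, x$ci_high, x$n, x$design, x$method))
  if (x$design == "selfing")
    cat("  note: heterozygote counts ignored (p_H = 1/2 for every k)\n")
  invisible(x)
}

# Exact multinomial p-value by full enumeration of outcomes at the observed
# total: sum of probabilities of all outcomes no more probable than observed.
.exact_multinomial_p <- function(obs, probs) {
  n <- sum(obs)
  m <- length(obs)
  p_obs <- stats::dmultinom(obs, prob = probs)
  thresh <- p_obs * (1 + 1e-7) # relative tolerance for floating-point ties
  total <- 0
  counts <- integer(m)
  recurse <- function(i, remaining) {
    if (i == m) {
      counts[m] <<- remaining
      p <- stats::dmultinom(counts, prob = probs)
      if (p <= thresh) total <<- total + p
      return(invisible(NULL))
    }
    for (x in 0:remaining) {
      counts[i] <<- x
      recurse(i + 1L, remaining - x)
    }
  }
  recurse(1L, n)
  min(total, 1)
}

#' Goodness-of-fit test of segregation counts against an expected ratio
#'
#' `method = "pearson"` computes the standard Pearson chi-square statistic
#' `sum((O - E)^2 / E)` with `df = classes - 1`. `method =
#' "exact_multinomial"` enumerates all outcomes at the observed total and
#' sums the probabilities of outcomes no more probable than the observed one
#' (suitable for small totals; cost grows as `n^(m-1)`). The Pearson
#' statistic is reported in both cases.
#'
#' @param counts Numeric vector of observed class counts (or a
#'   [count_data()]; zero classes are retained).
#' @param ratio Expected ratio, same length as `counts`, entries > 0
#'   (e.g. `c(1, 2, 1)`).
#' @param method `"pearson"` or `"exact_multinomial"`.
#' @return An object of class `gof_result` with `statistic`, `df`,
#'   `p_value`, `method`.
#' @examples
#' gof_test(c(17, 134), c(1, 1))              # X^2 = 90.66
#' gof_test(c(3, 9), c(1, 1), "exact_multinomial")
#' @export
gof_test <- function(counts, ratio, method = c("pearson", "exact_multinomial")) {
  method <- match.arg(method)
  counts <- as.numeric(unclass(counts))
  if (length(counts) != length(ratio))
    stop("counts and ratio must have the same number of classes")
  if (any(ratio <= 0)) stop("expected ratio entries must be > 0")
  if (any(counts < 0) || sum(counts) <= 0) stop("counts must be non-negative with positive total")
  probs <- ratio / sum(ratio)
  expected <- sum(counts) * probs
  statistic <- sum((counts - expected)^2 / expected)
  df <- length(counts) - 1L
  p_value <- switch(method,
    pearson = stats::pchisq(statistic, df, lower.tail = FALSE),
    exact_multinomial = .exact_multinomial_p(as.integer(round(counts)), probs)
  )
  structure(
    list(statistic = statistic, df = df, p_value = p_value, method = method),
    class = "gof_result"
  )
}

#' @export
print.gof_result <- function(x, ...) {
  cat(sprintf("<goodness of fit> X^2 = %.4g, df = %d, p = %.4g (%s)\n",
              x$statistic, x$df, x$p_value, x$method))
  invisible(x)
}
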