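#' Truncate a sample at a coverage fraction
#'
#' Keeps the smallest `x_max` such that at least `coverage` of the values
#' are `<= x_max`, and drops everything above it. Distribution fits of
#' read-start integers are performed on the 90%-coverage truncation by
#' default, which discards the long sparse tail.
#'
#' @param values positive integers.
#' @param coverage fraction in (0, 1].
#' @return The retained values (original order).
#' @export
truncate_at_coverage <- function(values, coverage = 0.90) {
  if (!is.numeric(coverage) || length(coverage) != 1L || is.na(coverage) ||
    coverage <= 0 || coverage > 1) {
    stop("coverage must lie in (0, 1]")
  }
  if (length(values) == 0L) stop("empty sample")
  x_max <- sort(values)[ceiling(coverage * length(values))]
  values[values <= x_max]
}

#' Power-law probability weight for the extended Golomb fit
#'
#' `P_i = 2^(-log_m(i)) / (2 i (m - 1))` for integer `i >= 1` and divisor
#' `m >= 2`. The weights are used exactly as written, without
#' renormalization; they do not sum to 1 over `i >= 1`, so likelihood
#' comparisons renormalize over the truncated support (see
#' [recommend_codec()]).
#'
#' @param i positive integer(s) to be encoded.
#' @param m extended-Golomb divisor, `m >= 2`.
#' @return Numeric vector of unnormalized weights.
#' @export
power_law_pmf <- function(i, m) {
  if (any(i < 1)) stop("power-law support starts at i = 1")
  m <- check_scalar_pos(m, "divisor m")
  if (m < 2L) stop("power-law divisor m must be >= 2")
  2^(-log(i, base = m)) / (2 * i * (m - 1))
}

#' Fit a geometric model to positive integers
#'
#' Support is `{1, 2, ...}` (positions and gaps are at least 1), so the
#' pmf is `p (1 - p)^(x - 1)`. `"mle"` gives the closed form
#' `p = 1 / mean(x)`; `"least_squares"` minimizes the summed squared
#' residuals between the empirical and model pmf over `p`.
#'
#' @param values positive integers.
#' @param method `"mle"` or `"least_squares"`.
#' @return A list of class `geometric_model` with `p` and `mu = 1/p`.
#' @export
fit_geometric <- function(values, method = c("mle", "least_squares")) {
  method <- match.arg(method)
  if (length(values) == 0L) stop("empty sample")
  if (any(values < 1)) stop("geometric support starts at 1")
  p <- if (method == "mle") {
    1 / mean(values)
  } else {
    tab <- table(values)
    x <- as.integer(names(tab))
    emp <- as.numeric(tab) / length(values)
    stats::optimize(
      function(p) sum((emp - stats::dgeom(x - 1L, p))^2),
      interval = c(1e-9, 1)
    )$minimum
  }
  structure(list(p = p, mu = 1 / p, method = method), class = "geometric_model")
}

#' Fit a negative binomial model by maximum likelihood
#'
#' Values (support `{1, 2, ...}`) are shifted by one and fitted with the
#' negative binomial MLE of `MASS::fitdistr` (convergence tolerance is
#' `optim`'s default, `reltol = 1e-8`). Requires overdispersion: an
#' error is signalled when the sample variance does not exceed the mean.
#'
#' @param values positive integers with at least two distinct values.
#' @return A list of class `negbin_model` with dispersion `r`, success
#'   probability `p`, and the fitted mean `mu` (on the original support).
#' @export
fit_negbin <- function(values) {
  if (length(unique(values)) < 2L) stop("degenerate (zero-variance) sample")
  shifted <- values - 1
  if (stats::var(shifted) <= mean(shifted)) {
    stop("negative binomial requires overdispersion (variance > mean)")
  }
  fit <- MASS::fitdistr(shifted, "negative binomial")
  r <- unname(fit$estimate["size"])
  mu <- unname(fit$estimate["mu"])
  structure(
    list(r = r, p = r / (r + mu), mu = mu + 1),
    class = "negbin_model"
  )
}

#' Recommend an integer codec from the data
#'
#' Compares the goodness of fit (log-likelihood on the 90%-truncated
#' sample, each model renormalized over the truncated support) of a
#' geometric model against the power-law model on a divisor grid
#' `m in {2, 3, 4}`. A geometric winner maps to Golomb coding (divisor
#' kept at the default 3), a power-law winner to extended Golomb with the
#' best grid divisor. Huffman is always reported as the archival-ratio
#' option, and is the recommendation outright for degenerate
#' (single-value) input.
#'
#' @param values positive integers.
#' @param m_grid candidate extended-Golomb divisors.
#' @return A list with `codec`, `m`, and `archival = "huffman"`.
#' @export
recommend_codec <- function(values, m_grid = 2:4) {
  if (length(values) == 0L) stop("empty sample")
  if (length(unique(values)) < 2L) {
    return(list(codec = "huffman", m = NA_integer_, archival = "huffman"))
  }
  x <- truncate_at_coverage(values, 0.90)
  x_max <- max(x)
  sup <- seq_len(x_max)

  geo <- fit_geometric(x, "mle")
  geo_w <- stats::dgeom(sup - 1L, geo$p)
  ll_geo <- sum(log(geo_w[x])) - length(x) * log(sum(geo_w))

  ll_pl <- vapply(m_grid, function(m) {
    w <- power_law_pmf(sup, m)
    sum(log(w[x])) - length(x) * log(sum(w))
  }, numeric(1))

  if (ll_geo >= max(ll_pl)) {
    list(codec = "golomb", m = 3L, archival = "huffman")
  } else {
    list(codec = "extended_golomb", m = as.integer(m_grid[which.max(ll_pl)]), archival = "huffman")
  }
}

#' Export a histogram of an integer sample
#'
#' Plain-text `(integer, count)` table, for plotting start-position
#' distributions next to their fitted models.
#'
#' @param values integers.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
export_histogram <- function(values, path) {
  tab <- table(values)
  utils::write.table(
    data.frame(integer = as.integer(names(tab)), count = as.integer(tab)),
    path,
    sep = "\t", quote = FALSE, row.names = FALSE
  )
  invisible(path)
}
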