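#' Negative-binomial (size, prob) parameters from a mean and CV
#'
#' Converts the (mean, CV) parameterization used for smFISH per-cell mRNA
#' count tables into the classical negative-binomial \code{(size r, prob p)}
#' pair: \code{var = (cv * mean)^2}, \code{r = mean^2 / (var - mean)},
#' \code{p = r / (r + mean)}. At or below equidispersion
#' (\code{var <= mean}) the Poisson sentinel \code{r = Inf, p = 1} is
#' returned.
#'
#' @param mean expected copies per cell (> 0).
#' @param cv coefficient of variation as a fraction (>= 0), e.g. 0.295
#'   for 29.5\%.
#' @return A list with \code{size}, \code{prob}, \code{mean}, \code{var}
#'   and logical \code{poisson} (TRUE when the sentinel applies).
#' @examples
#' nb_params_from_mean_cv(38, 0.295)
#' @export
nb_params_from_mean_cv <- function(mean, cv) {
  if (!is.numeric(mean) || mean <= 0) stop("mean must be > 0", call. = FALSE)
  if (!is.numeric(cv) || cv < 0) stop("cv must be >= 0", call. = FALSE)
  v <- (cv * mean)^2
  if (v <= mean)
    return(list(size = Inf, prob = 1, mean = mean, var = v, poisson = TRUE))
  r <- mean^2 / (v - mean)
  list(size = r, prob = r / (r + mean), mean = mean, var = v,
       poisson = FALSE)
}

#' Generate a synthetic smFISH-like per-cell mRNA count sample
#'
#' Draws \code{n_cells} integer mRNA copy numbers from a negative-binomial
#' or Poisson law with the requested mean and CV, emulating smFISH count
#' populations. \code{family = "auto"} selects Poisson when the requested
#' variance does not exceed the mean (\code{cv^2 <= 1/mean}) and
#' negative-binomial otherwise.
#'
#' @param mean expected copies per cell (> 0).
#' @param cv coefficient of variation (fraction). Must satisfy
#'   \code{cv^2 > 1/mean} when \code{family = "negative_binomial"}
#'   (overdispersion), and \code{cv > 0} always (a zero-variance count law
#'   is refused).
#' @param family \code{"negative_binomial"}, \code{"poisson"} or
#'   \code{"auto"}. For \code{"poisson"} the CV is implied by the mean
#'   (\code{1/sqrt(mean)}); the argument is accepted for the spec of the
#'   target population but does not reshape the law.
#' @param n_cells number of cells (>= 1).
#' @param seed integer seed; \code{NULL} continues the current stream.
#' @param label optional construct label carried in the result.
#' @return An object of class \code{"count_sample"}: an integer vector of
#'   counts with attributes \code{label} and \code{spec}.
#' @examples
#' x <- gen_counts(mean = 38, cv = 0.295, n_cells = 1000, seed = 1)
#' summarize_counts(x)
#' @export
gen_counts <- function(mean, cv,
                       family = c("negative_binomial", "poisson", "auto"),
                       n_cells, seed = NULL, label = NULL) {
  family <- match.arg(family)
  if (!is.numeric(mean) || mean <= 0) stop("mean must be > 0", call. = FALSE)
  if (!is.numeric(cv) || cv < 0) stop("cv must be >= 0", call. = FALSE)
  if (!is.numeric(n_cells) || n_cells < 1)
    stop("n_cells must be >= 1", call. = FALSE)
  if (cv == 0)
    stop("cv = 0 requested: a zero-variance count law is not supported",
         call. = FALSE)
  if (family == "auto")
    family <- if (cv^2 <= 1 / mean) "poisson" else "negative_binomial"
  if (!is.null(seed)) set.seed(as.integer(seed))
  counts <- switch(family,
    poisson = rpois(n_cells, lambda = mean),
    negative_binomial = {
      nb <- nb_params_from_mean_cv(mean, cv)
      if (nb$poisson)
        stop("negative binomial requires cv^2 > 1/mean (overdispersion); ",
             "got cv^2 = ", signif(cv^2, 4), " vs 1/mean = ",
             signif(1 / mean, 4), call. = FALSE)
      rnbinom(n_cells, size = nb$size, mu = mean)
    })
  structure(as.integer(counts),
            label = label,
            spec = list(mean = mean, cv = cv, family = family,
                        n_cells = n_cells, seed = seed),
            class = "count_sample")
}

#' @export
print.count_sample <- function(x, ...) {
  s <- attr(x, "spec")
  cat(sprintf("count_sample: %d cells (%s, requested mean %g, cv %g)\n",
              length(x), s$family, s$mean, s$cv))
  if (!is.null(attr(x, "label"))) cat("  label:", attr(x, "label"), "\n")
  print(utils::head(as.integer(x), 20))
  invisible(x)
}
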