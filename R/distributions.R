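#' Specify an insert-length distribution
#'
#' Nontemplated (TdT) insert lengths in V(D)J junctions are small counts; the
#' simulator supports the families used throughout the package:
#'
#' * `"poisson"`: Poisson with the given `mean`.
#' * `"geometric"`: geometric on \{0, 1, 2, ...\} with the given `mean`.
#' * `"zi_geometric"`: a zero-inflated shifted geometric. With probability
#'   `zero_prob` the length is exactly 0 (a precise joint); otherwise it is
#'   `1 + G` where `G` is geometric with mean `mean_nonzero - 1`, so the
#'   non-zero part has mean `mean_nonzero`.
#' * `"constant"`: always `value` (useful in tests).
#'
#' @param family One of `"poisson"`, `"geometric"`, `"zi_geometric"`,
#'   `"constant"`.
#' @param mean Mean for the Poisson and geometric families.
#' @param zero_prob Probability of a zero-length insert (`zi_geometric`).
#' @param mean_nonzero Mean of the insert length conditional on it being
#'   non-zero (`zi_geometric`); must be > 1.
#' @param value Fixed value for the `constant` family.
#' @return A `dd_dist` object.
#' @examples
#' d <- dist_spec("zi_geometric", zero_prob = 0.38, mean_nonzero = 9.677)
#' dist_mean(d)
#' @export
dist_spec <- function(family = c("poisson", "geometric", "zi_geometric", "constant"),
                      mean = NULL, zero_prob = NULL, mean_nonzero = NULL,
                      value = NULL) {
  family <- match.arg(family)
  spec <- switch(family,
    poisson = {
      if (is.null(mean) || mean < 0) {
        dd_abort("poisson family needs a non-negative `mean`", "ddloop_parameter_error")
      }
      list(family = family, mean = mean)
    },
    geometric = {
      if (is.null(mean) || mean < 0) {
        dd_abort("geometric family needs a non-negative `mean`", "ddloop_parameter_error")
      }
      list(family = family, mean = mean)
    },
    zi_geometric = {
      if (is.null(zero_prob) || zero_prob < 0 || zero_prob > 1) {
        dd_abort("`zero_prob` must lie in [0, 1]", "ddloop_parameter_error")
      }
      if (is.null(mean_nonzero) || mean_nonzero <= 1) {
        dd_abort("`mean_nonzero` must exceed 1", "ddloop_parameter_error")
      }
      list(family = family, zero_prob = zero_prob, mean_nonzero = mean_nonzero)
    },
    constant = {
      if (is.null(value) || value < 0) {
        dd_abort("constant family needs a non-negative `value`", "ddloop_parameter_error")
      }
      list(family = family, value = value)
    }
  )
  structure(spec, class = "dd_dist")
}

#' @rdname dist_spec
#' @param x A `dd_dist` object.
#' @export
dist_mean <- function(x) {
  stopifnot(inherits(x, "dd_dist"))
  switch(x$family,
    poisson = x$mean,
    geometric = x$mean,
    zi_geometric = (1 - x$zero_prob) * x$mean_nonzero,
    constant = x$value
  )
}

#' @rdname dist_spec
#' @param n Number of draws.
#' @export
dist_sample <- function(x, n) {
  stopifnot(inherits(x, "dd_dist"))
  if (n == 0) {
    return(integer())
  }
  switch(x$family,
    poisson = rpois(n, x$mean),
    ## geometric with mean m on {0,1,...} has success prob 1/(m+1)
    geometric = if (x$mean == 0) rep(0L, n) else rgeom(n, 1 / (x$mean + 1)),
    zi_geometric = {
      zero <- runif(n) < x$zero_prob
      len <- 1L + rgeom(n, 1 / x$mean_nonzero)
      ifelse(zero, 0L, len)
    },
    constant = rep(as.integer(x$value), n)
  )
}

#' @export
print.dd_dist <- function(x, ...) {
  pars <- x[setdiff(names(x), "family")]
  cat(sprintf(
    "<dd_dist: %s (%s), mean %.3f>\n", x$family,
    paste(sprintf("%s=%g", names(pars), unlist(pars)), collapse = ", "),
    dist_mean(x)
  ))
  invisible(x)
}
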