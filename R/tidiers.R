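#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy an LAI regression
#' @param x a [fit_lai_model()] result.
#' @param ... unused.
#' @return one row per coefficient with `term`, `estimate`, `std.error`,
#'   `statistic`, `p.value`.
#' @export
tidy.lai_model <- function(x, ...) {
  s <- summary(x$fit)$coefficients
  tibble::tibble(term = c("intercept", tolower(x$kind)),
                 estimate = s[, 1], std.error = s[, 2],
                 statistic = s[, 3], p.value = s[, 4])
}

#' @rdname tidy.lai_model
#' @export
glance.lai_model <- function(x, ...) {
  tibble::tibble(kind = x$kind, slope = x$slope, intercept = x$intercept,
                 r.squared = x$r_squared, n = x$n_points)
}

#' Tidy a fitted affine alignment
#' @param x an `affine2d` from [fit_alignment()].
#' @param ... unused.
#' @export
tidy.affine2d <- function(x, ...) {
  tibble::tibble(
    term = c("a11", "a12", "a21", "a22", "b1", "b2"),
    estimate = c(x$A[1, 1], x$A[1, 2], x$A[2, 1], x$A[2, 2], x$b)
  )
}

#' @rdname tidy.affine2d
#' @export
glance.affine2d <- function(x, ...) {
  tibble::tibble(rms = x$rms, n = x$n)
}

#' Tidy validation statistics
#' @param x an `et_validation` from [validation_stats()].
#' @param ... unused.
#' @export
tidy.et_validation <- function(x, ...) {
  tibble::tibble(
    statistic = c("rmse", "rmsd", "bias", "slope", "intercept", "r", "p_value"),
    value = c(x$rmse, x$rmsd, x$bias, x$slope, x$intercept, x$r, x$p_value)
  )
}

#' @rdname tidy.et_validation
#' @export
glance.et_validation <- function(x, ...) {
  tibble::tibble(rmse = x$rmse, rmsd = x$rmsd, bias = x$bias,
                 slope = x$slope, intercept = x$intercept, r = x$r,
                 p.value = x$p_value, n = x$n)
}
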