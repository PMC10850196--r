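#' Fit a feature transform on training data
#'
#' Feature scaling is fitted on training data only and applied frozen to
#' held-out data. `standardize` maps each feature to
#' `(x - mean) / sd` using training moments (constant features map to 0);
#' `quantile` maps training ranks monotonically onto the uniform distribution
#' on \[0, 1\] and applies the map to new data by interpolation (constant
#' features map to 0.5); `none` is the identity.
#'
#' @param x numeric matrix of training features (columns = features).
#' @param method `"standardize"`, `"quantile"` or `"none"`.
#' @return list with `spec` (a `transform_spec`, frozen) and `x` (the
#'   transformed training matrix).
#' @seealso [apply_transform()]
#' @export
fit_transform <- function(x, method = c("standardize", "quantile", "none")) {
  method <- match.arg(method)
  x <- as.matrix(x)
  spec <- switch(method,
    none = list(),
    standardize = list(
      mean = colMeans(x),
      sd = apply(x, 2, stats::sd)),
    quantile = apply(x, 2, function(col) {
      xs <- sort(unique(col))
      # mean normalized rank of each distinct value (ties averaged)
      u <- vapply(xs, function(v) {
        r <- which(sort(col) == v)
        (mean(r) - 0.5) / length(col)
      }, 0)
      list(x = xs, u = u)
    }, simplify = FALSE))
  spec <- structure(list(method = method, params = spec,
                         features = colnames(x)),
                    class = "transform_spec")
  list(spec = spec, x = apply_transform(spec, x))
}

#' Apply a fitted transform
#'
#' @param spec a `transform_spec` from [fit_transform()].
#' @param x numeric matrix with the same columns the spec was fitted on.
#' @return transformed numeric matrix.
#' @export
apply_transform <- function(spec, x) {
  stopifnot(inherits(spec, "transform_spec"))
  x <- as.matrix(x)
  if (!is.null(spec$features) && !is.null(colnames(x))) {
    if (!all(spec$features %in% colnames(x))) {
      stop("matrix lacks feature(s) the transform was fitted on",
           call. = FALSE)
    }
    x <- x[, spec$features, drop = FALSE]
  }
  switch(spec$method,
    none = x,
    standardize = {
      sd0 <- spec$params$sd
      sd0[sd0 == 0 | is.na(sd0)] <- Inf  # constant feature -> 0
      sweep(sweep(x, 2, spec$params$mean, "-"), 2, sd0, "/")
    },
    quantile = {
      out <- x
      for (j in seq_len(ncol(x))) {
        p <- spec$params[[j]]
        if (length(p$x) < 2) {
          out[, j] <- 0.5
        } else {
          out[, j] <- stats::approx(p$x, p$u, xout = x[, j], rule = 2)$y
        }
      }
      out
    })
}
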