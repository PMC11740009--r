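#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Subset a dataset, keeping its grid and provenance
#' @param x A `cest_dataset`.
#' @param ... Passed to the tibble method.
#' @export
`[.cest_dataset` <- function(x, ...) {
  out <- NextMethod()
  if (is.data.frame(out) && "z" %in% names(out)) {
    structure(out, class = unique(c("cest_dataset", class(out))),
              grid = attr(x, "grid"), sat = attr(x, "sat"),
              provenance = attr(x, "provenance"))
  } else out
}
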