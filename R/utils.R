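#' @importFrom rlang .data
#' @importFrom generics tidy glance
#' @importFrom ggplot2 autoplot
NULL

#' @export
ggplot2::autoplot

BASES <- c("A", "C", "G", "T")

# Watson-Crick complement of single bases; NA passes through
complement_base <- function(x) {
  out <- c(A = "T", C = "G", G = "C", T = "A")[x]
  unname(out)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
generics::tidy

#' @export
generics::glance
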