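#' Syndrome elements and quality-of-life domains
#'
#' The six traditional-Chinese-medicine syndrome elements scored by the CAT
#' model, in their canonical order, and the eight domains of the
#' functional-digestive-disorder quality-of-life (QoL) instrument. The QoL
#' total score is reported as a ninth pseudo-domain named `"total"`.
#'
#' @return character vector of element or domain names.
#' @export
syndrome_elements <- function() {
  c("liver", "stomach", "heat", "spleen_dampness",
    "qi_deficiency", "qi_stagnation")
}

#' @rdname syndrome_elements
#' @param include_total if `TRUE`, append `"total"` to the domain list.
#' @export
fddql_domains <- function(include_total = FALSE) {
  d <- c("activities", "anxiety", "diet", "sleep", "discomfort",
         "health_perceptions", "coping", "stress")
  if (include_total) c(d, "total") else d
}
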