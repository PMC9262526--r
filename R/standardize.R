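#' Fit the min-max score standardizer
#'
#' Records per-element score extremes over a calibration sample of raw CAT
#' reporting-scale scores (typically baseline and follow-up pooled, so both
#' timepoints share one scale). These extremes anchor the 0-100
#' standardized scale: `(score - min) / (max - min) * 100`.
#'
#' @param raw_scores numeric matrix or data.frame of raw CAT scores with one
#'   column per element (column names are the element names).
#' @param provenance free-text note on the calibration sample.
#' @return object of class `score_standardizer` with named `min` and `max`
#'   vectors.
#' @export
fit_standardizer <- function(raw_scores, provenance = "pooled calibration sample") {
  m <- as.matrix(raw_scores)
  if (is.null(colnames(m))) stop_("raw_scores must have element column names")
  mins <- apply(m, 2, min, na.rm = TRUE)
  maxs <- apply(m, 2, max, na.rm = TRUE)
  if (any(maxs <= mins))
    stop_("constant scores for element(s): ",
          paste(colnames(m)[maxs <= mins], collapse = ", "))
  structure(list(min = mins, max = maxs, provenance = provenance),
            class = "score_standardizer")
}

#' Standardize raw CAT scores to the 0-100 scale
#'
#' Applies the affine map `(raw - min) / (max - min) * 100` per element.
#' Values outside the calibration range are clamped to [0, 100] with a
#' warning; calibration points themselves always map inside the scale, with
#' the extremes attaining 0 and 100 exactly.
#'
#' @param params a fitted [fit_standardizer()] object.
#' @param raw numeric vector (with `element` given) or matrix/data.frame with
#'   element column names.
#' @param element element name when `raw` is a plain vector.
#' @return standardized scores with the shape of `raw`.
#' @export
standardize_scores <- function(params, raw, element = NULL) {
  if (!inherits(params, "score_standardizer")) stop_("params must be fitted")
  if (is.null(dim(raw))) {
    if (is.null(element)) stop_("element required for vector input")
    if (!element %in% names(params$min)) stop_("unfitted element: ", element)
    out <- (raw - params$min[[element]]) /
      (params$max[[element]] - params$min[[element]]) * 100
    out <- check_clamp(out)
    return(unname(out))
  }
  m <- as.matrix(raw)
  if (!all(colnames(m) %in% names(params$min)))
    stop_("unfitted element(s): ",
          paste(setdiff(colnames(m), names(params$min)), collapse = ", "))
  out <- sweep(m, 2, params$min[colnames(m)], "-")
  out <- sweep(out, 2, (params$max - params$min)[colnames(m)], "/") * 100
  check_clamp(out)
}

check_clamp <- function(x) {
  n <- sum(x < 0 | x > 100, na.rm = TRUE)
  if (n > 0)
    warning("standardize_scores: ", n,
            " score(s) outside the calibration range clamped to [0, 100]")
  out <- pmin(pmax(x, 0), 100)
  attributes(out) <- attributes(x)
  out
}

#' @export
print.score_standardizer <- function(x, ...) {
  cat("Score standardizer (", x$provenance, ")\n", sep = "")
  print(round(rbind(min = x$min, max = x$max), 4))
  invisible(x)
}

#' Read / write standardizer parameters as JSON
#'
#' Serialized as `{element: {"min": m, "max": M}}`.
#'
#' @param params a `score_standardizer`.
#' @param path file path.
#' @return `read_standardizer` returns a `score_standardizer`.
#' @export
write_standardizer <- function(params, path) {
  obj <- lapply(seq_along(params$min), function(i)
    list(min = unname(params$min[i]), max = unname(params$max[i])))
  names(obj) <- names(params$min)
  # I(17) = 17 significant digits: doubles survive the round trip bit-exactly
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = I(17))
  invisible(path)
}

#' @rdname write_standardizer
#' @export
read_standardizer <- function(path) {
  obj <- jsonlite::read_json(path)
  mins <- vapply(obj, function(x) as.numeric(x$min), numeric(1))
  maxs <- vapply(obj, function(x) as.numeric(x$max), numeric(1))
  structure(list(min = mins, max = maxs, provenance = paste("read from", path)),
            class = "score_standardizer")
}
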