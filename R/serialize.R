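# JSON round-trip for observer specifications. The schema carries explicit
# units so serialized observers are self-describing; schema_version guards
# against silent format drift.

OBSERVER_SCHEMA_VERSION <- "1.0"

#' Serialize an observer specification to JSON
#'
#' @param observer an [observer_spec()].
#' @param path optional file path; if `NULL` the JSON string is returned.
#' @return the JSON string, invisibly when written to a file.
#' @export
observer_to_json <- function(observer, path = NULL) {
  stopifnot(inherits(observer, "observer_spec"))
  doc <- list(
    schema_version = OBSERVER_SCHEMA_VERSION,
    units = list(speed = "deg/s", slope = "1/(deg/s)", g = "deg/s",
                 contrast = "fraction", tau = "s",
                 spatial_frequency = "cycles/deg"),
    prior = list(knot_speeds = observer$prior$knot_speeds,
                 knot_slopes = observer$prior$knot_slopes),
    likelihood = list(knot_speeds = observer$likelihood$knot_speeds,
                      knot_g = observer$likelihood$knot_g,
                      contrast = unclass(observer$likelihood$contrast)),
    ratio = if (is.null(observer$ratio)) NULL else unclass(observer$ratio),
    spatial_frequency = observer$spatial_frequency
  )
  js <- jsonlite::toJSON(doc, auto_unbox = TRUE, digits = NA, null = "null")
  if (!is.null(path)) {
    writeLines(js, path)
    return(invisible(js))
  }
  js
}

#' Deserialize an observer specification from JSON
#'
#' @param x a JSON string or a path to a JSON file.
#' @return an [observer_spec()].
#' @export
observer_from_json <- function(x) {
  doc <- jsonlite::fromJSON(x)
  if (is.null(doc$schema_version) ||
      doc$schema_version != OBSERVER_SCHEMA_VERSION) {
    stop("unsupported observer schema version: ", doc$schema_version)
  }
  cr <- contrast_response(q = doc$likelihood$contrast$q,
                          c50 = doc$likelihood$contrast$c50,
                          r_max = doc$likelihood$contrast$r_max,
                          r_base = doc$likelihood$contrast$r_base)
  ratio <- NULL
  if (!is.null(doc$ratio)) {
    ratio <- ratio_params(tau1 = doc$ratio$tau1, tau2 = doc$ratio$tau2,
                          k = doc$ratio$k, s_p = doc$ratio$s_p,
                          s_m = doc$ratio$s_m)
  }
  observer_spec(
    prior = prior_model(doc$prior$knot_slopes, doc$prior$knot_speeds),
    likelihood = likelihood_model(doc$likelihood$knot_g, cr,
                                  doc$likelihood$knot_speeds),
    ratio = ratio,
    spatial_frequency = doc$spatial_frequency
  )
}
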