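#' Extract event or sample times
#'
#' @param x a series object.
#' @return numeric vector of times in seconds.
#' @export
setGeneric("seriesTimes", function(x) standardGeneric("seriesTimes"))

#' Extract the number of events or samples
#'
#' @param x a series object.
#' @return integer count.
#' @export
setGeneric("nBeats", function(x) standardGeneric("nBeats"))

#' Convert a series object to a data.frame
#'
#' @param x a series object.
#' @return a data.frame with one row per event or sample.
#' @export
setGeneric("asTable", function(x) standardGeneric("asTable"))
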