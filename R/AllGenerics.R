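#' @rdname model-accessors
#' @export
setGeneric("prototypes", function(object) standardGeneric("prototypes"))

#' @rdname model-accessors
#' @export
setGeneric("memberships", function(object) standardGeneric("memberships"))

#' @rdname model-accessors
#' @export
setGeneric("typicalities", function(object) standardGeneric("typicalities"))

#' @rdname model-accessors
#' @export
setGeneric("objectiveHistory",
           function(object) standardGeneric("objectiveHistory"))
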