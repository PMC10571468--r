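#' @include AllClasses.R
NULL

#' @export
setGeneric("bloomAdd", function(x, elements, ...) standardGeneric("bloomAdd"))

#' @export
setGeneric("bloomContains", function(x, elements, ...)
    standardGeneric("bloomContains"))

#' @export
setGeneric("filterSpec", function(x) standardGeneric("filterSpec"))

#' @export
setGeneric("hashScheme", function(x) standardGeneric("hashScheme"))

#' @export
setGeneric("filterSize", function(x) standardGeneric("filterSize"))

#' @export
setGeneric("numHashFunctions", function(x) standardGeneric("numHashFunctions"))

#' @export
setGeneric("designCapacity", function(x) standardGeneric("designCapacity"))

#' @export
setGeneric("targetFpr", function(x) standardGeneric("targetFpr"))

#' @export
setGeneric("countAdded", function(x) standardGeneric("countAdded"))

#' @export
setGeneric("filterBits", function(x) standardGeneric("filterBits"))

#' @export
setGeneric("isCanonicalizing", function(x) standardGeneric("isCanonicalizing"))

#' @export
setGeneric("schemeLabel", function(x) standardGeneric("schemeLabel"))
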