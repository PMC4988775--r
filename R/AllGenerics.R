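# Generics for the mesh-geometry layer. Downstream operations are plain
# functions: they take several objects of equal standing and gain nothing
# from dispatch.

#' @rdname vertexNormals
#' @export
setGeneric("vertexNormals", function(mesh, ...) standardGeneric("vertexNormals"))

#' @rdname gaussianCurvature
#' @export
setGeneric("gaussianCurvature", function(mesh, ...) standardGeneric("gaussianCurvature"))

#' @rdname geodesicDistance
#' @export
setGeneric("geodesicDistance", function(mesh, source, targets, ...)
  standardGeneric("geodesicDistance"))

#' @rdname meshAccessors
#' @export
setGeneric("meshVertices", function(x) standardGeneric("meshVertices"))

#' @rdname meshAccessors
#' @export
setGeneric("meshFaces", function(x) standardGeneric("meshFaces"))

#' @rdname meshAccessors
#' @export
setGeneric("meshEdges", function(x) standardGeneric("meshEdges"))

#' @rdname meshAccessors
#' @export
setGeneric("edgeLengths", function(x) standardGeneric("edgeLengths"))

#' @rdname meshAccessors
#' @export
setGeneric("nVertices", function(x) standardGeneric("nVertices"))

#' @rdname meshAccessors
#' @export
setGeneric("nFaces", function(x) standardGeneric("nFaces"))

#' @rdname fieldAccessors
#' @export
setGeneric("fieldValues", function(x) standardGeneric("fieldValues"))

#' @rdname fieldAccessors
#' @export
setGeneric("targetSites", function(x) standardGeneric("targetSites"))

#' @rdname fieldAccessors
#' @export
setGeneric("backgroundSites", function(x) standardGeneric("backgroundSites"))

#' @rdname segAccessors
#' @export
setGeneric("faceLabels", function(x) standardGeneric("faceLabels"))

#' @rdname segAccessors
#' @export
setGeneric("grooveBand", function(x) standardGeneric("grooveBand"))
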