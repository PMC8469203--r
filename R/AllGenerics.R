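## Generics, accessors and show methods.

#' @rdname PrimerPair
#' @param object,x a \code{PrimerPair} or \code{PrimerPanel}.
#' @export
setGeneric("fwdPrimer", function(x) standardGeneric("fwdPrimer"))
#' @rdname PrimerPair
#' @export
setGeneric("revPrimer", function(x) standardGeneric("revPrimer"))
#' @rdname PrimerPair
#' @export
setGeneric("expectedLength", function(x) standardGeneric("expectedLength"))
#' @rdname PrimerPair
#' @export
setGeneric("clusterLabel", function(x) standardGeneric("clusterLabel"))
#' @rdname PrimerPair
#' @export
setGeneric("pairDegeneracy", function(x) standardGeneric("pairDegeneracy"))

#' @rdname PrimerPair
#' @export
setMethod("fwdPrimer", "PrimerPair", function(x) x@fwd)
#' @rdname PrimerPair
#' @export
setMethod("revPrimer", "PrimerPair", function(x) x@rev)
#' @rdname PrimerPair
#' @export
setMethod("expectedLength", "PrimerPair", function(x) x@expectedLen)
#' @rdname PrimerPair
#' @export
setMethod("clusterLabel", "PrimerPair", function(x) x@cluster)
#' @rdname PrimerPair
#' @export
setMethod("pairDegeneracy", "PrimerPair", function(x) {
  degeneracy(x@fwd) * degeneracy(x@rev)
})

#' @rdname PrimerPair
#' @export
setMethod("show", "PrimerPair", function(object) {
  cat(sprintf(
    "PrimerPair [cluster %s]\n  fwd: 5'-%s-3'  (degeneracy %g)\n  rev: 5'-%s-3'  (degeneracy %g)\n  expected product: %d nt | pair degeneracy %g | %g nM\n",
    object@cluster, object@fwd, degeneracy(object@fwd),
    object@rev, degeneracy(object@rev), object@expectedLen,
    pairDegeneracy(object), recommendConcentration(pairDegeneracy(object))))
})

#' @rdname PrimerPanel
#' @param x,object,i a \code{PrimerPanel} / index.
#' @export
setMethod("length", "PrimerPanel", function(x) length(x@entries))
#' @rdname PrimerPanel
#' @export
setMethod("names", "PrimerPanel", function(x) names(x@entries))
#' @rdname PrimerPanel
#' @export
setMethod("[[", "PrimerPanel", function(x, i) x@entries[[i]])
#' @rdname PrimerPanel
#' @export
setMethod("show", "PrimerPanel", function(object) {
  cat(sprintf("PrimerPanel with %d primer pair(s): %s\n",
              length(object), paste(names(object), collapse = ", ")))
  df <- as.data.frame(object)
  print(df, row.names = FALSE)
})

#' Tabular view of a PrimerPanel
#'
#' @param x a [PrimerPanel-class].
#' @param ... ignored.
#' @return data.frame with one row per pair: cluster, fwd, rev,
#'   expected_len, pair_degeneracy, recommended_conc (nM).
#' @export
as.data.frame.PrimerPanel <- function(x, ...) {
  do.call(rbind, lapply(x@entries, function(e) {
    data.frame(cluster = e@cluster, fwd = e@fwd, rev = e@rev,
               expected_len = e@expectedLen,
               pair_degeneracy = pairDegeneracy(e),
               recommended_conc = recommendConcentration(pairDegeneracy(e)),
               stringsAsFactors = FALSE)
  }))
}

#' @rdname DesignResult
#' @param object a \code{DesignResult}.
#' @export
setMethod("show", "DesignResult", function(object) {
  cat(sprintf("DesignResult (%s) on %d leaf/leaves: %s\n", object@status,
              length(object@leaves),
              paste(object@leaves, collapse = ", ")))
  if (object@status == "success") show(object@pair[[1]])
  else if (length(object@diagnostics)) {
    cat("  diagnostics:",
        paste(names(object@diagnostics), object@diagnostics,
              sep = "=", collapse = ", "), "\n")
  }
})
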